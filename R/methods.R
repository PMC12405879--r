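# Accessors and show methods for the S4 classes.

#' @name accessors
#' @title Accessors for satmine classes
#' @description Accessor generics for \linkS4class{SatelliteFamilySet} and
#'   \linkS4class{KmerSatProfile}.
#' @param x a satmine object.
#' @param ... unused.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("familyIds", function(x, ...) standardGeneric("familyIds"))

#' @rdname accessors
#' @export
setGeneric("consensusSeqs", function(x, ...) standardGeneric("consensusSeqs"))

#' @rdname accessors
#' @export
setGeneric("familyMembers", function(x, ...) standardGeneric("familyMembers"))

#' @rdname accessors
#' @export
setGeneric("familyVariants", function(x, ...) standardGeneric("familyVariants"))

#' @rdname accessors
#' @export
setGeneric("familyTotalBp", function(x, ...) standardGeneric("familyTotalBp"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x, ...) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("unitAbundance",
           function(x, perGb = FALSE, ...) standardGeneric("unitAbundance"))

#' @rdname accessors
#' @export
setMethod("familyIds", "SatelliteFamilySet",
          function(x, ...) names(x@consensus))

#' @rdname accessors
#' @export
setMethod("consensusSeqs", "SatelliteFamilySet", function(x, ...) x@consensus)

#' @rdname accessors
#' @export
setMethod("familyMembers", "SatelliteFamilySet", function(x, ...) x@members)

#' @rdname accessors
#' @export
setMethod("familyVariants", "SatelliteFamilySet", function(x, ...) x@variants)

#' @rdname accessors
#' @export
setMethod("familyTotalBp", "SatelliteFamilySet", function(x, ...) x@totalBp)

#' @rdname accessors
#' @export
setMethod("length", "SatelliteFamilySet", function(x) length(x@consensus))

setMethod("show", "SatelliteFamilySet", function(object) {
  cat("SatelliteFamilySet with", length(object), "families,",
      nrow(object@members), "member monomers\n")
  if (length(object)) {
    ids <- familyIds(object)
    n <- min(8L, length(ids))
    for (i in seq_len(n)) {
      cat(sprintf("  %-14s unit %4d bp  %8.1f kb  %d member(s)\n",
                  ids[i], length(object@consensus[[i]]),
                  object@totalBp[i] / 1000,
                  sum(object@members$family_id == ids[i])))
    }
    if (length(ids) > n) cat("  ...", length(ids) - n, "more\n")
  }
  if (nrow(object@variants))
    cat("  variants called in",
        length(unique(object@variants$family_id)), "family(ies)\n")
})

#' @rdname accessors
#' @export
setMethod("sampleId", "KmerSatProfile", function(x, ...) x@sampleId)

#' @rdname accessors
#' @param perGb logical; if \code{TRUE} abundances are depth-normalized to
#'   bp per Gb of sequenced read bp.
#' @export
setMethod("unitAbundance", "KmerSatProfile", function(x, perGb = FALSE, ...) {
  if (!perGb) return(x@unitBp)
  if (x@totalReadBp <= 0) stop("empty sample")
  x@unitBp * 1e9 / x@totalReadBp
})

setMethod("show", "KmerSatProfile", function(object) {
  cat("KmerSatProfile '", object@sampleId, "': ",
      length(object@unitBp), " unit(s), ",
      object@readsScanned, " reads (", object@totalReadBp, " bp)\n",
      sep = "")
  u <- sort(object@unitBp, decreasing = TRUE)
  for (i in seq_len(min(6L, length(u))))
    cat(sprintf("  %-20s %10.0f bp\n", names(u)[i], u[i]))
})
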