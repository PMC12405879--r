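#' Tandem array detector parameters
#'
#' Holds the filters and alignment scores of the tandem-array detector.
#' Defaults follow satellite-annotation practice for repeat units of
#' 20--500 bp present in arrays of at least 5 copies.
#'
#' @slot unitMin,unitMax integer, allowed repeat unit length range in bp.
#' @slot minCopies numeric, minimum tandem copy number (span / unit length).
#' @slot minIdentity numeric in (0,1], minimum mean per-copy identity to the
#'   array consensus.
#' @slot matchScore,mismatchScore,gapScore integer alignment scores used for
#'   array scoring.
#' @slot minArrayScore integer, minimum array alignment score.
#' @exportClass DetectorParams
setClass("DetectorParams", representation(
  unitMin = "integer", unitMax = "integer",
  minCopies = "numeric", minIdentity = "numeric",
  matchScore = "integer", mismatchScore = "integer", gapScore = "integer",
  minArrayScore = "integer"
))

setValidity("DetectorParams", function(object) {
  msg <- character()
  if (object@unitMin < 1L) msg <- c(msg, "unitMin must be >= 1")
  if (object@unitMax < object@unitMin)
    msg <- c(msg, "unitMax must be >= unitMin")
  if (object@minCopies < 2) msg <- c(msg, "minCopies must be >= 2")
  if (object@minIdentity <= 0 || object@minIdentity > 1)
    msg <- c(msg, "minIdentity must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct detector parameters
#'
#' @param unitMin,unitMax allowed unit length range in bp (defaults 20, 500).
#' @param minCopies minimum tandem copy count (default 5).
#' @param minIdentity minimum mean per-copy identity (default 0.8).
#' @param matchScore,mismatchScore,gapScore alignment scores (defaults
#'   +2/-3/-5).
#' @param minArrayScore minimum array score (default 50).
#' @return A \linkS4class{DetectorParams} object.
#' @examples
#' detectorParams(unitMin = 10, minCopies = 3)
#' @export
detectorParams <- function(unitMin = 20L, unitMax = 500L, minCopies = 5,
                           minIdentity = 0.8, matchScore = 2L,
                           mismatchScore = -3L, gapScore = -5L,
                           minArrayScore = 50L) {
  new("DetectorParams",
      unitMin = as.integer(unitMin), unitMax = as.integer(unitMax),
      minCopies = as.numeric(minCopies), minIdentity = as.numeric(minIdentity),
      matchScore = as.integer(matchScore),
      mismatchScore = as.integer(mismatchScore),
      gapScore = as.integer(gapScore),
      minArrayScore = as.integer(minArrayScore))
}

#' Satellite family set
#'
#' The result of clustering canonical monomers into satellite DNA families.
#' Families are ordered by decreasing total genomic weight (bp).
#'
#' @slot consensus \linkS4class{DNAStringSet} of family consensus monomers,
#'   named by family id.
#' @slot members \linkS4class{DataFrame} with one row per member monomer:
#'   \code{monomer} (canonical sequence), \code{family_id},
#'   \code{weight_bp}, \code{identity} (rotational identity to the family
#'   representative).
#' @slot variants \linkS4class{DataFrame} with one row per called sequence
#'   variant: \code{family_id}, \code{label} ("A", "B", ...),
#'   \code{consensus}, \code{share}, \code{diagnostic_positions}
#'   (comma-separated 1-based consensus coordinates).
#' @slot totalBp named numeric, summed member weight per family.
#' @exportClass SatelliteFamilySet
setClass("SatelliteFamilySet", representation(
  consensus = "DNAStringSet",
  members = "DataFrame",
  variants = "DataFrame",
  totalBp = "numeric"
))

setValidity("SatelliteFamilySet", function(object) {
  msg <- character()
  ids <- names(object@consensus)
  if (length(object@consensus) && is.null(ids))
    msg <- c(msg, "consensus sequences must be named by family id")
  if (!all(object@members$family_id %in% c(ids, NA_character_)))
    msg <- c(msg, "members reference unknown family ids")
  if (!identical(names(object@totalBp), ids))
    msg <- c(msg, "totalBp must be named identically to consensus")
  if (length(object@totalBp) && any(object@totalBp < 0))
    msg <- c(msg, "totalBp must be non-negative")
  if (nrow(object@variants) &&
      !all(object@variants$family_id %in% ids))
    msg <- c(msg, "variants reference unknown family ids")
  if (length(msg)) msg else TRUE
})

#' K-mer satellite profile of a read set
#'
#' Total bp attributed to each simple short satellite unit (canonical form)
#' across a set of unassembled reads.
#'
#' @slot sampleId character scalar.
#' @slot unitBp named numeric; names are canonical units (<= 20 bp,
#'   primitive), values are total bp covered by exact tandem runs.
#' @slot readsScanned numeric, number of reads scanned.
#' @slot totalReadBp numeric, total bp in the scanned reads.
#' @exportClass KmerSatProfile
setClass("KmerSatProfile", representation(
  sampleId = "character",
  unitBp = "numeric",
  readsScanned = "numeric",
  totalReadBp = "numeric"
))

setValidity("KmerSatProfile", function(object) {
  msg <- character()
  u <- names(object@unitBp)
  if (length(object@unitBp)) {
    if (is.null(u)) msg <- c(msg, "unitBp must be named by unit sequence")
    else {
      if (any(nchar(u) > 20L)) msg <- c(msg, "units must be <= 20 bp")
      if (any(object@unitBp > object@totalReadBp))
        msg <- c(msg, "a unit cannot exceed total read bp")
    }
  }
  if (object@totalReadBp < 0 || object@readsScanned < 0)
    msg <- c(msg, "read counters must be non-negative")
  if (length(msg)) msg else TRUE
})
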