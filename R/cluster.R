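# Greedy identity clustering of canonical monomers into satellite families,
# weighted consensus building, A/B variant calling and family naming.

#' Canonical monomers from detected arrays
#'
#' Canonicalizes each array's unit (rotation/strand standardization) and
#' aggregates identical canonical monomers, weighting each by the total bp
#' of the arrays that carry it.
#'
#' @param arrays array data.frame from [scanAssembly()] / [scanContig()].
#' @return \linkS4class{DataFrame} with columns \code{monomer} (canonical),
#'   \code{source_unit}, \code{rotation}, \code{strand}, \code{weight_bp},
#'   sorted by decreasing weight.
#' @export
monomersFromArrays <- function(arrays) {
  if (!nrow(arrays)) {
    return(S4Vectors::DataFrame(monomer = character(),
                                source_unit = character(),
                                rotation = integer(), strand = character(),
                                weight_bp = numeric()))
  }
  info <- lapply(arrays$unit_seq, canonicalInfo)
  df <- S4Vectors::DataFrame(
    monomer = vapply(info, `[[`, character(1), "seq"),
    source_unit = arrays$unit_seq,
    rotation = vapply(info, `[[`, integer(1), "rotation"),
    strand = vapply(info, `[[`, character(1), "strand"),
    weight_bp = as.numeric(arrays$end - arrays$start))
  agg <- tapply(df$weight_bp, df$monomer, sum)
  first <- !duplicated(df$monomer)
  df <- df[first, , drop = FALSE]
  df$weight_bp <- as.numeric(agg[df$monomer])
  df[order(-df$weight_bp, df$monomer), , drop = FALSE]
}

#' Greedy clustering of canonical monomers into satellite families
#'
#' cd-hit-style greedy incremental clustering: monomers are visited in
#' decreasing weight order; each joins the first existing family whose
#' representative it matches at \code{idThreshold} or better under
#' [rotationalIdentity()], otherwise it founds a new family with itself as
#' representative. Family consensi are then built by weighted per-column
#' majority ([buildConsensus()]) and families are ordered by decreasing
#' total bp.
#'
#' @param monomers \linkS4class{DataFrame} from [monomersFromArrays()], or a
#'   character vector of canonical monomers (unit weights).
#' @param idThreshold clustering identity threshold in [0.5, 1]
#'   (default 0.8).
#' @return A \linkS4class{SatelliteFamilySet} with provisional family ids
#'   ("F1", "F2", ... in decreasing total bp); use [nameFamilies()] to apply
#'   the (prefix)Sat-(unit length) convention.
#' @export
clusterMonomers <- function(monomers, idThreshold = 0.8) {
  if (is.character(monomers)) {
    monomers <- S4Vectors::DataFrame(monomer = monomers,
                                     weight_bp = rep(1, length(monomers)))
  }
  stopifnot(idThreshold >= 0.5, idThreshold <= 1)
  n <- nrow(monomers)
  if (!n) {
    return(new("SatelliteFamilySet",
               consensus = Biostrings::DNAStringSet(),
               members = S4Vectors::DataFrame(monomer = character(),
                                              family_id = character(),
                                              weight_bp = numeric(),
                                              identity = numeric()),
               variants = .emptyVariants(), totalBp = numeric()))
  }
  ord <- order(-monomers$weight_bp, monomers$monomer)
  monomers <- monomers[ord, , drop = FALSE]
  reps <- character()
  assign <- integer(n)
  ident <- numeric(n)
  for (i in seq_len(n)) {
    m <- monomers$monomer[i]
    placed <- FALSE
    for (f in seq_along(reps)) {
      idv <- .rotIdentityCapped(m, reps[f], idThreshold)
      if (idv >= idThreshold) {
        assign[i] <- f; ident[i] <- idv; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, m)
      assign[i] <- length(reps)
      ident[i] <- 1
    }
  }
  tot <- tapply(monomers$weight_bp, assign, sum)
  famOrd <- order(-as.numeric(tot), as.integer(names(tot)))
  newId <- integer(length(tot))
  newId[as.integer(names(tot))[famOrd]] <- seq_along(famOrd)
  ids <- paste0("F", newId[assign])

  members <- S4Vectors::DataFrame(monomer = monomers$monomer,
                                  family_id = ids,
                                  weight_bp = monomers$weight_bp,
                                  identity = ident)
  famIds <- paste0("F", seq_along(famOrd))
  consensus <- vapply(famIds, function(fid) {
    idx <- which(ids == fid)
    rep0 <- reps[assign[idx[1L]]]
    buildConsensus(monomers$monomer[idx], monomers$weight_bp[idx], rep0)
  }, character(1))
  totalBp <- as.numeric(tot)[match(famIds, paste0("F", newId[as.integer(names(tot))]))]
  names(totalBp) <- famIds
  cset <- Biostrings::DNAStringSet(consensus)
  names(cset) <- famIds
  new("SatelliteFamilySet", consensus = cset, members = members,
      variants = .emptyVariants(), totalBp = totalBp)
}

.emptyVariants <- function() {
  S4Vectors::DataFrame(family_id = character(), label = character(),
                       consensus = character(), share = numeric(),
                       diagnostic_positions = character())
}

#' Weighted consensus of a set of monomers
#'
#' Orients every member against the representative (best rotation/strand,
#' [bestOrientation()]), projects each onto the representative frame by
#' global alignment (member insertions dropped, deletions left uncounted)
#' and takes the weighted per-column majority; ties go to the earlier base
#' in A < C < G < T. The result is returned in canonical form.
#'
#' @param members character vector of member monomer sequences.
#' @param weights numeric weights (bp); default equal.
#' @param representative frame sequence; default the heaviest member.
#' @return Consensus DNA string (canonical), same length as the
#'   representative.
#' @export
buildConsensus <- function(members, weights = NULL, representative = NULL) {
  stopifnot(length(members) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(members))
  if (is.null(representative)) representative <- members[which.max(weights)]
  L <- nchar(representative)
  counts <- matrix(0, nrow = 4L, ncol = L)
  for (i in seq_along(members)) {
    ort <- if (members[i] == representative) representative
           else bestOrientation(representative, members[i])$seq
    proj <- .projectOnFrame(ort, representative)
    idx <- match(proj, c("A", "C", "G", "T"))
    ok <- !is.na(idx)
    counts[cbind(idx[ok], which(ok))] <-
      counts[cbind(idx[ok], which(ok))] + weights[i]
  }
  base <- c("A", "C", "G", "T")[apply(counts, 2L, which.max)]
  # columns never covered by any member fall back to the representative
  empty <- colSums(counts) == 0
  if (any(empty)) base[empty] <- strsplit(representative, "")[[1]][empty]
  canonicalMonomer(paste(base, collapse = ""))
}

# Align member (already oriented) to the frame and return one character per
# frame column ("-" where the member has a deletion).
.projectOnFrame <- function(member, frame) {
  if (member == frame) return(strsplit(member, "")[[1]])
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(member), Biostrings::DNAString(frame),
    type = "global", substitutionMatrix = .submat(),
    gapOpening = 5, gapExtension = 2)
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  pat[sub != "-"]
}

#' Call abundant sequence variants within a family
#'
#' Sub-clusters the family's members at a stricter identity threshold; if at
#' least two sub-clusters each hold at least \code{minShare} of the family's
#' total bp, those sub-clusters are reported as variants labelled "A", "B",
#' ... in decreasing share, each with its own consensus and the diagnostic
#' positions at which it differs from variant A.
#'
#' @param members character vector of member monomers.
#' @param weights numeric bp weights.
#' @param variantThreshold sub-clustering identity threshold (default 0.95).
#' @param minShare minimum share of family bp per variant (default 0.20).
#' @return \linkS4class{DataFrame} of variants (zero rows when the family
#'   has no variant structure).
#' @export
splitVariants <- function(members, weights = NULL, variantThreshold = 0.95,
                          minShare = 0.20) {
  if (is.null(weights)) weights <- rep(1, length(members))
  if (length(members) < 2L) return(.emptyVariants())
  sub <- clusterMonomers(
    S4Vectors::DataFrame(monomer = members, weight_bp = weights),
    idThreshold = variantThreshold)
  shares <- familyTotalBp(sub) / sum(weights)
  qual <- names(shares)[shares >= minShare]
  if (length(qual) < 2L) return(.emptyVariants())
  qual <- qual[order(-shares[qual], qual)]
  cons <- as.character(consensusSeqs(sub))[qual]
  labels <- LETTERS[seq_along(qual)]
  diag <- vapply(seq_along(qual), function(i) {
    if (i == 1L) return("")
    paste(.diagnosticPositions(cons[1L], cons[i]), collapse = ",")
  }, character(1))
  S4Vectors::DataFrame(family_id = rep(NA_character_, length(qual)),
                       label = labels, consensus = unname(cons),
                       share = unname(as.numeric(shares[qual])),
                       diagnostic_positions = diag)
}

# 1-based positions (frame of `a`) at which the oriented form of `b`
# differs from `a`.
.diagnosticPositions <- function(a, b) {
  ort <- bestOrientation(a, b)$seq
  proj <- .projectOnFrame(ort, a)
  av <- strsplit(a, "")[[1]]
  which(proj != av)
}

#' Detect variants for every family in a set
#'
#' Applies [splitVariants()] to each family with two or more members and
#' stores the results in the \code{variants} slot.
#'
#' @param set a \linkS4class{SatelliteFamilySet}.
#' @inheritParams splitVariants
#' @return The updated \linkS4class{SatelliteFamilySet}.
#' @export
detectVariants <- function(set, variantThreshold = 0.95, minShare = 0.20) {
  out <- list()
  for (fid in familyIds(set)) {
    idx <- which(set@members$family_id == fid)
    if (length(idx) < 2L) next
    v <- splitVariants(set@members$monomer[idx], set@members$weight_bp[idx],
                       variantThreshold, minShare)
    if (nrow(v)) { v$family_id <- fid; out[[fid]] <- v }
  }
  set@variants <- if (length(out)) do.call(rbind, out) else .emptyVariants()
  methods::validObject(set)
  set
}

#' Name a satellite family
#'
#' Applies the (species prefix)Sat-(unit length) convention, e.g.
#' "BcopSat-145" for a 145 bp unit. On collision with an already-taken name
#' a lowercase letter suffix is appended ("-155b", "-155c", ...).
#'
#' @param speciesPrefix species abbreviation, e.g. "Bcop".
#' @param unitLen consensus unit length in bp.
#' @param taken character vector of names already in use.
#' @return The family name.
#' @examples
#' nameFamily("Bcop", 145)                      # "BcopSat-145"
#' nameFamily("Bcop", 155, "BcopSat-155")       # "BcopSat-155b"
#' @export
nameFamily <- function(speciesPrefix, unitLen, taken = character()) {
  stopifnot(unitLen >= 1)
  base <- paste0(speciesPrefix, "Sat-", unitLen)
  if (!(base %in% taken)) return(base)
  for (sfx in letters[-1]) {
    cand <- paste0(base, sfx)
    if (!(cand %in% taken)) return(cand)
  }
  stop("name space exhausted for ", base)
}

#' Apply the naming convention to a family set
#'
#' Renames families (in their stored order, i.e. decreasing total bp) to
#' (prefix)Sat-(consensus length), resolving collisions with letter
#' suffixes.
#'
#' @param set a \linkS4class{SatelliteFamilySet}.
#' @param speciesPrefix species abbreviation (default "Bcop").
#' @return The renamed \linkS4class{SatelliteFamilySet}.
#' @export
nameFamilies <- function(set, speciesPrefix = "Bcop") {
  old <- familyIds(set)
  taken <- character()
  for (i in seq_along(old)) {
    nm <- nameFamily(speciesPrefix, length(set@consensus[[i]]), taken)
    taken <- c(taken, nm)
  }
  names(set@consensus) <- taken
  names(set@totalBp) <- taken
  set@members$family_id <- taken[match(set@members$family_id, old)]
  if (nrow(set@variants))
    set@variants$family_id <- taken[match(set@variants$family_id, old)]
  methods::validObject(set)
  set
}
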