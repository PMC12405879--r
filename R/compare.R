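# Cross-assembly family matching and restricted/enriched family flagging
# (the germline-restricted chromosome logic).

#' Match satellite families across two assemblies
#'
#' Greedy best-first bipartite matching of family consensi on
#' [rotationalIdentity()]: pairs are taken in decreasing identity (ties by
#' family ids), each family participates in at most one match, pairs below
#' \code{matchThreshold} are never matched. Unmatched families are reported
#' as \code{a_only} / \code{b_only}.
#'
#' @param familiesA,familiesB \linkS4class{SatelliteFamilySet} objects.
#' @param matchThreshold minimum identity for a match (default 0.8).
#' @param abundanceA,abundanceB optional named numeric vectors of total kb
#'   per family id (e.g. from [familyAbundance()]); families absent from the
#'   vector get 0 kb.
#' @return data.frame with columns \code{family_a_id, family_b_id,
#'   identity, abundance_a_kb, abundance_b_kb, ratio_b_over_a, status}
#'   (status one of shared / a_only / b_only). The ratio uses a +1 kb
#'   pseudocount on both sides so it is always finite and positive.
#' @export
matchFamilies <- function(familiesA, familiesB, matchThreshold = 0.8,
                          abundanceA = NULL, abundanceB = NULL) {
  idsA <- familyIds(familiesA)
  idsB <- familyIds(familiesB)
  consA <- as.character(consensusSeqs(familiesA))
  consB <- as.character(consensusSeqs(familiesB))
  pairs <- expand.grid(a = seq_along(idsA), b = seq_along(idsB))
  if (nrow(pairs)) {
    pairs$identity <- mapply(function(i, j)
      .rotIdentityCapped(consA[i], consB[j], matchThreshold),
      pairs$a, pairs$b)
    pairs <- pairs[pairs$identity >= matchThreshold, , drop = FALSE]
    pairs <- pairs[order(-pairs$identity, idsA[pairs$a], idsB[pairs$b]), ,
                   drop = FALSE]
  }
  usedA <- logical(length(idsA)); usedB <- logical(length(idsB))
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]; b <- pairs$b[i]
    if (usedA[a] || usedB[b]) next
    usedA[a] <- TRUE; usedB[b] <- TRUE
    rows[[length(rows) + 1L]] <-
      data.frame(family_a_id = idsA[a], family_b_id = idsB[b],
                 identity = pairs$identity[i], status = "shared",
                 stringsAsFactors = FALSE)
  }
  for (a in which(!usedA))
    rows[[length(rows) + 1L]] <-
      data.frame(family_a_id = idsA[a], family_b_id = NA_character_,
                 identity = NA_real_, status = "a_only",
                 stringsAsFactors = FALSE)
  for (b in which(!usedB))
    rows[[length(rows) + 1L]] <-
      data.frame(family_a_id = NA_character_, family_b_id = idsB[b],
                 identity = NA_real_, status = "b_only",
                 stringsAsFactors = FALSE)
  m <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_a_id = character(), family_b_id = character(),
               identity = numeric(), status = character(),
               stringsAsFactors = FALSE)
  lookup <- function(x, tab) {
    v <- rep(0, length(x))
    if (!is.null(tab)) {
      hit <- match(x, names(tab))
      v[!is.na(hit)] <- as.numeric(tab[hit[!is.na(hit)]])
    }
    v[is.na(x)] <- 0
    v
  }
  m$abundance_a_kb <- lookup(m$family_a_id, abundanceA)
  m$abundance_b_kb <- lookup(m$family_b_id, abundanceB)
  m$ratio_b_over_a <- (m$abundance_b_kb + 1) / (m$abundance_a_kb + 1)
  rownames(m) <- NULL
  m[, c("family_a_id", "family_b_id", "identity", "abundance_a_kb",
        "abundance_b_kb", "ratio_b_over_a", "status")]
}

#' Flag families restricted to or enriched in one assembly
#'
#' Operationalizes "at very low abundance or absent in the other assembly":
#' families private to side \code{b} with abundance at least \code{minKb}
#' are flagged as restricted, and shared families whose b/a abundance ratio
#' (pseudocounted) is at least \code{ratioMin} are flagged as
#' \code{b_enriched}. Use \code{side = "a"} for the symmetric operation.
#'
#' @param matches data.frame from [matchFamilies()].
#' @param minKb abundance floor in kb (default 200).
#' @param ratioMin enrichment ratio floor (default 5).
#' @param side which assembly to flag candidates for ("b", the default, or
#'   "a").
#' @return Subset of \code{matches} with status \code{b_only} /
#'   \code{b_enriched} (or the \code{a} equivalents).
#' @export
flagRestricted <- function(matches, minKb = 200, ratioMin = 5, side = "b") {
  side <- match.arg(side, c("a", "b"))
  if (side == "b") {
    only <- matches$status == "b_only" & matches$abundance_b_kb >= minKb
    enr <- matches$status == "shared" & matches$ratio_b_over_a >= ratioMin &
      matches$abundance_b_kb >= minKb
    out <- matches[only | enr, , drop = FALSE]
    out$status[out$status == "shared"] <- "b_enriched"
  } else {
    ratioA <- (matches$abundance_a_kb + 1) / (matches$abundance_b_kb + 1)
    only <- matches$status == "a_only" & matches$abundance_a_kb >= minKb
    enr <- matches$status == "shared" & ratioA >= ratioMin &
      matches$abundance_a_kb >= minKb
    out <- matches[only | enr, , drop = FALSE]
    out$status[out$status == "shared"] <- "a_enriched"
  }
  rownames(out) <- NULL
  out
}
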