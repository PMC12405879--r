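# Tandem array detection: k-mer recurrence-distance seeding followed by
# jittered fixed-stride extension against a running consensus unit.
# Coordinates are 0-based half-open on the forward strand throughout.

.ARRAY_COLS <- c("contig", "start", "end", "unit_len", "copies",
                 "mean_identity", "score", "unit_seq")

.emptyArrays <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             unit_len = integer(), copies = numeric(),
             mean_identity = numeric(), score = numeric(),
             unit_seq = character(), stringsAsFactors = FALSE)
}

# Split a byte vector into maximal ACGT segments (N or other bytes break).
.acgtSegments <- function(b) {
  ok <- b %in% .DNA_BYTES
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(i) c(starts[i], ends[i]))
}

# Seed candidate (start, period) pairs inside one ACGT segment by locating,
# for each k-mer position, the distance to the next occurrence of the same
# k-mer, then grouping positions that repeat at a consistent distance.
.seedCandidates <- function(b, params, k = 10L) {
  n <- length(b)
  k <- max(2L, min(k, n %/% 2L))
  np <- n - k + 1L
  if (np < 2L) return(NULL)
  v <- as.integer(match(b, .DNA_BYTES)) - 1L
  code <- v[seq_len(np)]
  for (j in 2:k) code <- code * 4 + v[j:(np + j - 1L)]
  o <- order(code, seq_len(np))
  cs <- code[o]
  same <- diff(cs) == 0
  d <- diff(o)
  keep <- same & d >= 2L & d <= params@unitMax
  if (!any(keep)) return(NULL)
  pos <- o[-length(o)][keep]
  dd <- d[keep]
  ord <- order(pos)
  pos <- pos[ord]; dd <- dd[ord]

  cands <- list()
  covered <- IRanges::IRanges()
  for (p in sort(unique(dd))) {
    ps <- pos[dd == p]
    if (length(ps) < 2L) next
    grp <- cumsum(c(TRUE, diff(ps) > p + k))
    for (g in split(ps, grp)) {
      span <- g[length(g)] - g[1L] + p + k - 1L
      if (length(g) < 2L || span < params@minCopies * p * 0.7) next
      rng <- IRanges::IRanges(g[1L], g[1L] + span - 1L)
      ov <- IRanges::intersect(rng, covered)
      if (sum(IRanges::width(ov)) >= 0.8 * IRanges::width(rng)) next
      covered <- IRanges::reduce(c(covered, rng))
      cands[[length(cands) + 1L]] <- c(start = g[1L], period = p)
    }
  }
  cands
}

# Per-column weighted majority over a matrix of byte codes 1..4 (rows =
# copies); ties resolved toward the earlier base in A < C < G < T.
.columnMajority <- function(m, weights = NULL) {
  if (is.null(weights)) weights <- rep.int(1, nrow(m))
  tally <- vapply(1:4, function(x) colSums((m == x) * weights), numeric(ncol(m)))
  if (is.null(dim(tally))) tally <- matrix(tally, nrow = 1L)
  .DNA_BYTES[max.col(tally, ties.method = "first")]
}

# Extend a seed unit left/right from an anchor with a fixed stride and a
# small jitter (+/- 2 bp) to absorb occasional indels. Returns copy start
# positions and per-copy identities to the unit, or NULL.
.extendArray <- function(b, anchor, unit, minIdentity) {
  p <- length(unit)
  n <- length(b)
  jit <- if (p >= 8L) c(-1L, 1L, -2L, 2L) else integer(0)
  fastBar <- max(minIdentity, 1 - 2 / p, 0.92)
  stepFrom <- function(cur, dir) {
    starts <- integer(256L); ids <- numeric(256L); k <- 0L
    repeat {
      target <- cur + dir * p
      bestId <- -1; bestS <- NA_integer_
      if (target >= 1L && target + p - 1L <= n) {
        bestId <- sum(b[target:(target + p - 1L)] == unit) / p
        bestS <- target
      }
      # explore small offsets only when the in-phase window is imperfect
      if (bestId < fastBar) {
        for (off in jit) {
          s0 <- target + off
          if (s0 < 1L || s0 + p - 1L > n) next
          idv <- sum(b[s0:(s0 + p - 1L)] == unit) / p
          if (idv > bestId) { bestId <- idv; bestS <- s0 }
        }
      }
      if (is.na(bestS) || bestId < minIdentity) break
      k <- k + 1L
      if (k > length(starts)) {
        length(starts) <- 2L * length(starts)
        length(ids) <- 2L * length(ids)
      }
      starts[k] <- bestS; ids[k] <- bestId
      cur <- bestS
    }
    list(starts = starts[seq_len(k)], ids = ids[seq_len(k)])
  }
  if (anchor + p - 1L > n) return(NULL)
  a0 <- sum(b[anchor:(anchor + p - 1L)] == unit) / p
  if (a0 < minIdentity) return(NULL)
  r <- stepFrom(anchor, +1L)
  l <- stepFrom(anchor, -1L)
  list(starts = c(rev(l$starts), anchor, r$starts),
       ids = c(rev(l$ids), a0, r$ids))
}

#' Refine a tandem array around a seed
#'
#' Given a seed position and seed unit inside a contig, extends the array
#' left and right while per-copy identity to the running consensus stays at
#' or above \code{minIdentity} (small indels absorbed by a +/- 2 bp jitter),
#' rebuilds the consensus unit by per-column majority over the copies, and
#' re-extends once with the improved consensus.
#'
#' @param contigSeq contig DNA string (A/C/G/T only in the scanned region).
#' @param seedStart 1-based seed position within \code{contigSeq}.
#' @param seedUnit seed unit string.
#' @param params a \linkS4class{DetectorParams}.
#' @return One-row array data.frame (0-based half-open coordinates) or
#'   \code{NULL} if no extension reaches 2 copies.
#' @export
refineArray <- function(contigSeq, seedStart, seedUnit, params = detectorParams()) {
  b <- charToRaw(toupper(contigSeq))
  res <- .refineArrayBytes(b, as.integer(seedStart), charToRaw(toupper(seedUnit)),
                           params)
  if (is.null(res)) return(NULL)
  res$contig <- "contig"
  res[, .ARRAY_COLS]
}

.refineArrayBytes <- function(b, seedStart, unit, params, depth = 0L) {
  # reduce a non-primitive seed unit to its tandem root
  pp <- primitivePeriod(rawToChar(unit))
  if (pp < length(unit)) unit <- unit[seq_len(pp)]
  p <- length(unit)
  ext <- .extendArray(b, seedStart, unit, params@minIdentity)
  if (is.null(ext) || length(ext$starts) < 2L) return(NULL)

  # consensus rebuild from full copies, then one re-extension pass
  m <- matrix(0L, nrow = length(ext$starts), ncol = p)
  for (i in seq_along(ext$starts)) {
    s0 <- ext$starts[i]
    m[i, ] <- as.integer(match(b[s0:(s0 + p - 1L)], .DNA_BYTES))
  }
  cons <- .columnMajority(m)
  ccp <- primitivePeriod(rawToChar(cons))
  if (ccp < p && depth < 2L) {
    anchor <- ext$starts[which.max(ext$ids)]
    return(.refineArrayBytes(b, anchor, cons[seq_len(ccp)], params, depth + 1L))
  }
  anchor <- ext$starts[which.max(ext$ids)]
  ext <- .extendArray(b, anchor, cons, params@minIdentity)
  if (is.null(ext) || length(ext$starts) < 2L) return(NULL)

  start1 <- ext$starts[1L]
  end1 <- ext$starts[length(ext$starts)] + p - 1L
  nMatch <- round(ext$ids * p)
  jitterGaps <- abs(diff(ext$starts) - p)
  score <- sum(nMatch) * params@matchScore +
    sum(p - nMatch) * params@mismatchScore +
    sum(jitterGaps) * abs(params@gapScore) * -1
  data.frame(start = start1 - 1L, end = end1,
             unit_len = p,
             copies = (end1 - start1 + 1L) / p,
             mean_identity = mean(ext$ids),
             score = score,
             unit_seq = rawToChar(cons),
             stringsAsFactors = FALSE)
}

# Keep the best array among mutually overlapping candidates: higher score,
# then smaller unit length, then leftmost.
.resolveOverlaps <- function(arr) {
  if (nrow(arr) <= 1L) return(arr)
  ord <- order(-arr$score, arr$unit_len, arr$start)
  arr <- arr[ord, , drop = FALSE]
  kept <- IRanges::IRanges()
  keep <- logical(nrow(arr))
  for (i in seq_len(nrow(arr))) {
    rng <- IRanges::IRanges(arr$start[i] + 1L, arr$end[i])
    if (sum(IRanges::width(IRanges::intersect(rng, kept))) == 0L) {
      keep[i] <- TRUE
      kept <- IRanges::reduce(c(kept, rng))
    }
  }
  arr <- arr[keep, , drop = FALSE]
  arr[order(arr$start), , drop = FALSE]
}

#' Scan one contig for tandem arrays
#'
#' Detects tandem repeat arrays by k-mer recurrence-distance seeding within
#' maximal A/C/G/T segments (runs of N split the scan), refines each seed
#' with [refineArray()], resolves overlaps (higher score, then smaller unit,
#' then leftmost) and applies the unit-length, copy-number, identity and
#' score filters.
#'
#' @param contigSeq contig DNA string (case-insensitive; N allowed).
#' @param params a \linkS4class{DetectorParams}.
#' @param contigId contig name used in the output.
#' @return data.frame of arrays with columns \code{contig, start, end,
#'   unit_len, copies, mean_identity, score, unit_seq}; coordinates 0-based
#'   half-open. Empty for contigs shorter than twice the minimum unit.
#' @examples
#' ctg <- paste0(strrep("ACGTT", 8), strrep("AAAACGTATT", 12))
#' scanContig(ctg, detectorParams(unitMin = 5, minCopies = 5))
#' @export
scanContig <- function(contigSeq, params = detectorParams(),
                       contigId = "contig") {
  s <- toupper(contigSeq)
  if (nchar(s) < 2L * params@unitMin) return(.emptyArrays())
  b <- charToRaw(s)
  out <- list()
  for (seg in .acgtSegments(b)) {
    sb <- b[seg[1L]:seg[2L]]
    if (length(sb) < 2L * max(2L, params@unitMin)) next
    cands <- .seedCandidates(sb, params)
    claimed <- IRanges::IRanges()
    for (cd in cands) {
      # skip seeds already explained by a refined array
      sr <- IRanges::IRanges(cd["start"],
                             min(cd["start"] + 2L * cd["period"], length(sb)))
      if (sum(IRanges::width(IRanges::intersect(sr, claimed))) >=
          0.9 * IRanges::width(sr)) next
      unit <- sb[cd["start"]:(cd["start"] + cd["period"] - 1L)]
      a <- .refineArrayBytes(sb, cd["start"], unit, params)
      if (!is.null(a)) {
        claimed <- IRanges::reduce(c(claimed,
                                     IRanges::IRanges(a$start + 1L, a$end)))
        a$start <- a$start + seg[1L] - 1L
        a$end <- a$end + seg[1L] - 1L
        out[[length(out) + 1L]] <- a
      }
    }
  }
  if (!length(out)) return(.emptyArrays())
  arr <- do.call(rbind, out)
  arr <- arr[!duplicated(arr[, c("start", "end", "unit_len")]), , drop = FALSE]
  arr <- .resolveOverlaps(arr)
  arr$contig <- contigId
  arr <- arr[arr$mean_identity >= params@minIdentity &
               arr$score >= params@minArrayScore, , drop = FALSE]
  arr <- filterArrays(arr[, .ARRAY_COLS], params)
  rownames(arr) <- NULL
  arr
}

#' Filter arrays by copy number and unit length
#'
#' Keeps arrays with \code{copies >= minCopies} and unit length within
#' \code{[unitMin, unitMax]} (boundaries inclusive); output is ordered by
#' (contig, start).
#'
#' @param arrays array data.frame as returned by [scanContig()].
#' @param params a \linkS4class{DetectorParams}.
#' @return Filtered array data.frame.
#' @export
filterArrays <- function(arrays, params = detectorParams()) {
  if (!nrow(arrays)) return(.emptyArrays())
  keep <- arrays$copies >= params@minCopies &
    arrays$unit_len >= params@unitMin & arrays$unit_len <= params@unitMax
  arr <- arrays[keep, , drop = FALSE]
  arr <- arr[order(arr$contig, arr$start), , drop = FALSE]
  rownames(arr) <- NULL
  arr
}

#' Scan a whole assembly for tandem arrays
#'
#' @param assembly a named \linkS4class{DNAStringSet}, a named character
#'   vector of contig sequences, or a path to a FASTA file.
#' @param params a \linkS4class{DetectorParams}.
#' @return Combined array data.frame over all contigs (see [scanContig()]).
#' @export
scanAssembly <- function(assembly, params = detectorParams()) {
  seqs <- .asContigSet(assembly)
  out <- lapply(names(seqs), function(nm)
    scanContig(seqs[[nm]], params, contigId = nm))
  arr <- do.call(rbind, c(list(.emptyArrays()), out))
  rownames(arr) <- NULL
  arr
}

# Normalize assembly input to a named character vector of contig strings.
.asContigSet <- function(assembly) {
  if (is.character(assembly) && length(assembly) == 1L &&
      file.exists(assembly) && !grepl("^[ACGTNacgtn]+$", assembly)) {
    x <- Biostrings::readDNAStringSet(assembly)
    if (!length(x)) stop("no sequences in FASTA: ", assembly)
    assembly <- x
  }
  if (methods::is(assembly, "DNAStringSet")) {
    seqs <- as.character(assembly)
  } else if (is.character(assembly)) {
    seqs <- assembly
  } else stop("unsupported assembly input")
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- paste0("contig", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  toupper(seqs)
}
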