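# FISH oligo probe design: conserved per-family probes and
# variant-discriminating probe pairs, plus an in-silico hit map.

.maxHomopolymer <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  max(r$lengths)
}

# Minimum Hamming distance of `probe` against every offset of `target`
# treated as a circular tandem template, on both strands.
.minTandemMismatch <- function(probe, target) {
  m <- nchar(probe)
  reps <- ceiling(m / nchar(target)) + 1L
  tmpl <- strrep(target, reps)
  min(min(.hammingScan(probe, tmpl)),
      min(.hammingScan(.revcomp(probe), tmpl)))
}

# Hamming mismatch counts of `probe` at every start of `seq` (no indels).
.hammingScan <- function(probe, seq) {
  pb <- charToRaw(toupper(probe))
  sb <- charToRaw(toupper(seq))
  m <- length(pb)
  npos <- length(sb) - m + 1L
  if (npos < 1L) return(integer(0))
  mm <- integer(npos)
  for (j in seq_len(m))
    mm <- mm + (sb[j:(j + npos - 1L)] != pb[j])
  mm
}

# All circular windows of the consensus with lengths in lenRange that pass
# the GC and homopolymer constraints. Returns data.frame(start, len, seq).
.probeWindows <- function(consensus, lenRange, gcRange, maxHomo = 8L) {
  L <- nchar(consensus)
  tmpl <- strrep(consensus, ceiling((L + max(lenRange)) / L))
  grid <- expand.grid(len = seq(lenRange[1], lenRange[2]),
                      start = seq_len(L))
  grid <- grid[order(grid$start, grid$len), , drop = FALSE]
  seqs <- substr(rep(tmpl, nrow(grid)), grid$start,
                 grid$start + grid$len - 1L)
  gc <- vapply(seqs, gcContent, numeric(1), USE.NAMES = FALSE)
  homo <- vapply(seqs, .maxHomopolymer, numeric(1), USE.NAMES = FALSE)
  ok <- gc >= gcRange[1] & gc <= gcRange[2] & homo <= maxHomo
  data.frame(start = grid$start[ok], len = grid$len[ok], seq = seqs[ok],
             gc = gc[ok], stringsAsFactors = FALSE)
}

.probeRow <- function(seq, familyId, variantLabel, start, onMM, offMM) {
  data.frame(family_id = familyId, variant_label = variantLabel,
             probe_seq = seq, start = start, length = nchar(seq),
             gc = gcContent(seq),
             on_target_max_mismatch = onMM,
             off_target_min_mismatch = offMM,
             stringsAsFactors = FALSE)
}

#' Design a conserved probe for a satellite family
#'
#' Chooses the 30--40-mer window of the (circular) family consensus that
#' minimizes the worst-case mismatch count against any member monomer
#' (each member treated as a circular tandem template, both strands); ties
#' go to the higher-entropy window, then the leftmost, then the shorter.
#' For units shorter than the probe the window runs over concatenated
#' tandem copies of the unit, so e.g. a 10 bp unit yields a 30 nt probe of
#' three exact copies.
#'
#' @param consensus family consensus monomer.
#' @param members character vector of member monomers (default: the
#'   consensus itself).
#' @param lenRange probe length range in nt (default c(30, 40)).
#' @param gcRange allowed GC fraction range (default c(0.15, 0.65)).
#' @param familyId family id recorded in the output.
#' @return One-row probe data.frame (see [probeSheet] columns).
#' @export
designFamilyProbe <- function(consensus, members = consensus,
                              lenRange = c(30L, 40L),
                              gcRange = c(0.15, 0.65),
                              familyId = NA_character_) {
  L <- nchar(consensus)
  if (L < lenRange[1]) {
    # short units: probe is the smallest whole-copy concatemer that reaches
    # the length range (e.g. 3 exact copies of a 10 bp unit); only when no
    # whole multiple fits does the general window search take over
    m <- ceiling(lenRange[1] / L) * L
    if (m <= lenRange[2]) lenRange <- c(m, m)
  }
  win <- .probeWindows(consensus, lenRange, gcRange)
  if (!nrow(win)) stop("no feasible probe")
  maxMM <- vapply(win$seq, function(w)
    max(vapply(members, function(m) .minTandemMismatch(w, m), numeric(1))),
    numeric(1), USE.NAMES = FALSE)
  ent <- vapply(win$seq, sequenceEntropy, numeric(1), USE.NAMES = FALSE)
  ord <- order(maxMM, -ent, win$start, win$len)
  i <- ord[1L]
  .probeRow(win$seq[i], familyId, NA_character_, win$start[i],
            onMM = maxMM[i], offMM = NA_real_)
}

#' Design variant-discriminating probe pairs
#'
#' For each of two rotationally aligned variant consensi, selects the
#' constrained window maximizing the minimum mismatch count to the sister
#' variant (sister treated as a circular tandem template, both strands;
#' ties to the leftmost window). Errors if no window reaches
#' \code{minDiscrimination} mismatches.
#'
#' @param variantA,variantB variant consensus sequences.
#' @param lenRange,gcRange as in [designFamilyProbe()].
#' @param minDiscrimination minimum cross-variant mismatches (default 3,
#'   the discrimination observed for published 37 bp A/B probes).
#' @param familyId family id recorded in the output.
#' @return Two-row probe data.frame (variant labels "A" and "B") with
#'   \code{off_target_min_mismatch} holding the cross-variant mismatch
#'   count.
#' @export
designVariantProbes <- function(variantA, variantB, lenRange = c(30L, 40L),
                                gcRange = c(0.15, 0.65),
                                minDiscrimination = 3L,
                                familyId = NA_character_) {
  ortB <- bestOrientation(variantA, variantB)$seq
  pick <- function(own, sister, label) {
    win <- .probeWindows(own, lenRange, gcRange)
    if (!nrow(win)) stop("no feasible probe for variant ", label)
    offMM <- vapply(win$seq, .minTandemMismatch, numeric(1), sister,
                    USE.NAMES = FALSE)
    ord <- order(-offMM, win$start, win$len)
    i <- ord[1L]
    if (offMM[i] < minDiscrimination)
      stop("variants not discriminable at requested floor")
    onMM <- .minTandemMismatch(win$seq[i], own)
    .probeRow(win$seq[i], familyId, label, win$start[i], onMM, offMM[i])
  }
  rbind(pick(variantA, ortB, "A"), pick(ortB, variantA, "B"))
}

#' Map probe hits on a set of sequences
#'
#' Sliding-window Hamming search (no indels) for the probe on both strands
#' of each sequence.
#'
#' @param probe probe sequence (30--40 nt).
#' @param sequences named character vector or \linkS4class{DNAStringSet}.
#' @param maxMismatch maximum mismatches reported.
#' @return data.frame with \code{seq_id}, \code{position} (1-based, on the
#'   forward strand), \code{strand}, \code{mismatches}.
#' @export
probeHitMap <- function(probe, sequences, maxMismatch = 0L) {
  stopifnot(nchar(probe) >= 30L, nchar(probe) <= 40L)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  rows <- list()
  rc <- .revcomp(probe)
  for (nm in names(sequences)) {
    for (str in c("+", "-")) {
      p <- if (str == "+") probe else rc
      mm <- .hammingScan(p, sequences[[nm]])
      hit <- which(mm <= maxMismatch)
      if (length(hit))
        rows[[length(rows) + 1L]] <-
          data.frame(seq_id = nm, position = hit, strand = str,
                     mismatches = mm[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(seq_id = character(), position = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$seq_id, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate oligo probe sequences
#'
#' Checks the probe constraints: length within \code{lenRange}, pure
#' A/C/G/T alphabet, no homopolymer run longer than \code{maxHomopolymer}.
#'
#' @param probeSeqs character vector of probe sequences.
#' @param lenRange allowed length range (default c(30, 40)).
#' @param maxHomopolymer maximum homopolymer run (default 8).
#' @return data.frame with \code{probe_seq, length, gc, max_homopolymer,
#'   valid} (and per-check logical columns).
#' @export
validateProbes <- function(probeSeqs, lenRange = c(30L, 40L),
                           maxHomopolymer = 8L) {
  len <- nchar(probeSeqs)
  alpha <- grepl("^[ACGT]+$", toupper(probeSeqs))
  homo <- vapply(toupper(probeSeqs), .maxHomopolymer, numeric(1),
                 USE.NAMES = FALSE)
  gc <- rep(NA_real_, length(probeSeqs))
  gc[alpha] <- vapply(toupper(probeSeqs[alpha]), gcContent, numeric(1),
                      USE.NAMES = FALSE)
  data.frame(probe_seq = probeSeqs, length = len, gc = gc,
             max_homopolymer = homo,
             length_ok = len >= lenRange[1] & len <= lenRange[2],
             alphabet_ok = alpha,
             homopolymer_ok = homo <= maxHomopolymer,
             valid = len >= lenRange[1] & len <= lenRange[2] & alpha &
               homo <= maxHomopolymer,
             stringsAsFactors = FALSE)
}

#' Published satellite probe set of Bradysia coprophila
#'
#' Loads the published oligo probe/monomer sequences for the abundant core
#' satellite families (BcopSat-145 ... BcopSat-94) and the three
#' L-chromosome-enriched families (BcopSat-10/-38/-39), shipped as a
#' plain-text fixture. For BcopSat-37 the probe equals one full monomer;
#' for BcopSat-10 the probe is three exact tandem copies of the 10 bp unit.
#'
#' @return data.frame with \code{family}, \code{variant}, \code{unit_len},
#'   \code{probe_seq}.
#' @export
bcopSatProbes <- function() {
  path <- system.file("extdata", "bcop_sat_probes.tsv", package = "satmine",
                      mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "#", colClasses = "character")
}
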