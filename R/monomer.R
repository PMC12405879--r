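# Monomer-level string operations: primitive period, canonical rotation /
# strand standardization, and rotation/strand-invariant identity.

.DNA_BYTES <- charToRaw("ACGT")

.checkDNA <- function(seq, allowN = FALSE, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("empty input: ", what, " must be a non-empty DNA string")
  s <- toupper(seq)
  ok <- if (allowN) grepl("^[ACGTN]+$", s) else grepl("^[ACGT]+$", s)
  if (!ok) stop(what, " contains characters outside the ",
                if (allowN) "ACGTN" else "ACGT", " alphabet")
  s
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Primitive (fundamental) period of a DNA string
#'
#' Returns the length of the fundamental tandem unit of \code{seq}: the
#' smallest \code{p} dividing \code{nchar(seq)} such that \code{seq} is an
#' exact tandem expansion of its first \code{p} bases. A primitive string
#' returns its own length. Computed from the Knuth-Morris-Pratt failure
#' function.
#'
#' @param seq a non-empty DNA string over A/C/G/T/N.
#' @return Integer period in bp.
#' @examples
#' primitivePeriod("ACACACAC")  # 2
#' primitivePeriod("ACGTA")     # 5 (primitive)
#' @export
primitivePeriod <- function(seq) {
  s <- .checkDNA(seq, allowN = TRUE)
  b <- charToRaw(s)
  n <- length(b)
  if (n == 1L) return(1L)
  f <- integer(n)
  k <- 0L
  for (i in 2:n) {
    while (k > 0L && b[i] != b[k + 1L]) k <- f[k]
    if (b[i] == b[k + 1L]) k <- k + 1L
    f[i] <- k
  }
  p <- n - f[n]
  if (n %% p == 0L) p else n
}

# Booth's least-rotation algorithm on a byte vector; returns the 1-based
# start of the lexicographically least rotation.
.leastRotationStart <- function(b) {
  n <- length(b)
  s <- c(b, b)
  f <- rep.int(-1L, 2L * n)
  k <- 0L  # 0-based candidate start
  for (j in 1L:(2L * n - 1L)) {        # 0-based j over s[1..2n-1]
    sj <- s[j + 1L]
    i <- f[j - k]                       # f is 0-based via offset +1 below
    while (i != -1L && sj != s[k + i + 2L]) {
      if (sj < s[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != s[k + i + 2L]) {          # i == -1 here
      if (sj < s[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  k + 1L
}

#' Canonical monomer under rotation and reverse complement
#'
#' Standardizes a repeat monomer to the unique representative of its
#' equivalence class under cyclic rotation and reverse complement: the
#' lexicographically smallest string (alphabet order A < C < G < T) among
#' all rotations of the input and all rotations of its reverse complement.
#' Idempotent; output length equals input length.
#'
#' @param seq a non-empty DNA string over A/C/G/T.
#' @return The canonical monomer string.
#' @seealso [canonicalInfo()] for the rotation offset and strand chosen.
#' @examples
#' canonicalMonomer("GTATTAAAAC") == canonicalMonomer("AAAACGTATT")
#' @export
canonicalMonomer <- function(seq) canonicalInfo(seq)$seq

#' Canonicalization details for a monomer
#'
#' As [canonicalMonomer()] but also reports which rotation and strand
#' produced the canonical form.
#'
#' @inheritParams canonicalMonomer
#' @return A list with \code{seq} (canonical string), \code{rotation}
#'   (0-based offset into the chosen strand's sequence) and \code{strand}
#'   (\code{"+"} if the canonical form is a rotation of the input,
#'   \code{"-"} if of its reverse complement).
#' @export
canonicalInfo <- function(seq) {
  s <- .checkDNA(seq)
  rc <- .revcomp(s)
  bf <- charToRaw(s)
  br <- charToRaw(rc)
  n <- length(bf)
  kf <- .leastRotationStart(bf)
  kr <- .leastRotationStart(br)
  rotf <- rawToChar(c(bf, bf)[kf:(kf + n - 1L)])
  rotr <- rawToChar(c(br, br)[kr:(kr + n - 1L)])
  if (rotf <= rotr)
    list(seq = rotf, rotation = kf - 1L, strand = "+")
  else
    list(seq = rotr, rotation = kr - 1L, strand = "-")
}

.rotations <- function(seq) {
  n <- nchar(seq)
  d <- paste0(seq, seq)
  vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), character(1))
}

# All 2n orientations (rotations of seq and of its reverse complement).
.orientations <- function(seq) c(.rotations(seq), .rotations(.revcomp(seq)))

.submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat))
      mat <<- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                       mismatch = -3,
                                                       baseOnly = TRUE)
    mat
  }
})

# Global-alignment identity (matches / alignment columns) of each pattern
# string against one subject string. Column count avoids materializing the
# aligned strings: every base sits in exactly one column and aligned pairs
# share one, so columns = |pattern| + |subject| - (matches + mismatches).
.globalIdentity <- function(patterns, subjectSeq) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subjectSeq),
    type = "global", substitutionMatrix = .submat(),
    gapOpening = 5, gapExtension = 2)
  nm <- Biostrings::nmatch(al)
  cols <- nchar(patterns) + nchar(subjectSeq) - nm - Biostrings::nmismatch(al)
  nm / cols
}

#' Best orientation of one monomer against another
#'
#' Finds the rotation and strand of \code{b} maximizing global-alignment
#' identity to \code{a}.
#'
#' @param a,b non-empty DNA strings (lengths may differ).
#' @return A list with \code{seq} (the best-oriented form of \code{b}),
#'   \code{identity}, \code{rotation} (0-based) and \code{strand}.
#' @export
bestOrientation <- function(a, b) {
  a <- .checkDNA(a, what = "a"); b <- .checkDNA(b, what = "b")
  ors <- .orientations(b)
  ids <- .globalIdentity(ors, a)
  i <- which.max(ids)
  n <- nchar(b)
  list(seq = ors[i], identity = ids[i],
       rotation = (i - 1L) %% n,
       strand = if (i <= n) "+" else "-")
}

#' Rotation/strand-invariant identity between two monomers
#'
#' Maximum global-alignment identity between \code{a} and any rotation of
#' \code{b} or of its reverse complement (and symmetrically of \code{a}
#' against \code{b}, so the measure is exactly symmetric). Identity is
#' matches divided by alignment columns, so indels count against identity.
#'
#' @param a,b non-empty DNA strings; lengths may differ.
#' @return A fraction in [0, 1].
#' @examples
#' rotationalIdentity("AAAACGTATT", "GTATTAAAAC")  # 1
#' @export
rotationalIdentity <- function(a, b) {
  a <- .checkDNA(a, what = "a"); b <- .checkDNA(b, what = "b")
  if (canonicalMonomer(a) == canonicalMonomer(b)) return(1)
  i1 <- max(.globalIdentity(.orientations(b), a))
  i2 <- max(.globalIdentity(.orientations(a), b))
  max(i1, i2)
}

# Thresholded variant: global identity with terminal gaps counted is at
# most min(len)/max(len), so pairs below that bound skip alignment and
# return the bound itself (still a valid upper bound on the identity).
.rotIdentityCapped <- function(a, b, threshold) {
  bound <- min(nchar(a), nchar(b)) / max(nchar(a), nchar(b))
  if (bound < threshold) return(bound)
  rotationalIdentity(a, b)
}

#' Shannon entropy of base composition
#'
#' @param seq a DNA string.
#' @return Entropy in bits over the A/C/G/T frequencies of \code{seq}.
#' @export
sequenceEntropy <- function(seq) {
  s <- .checkDNA(seq)
  p <- table(strsplit(s, "")[[1]])
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' GC content of a sequence
#'
#' Fraction of G+C among informative (non-N) bases.
#'
#' @param seq a DNA string over A/C/G/T/N.
#' @return Fraction in [0, 1].
#' @examples
#' gcContent("GGCC")  # 1
#' @export
gcContent <- function(seq) {
  s <- .checkDNA(seq, allowN = TRUE)
  b <- strsplit(s, "")[[1]]
  inf <- b != "N"
  if (!any(inf)) stop("no informative bases")
  sum(b == "G" | b == "C") / sum(inf)
}
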