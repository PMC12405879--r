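# Brute-force oracles and small generators shared across the test files.
# The oracles deliberately use a different algorithmic strategy than the
# package implementations (direct definition checking instead of KMP /
# Booth) so agreement is meaningful.

# Smallest p dividing nchar(s) such that s is its length-p prefix repeated.
brutePeriod <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    if (strrep(substr(s, 1L, p), n %/% p) == s) return(p)
  }
  n
}

bruteRotations <- function(s) {
  n <- nchar(s)
  d <- paste0(s, s)
  substring(d, seq_len(n), seq_len(n) + n - 1L)
}

bruteRevcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Lexicographic minimum (A < C < G < T) over all rotations of s and of its
# reverse complement. Bases are mapped to digits so the comparison is
# byte-wise and locale-independent.
bruteCanonical <- function(s) {
  cand <- c(bruteRotations(s), bruteRotations(bruteRevcomp(s)))
  keys <- chartr("ACGT", "0123", cand)
  cand[match(min(keys), keys)]
}

# All strings of length n over an alphabet, as a character vector.
allStrings <- function(n, alphabet = c("A", "C")) {
  g <- do.call(expand.grid,
               c(rep(list(alphabet), n), stringsAsFactors = FALSE))
  do.call(paste0, g)
}

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A primitive random monomer of length n (resamples until primitive).
randPrimitive <- function(n) {
  repeat {
    s <- randSeq(n)
    if (brutePeriod(s) == n) return(s)
  }
}

# Plant `insert` into random background at (0-based) position pos;
# returns the contig string.
plantIn <- function(background, insert, pos) {
  paste0(substr(background, 1L, pos), insert,
         substr(background, pos + 1L, nchar(background)))
}
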