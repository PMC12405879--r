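# k-seek-style profiling of simple short satellites in unassembled reads:
# exact maximal tandem runs of primitive units of at most `maxUnit` bp.

#' Scan one read for simple short satellite runs
#'
#' Finds the longest exact tandem run for every unit length up to
#' \code{maxUnit}; a run contributes its covered bp to the canonical form of
#' its (primitive) unit when it spans at least \code{minCopies} copies and
#' at least \code{minSpanFrac} of the read. Runs are exact; an N (or a
#' sequencing error) terminates the run.
#'
#' @param readSeq read DNA string.
#' @param maxUnit maximum unit length in bp (default 20).
#' @param minCopies minimum copies in the run (default 3).
#' @param minSpanFrac minimum fraction of the read covered (default 0.5).
#' @return Named numeric vector: canonical unit -> bp covered.
#' @examples
#' scanRead(strrep("AT", 50))
#' @export
scanRead <- function(readSeq, maxUnit = 20L, minCopies = 3,
                     minSpanFrac = 0.5) {
  scanReads(readSeq, maxUnit, minCopies, minSpanFrac)$unitBp
}

#' Scan many reads for simple short satellite runs
#'
#' Vectorized version of [scanRead()] over a read set.
#'
#' @param reads a \linkS4class{DNAStringSet} or character vector of reads.
#' @inheritParams scanRead
#' @return List with \code{unitBp} (named numeric, canonical unit -> total
#'   bp), \code{readsScanned} and \code{totalReadBp}.
#' @export
scanReads <- function(reads, maxUnit = 20L, minCopies = 3,
                      minSpanFrac = 0.5) {
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- toupper(reads)
  totalBp <- sum(nchar(reads))
  acc <- new.env(parent = emptyenv())
  for (len in unique(nchar(reads))) {
    sel <- reads[nchar(reads) == len]
    if (len < 2L) next
    bm <- matrix(charToRaw(paste(sel, collapse = "")), nrow = len)
    nOk <- bm %in% .DNA_BYTES  # N breaks runs: mask as never-equal
    dim(nOk) <- dim(bm)
    for (u in seq_len(min(maxUnit, len %/% 2L))) {
      E <- (bm[seq_len(len - u), , drop = FALSE] ==
              bm[(u + 1L):len, , drop = FALSE]) &
           nOk[seq_len(len - u), , drop = FALSE] &
           nOk[(u + 1L):len, , drop = FALSE]
      run <- integer(ncol(E)); best <- integer(ncol(E))
      bestEnd <- integer(ncol(E))
      for (i in seq_len(nrow(E))) {
        run <- (run + 1L) * E[i, ]
        upd <- run > best
        best[upd] <- run[upd]; bestEnd[upd] <- i
      }
      span <- best + u
      hit <- which(best > 0L & span >= minCopies * u &
                     span >= minSpanFrac * len)
      for (j in hit) {
        st <- bestEnd[j] - best[j] + 1L
        unit <- substr(sel[j], st, st + u - 1L)
        if (primitivePeriod(unit) != u) next
        cu <- canonicalMonomer(unit)
        acc[[cu]] <- (if (is.null(acc[[cu]])) 0 else acc[[cu]]) + span[j]
      }
    }
  }
  v <- unlist(as.list(acc))
  if (is.null(v)) v <- setNames(numeric(0), character(0))
  list(unitBp = v[order(names(v))], readsScanned = length(reads),
       totalReadBp = totalBp)
}

#' Aggregate reads into a k-mer satellite profile
#'
#' @param reads a \linkS4class{DNAStringSet}, character vector of reads, or
#'   a path to a FASTQ file (gzip allowed).
#' @param sampleIdent sample identifier.
#' @inheritParams scanRead
#' @return A \linkS4class{KmerSatProfile}.
#' @export
aggregateProfiles <- function(reads, sampleIdent, maxUnit = 20L,
                              minCopies = 3, minSpanFrac = 0.5) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      !grepl("^[ACGTNacgtn]*$", reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  if (!length(reads)) stop("zero parseable reads in ", sampleIdent)
  r <- scanReads(reads, maxUnit, minCopies, minSpanFrac)
  new("KmerSatProfile", sampleId = sampleIdent, unitBp = r$unitBp,
      readsScanned = as.numeric(r$readsScanned),
      totalReadBp = as.numeric(r$totalReadBp))
}

#' Compare germline and somatic k-mer satellite profiles
#'
#' Depth-normalizes both profiles to bp per Gb of sequenced bases and
#' reports units enriched in the germline sample: normalized germ abundance
#' at least \code{minTotalKb} kb per Gb and germ/soma ratio at least
#' \code{ratioMin} (pseudocount of 1 bp per Gb on the denominator). The
#' complementary list of units abundant in soma (same abundance floor) is
#' returned alongside.
#'
#' @param germ,soma \linkS4class{KmerSatProfile} objects.
#' @param minTotalKb abundance floor in kb per Gb (default 10).
#' @param ratioMin minimum germ/soma ratio (default 5).
#' @return List with \code{enriched} (character vector of units),
#'   \code{abundant_soma}, and \code{table} (per-unit normalized bp and
#'   ratio).
#' @export
compareProfiles <- function(germ, soma, minTotalKb = 10, ratioMin = 5) {
  if (germ@totalReadBp <= 0 || soma@totalReadBp <= 0) stop("empty sample")
  units <- sort(union(names(germ@unitBp), names(soma@unitBp)))
  g <- setNames(numeric(length(units)), units)
  s <- g
  g[names(germ@unitBp)] <- unitAbundance(germ, perGb = TRUE)
  s[names(soma@unitBp)] <- unitAbundance(soma, perGb = TRUE)
  ratio <- g / (s + 1)
  minBp <- minTotalKb * 1000
  tab <- data.frame(unit = units, germ_bp_per_gb = unname(g),
                    soma_bp_per_gb = unname(s),
                    ratio_germ_over_soma = unname(ratio),
                    stringsAsFactors = FALSE)
  list(enriched = units[g >= minBp & ratio >= ratioMin],
       abundant_soma = units[s >= minBp],
       table = tab)
}

#' Write a k-mer satellite profile as TSV
#'
#' @param profile a \linkS4class{KmerSatProfile}.
#' @param path output file.
#' @param header optional comment lines (written with a leading "#").
#' @return Invisibly, the data.frame written.
#' @export
writeProfile <- function(profile, path, header = NULL) {
  df <- data.frame(unit = names(profile@unitBp),
                   bp = unname(profile@unitBp),
                   bp_per_gb = unname(unitAbundance(profile, perGb = TRUE)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("unit", "bp", "bp_per_gb"), collapse = "\t"), con)
  if (nrow(df))
    writeLines(paste(df$unit, df$bp, format(df$bp_per_gb, trim = TRUE),
                     sep = "\t"), con)
  invisible(df)
}
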