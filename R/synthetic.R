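# Seeded synthetic assemblies and reads with planted satellite landscapes
# and truth manifests, so every pipeline stage is testable end to end.

#' Random background DNA
#'
#' i.i.d. bases at the requested GC content, drawn from the current RNG
#' stream.
#'
#' @param n length in bp.
#' @param gc GC fraction (default 0.4).
#' @return A DNA string.
#' @export
randomDNA <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Mutate a monomer copy
#'
#' Applies i.i.d. per-base substitutions (uniform over the three alternative
#' bases) and single-base indels (insertion or deletion with equal
#' probability) from the current RNG stream.
#'
#' @param monomer DNA string.
#' @param subRate,indelRate per-base rates in [0, 0.2].
#' @return Mutated DNA string.
#' @export
mutateMonomer <- function(monomer, subRate = 0, indelRate = 0) {
  stopifnot(subRate >= 0, subRate <= 0.2, indelRate >= 0, indelRate <= 0.2)
  if (subRate == 0 && indelRate == 0) return(monomer)
  b <- strsplit(monomer, "")[[1]]
  n <- length(b)
  bases <- c("A", "C", "G", "T")
  subs <- which(runif(n) < subRate)
  for (i in subs) b[i] <- sample(setdiff(bases, b[i]), 1L)
  if (indelRate > 0) {
    ind <- which(runif(n) < indelRate)
    if (length(ind)) {
      out <- vector("list", n)
      for (i in seq_len(n)) out[[i]] <- b[i]
      for (i in ind) {
        if (runif(1) < 0.5) out[[i]] <- character(0)        # deletion
        else out[[i]] <- c(sample(bases, 1L), b[i])          # insertion
      }
      b <- unlist(out)
    }
  }
  paste(b, collapse = "")
}

#' Describe a planted satellite family
#'
#' @param name family label used in the truth manifest.
#' @param monomer ancestral monomer (must be primitive).
#' @param arrays data.frame with columns \code{contig}, \code{start}
#'   (0-based position in the background), \code{copies}.
#' @param subRate,indelRate per-base mutation rates applied independently to
#'   every planted copy.
#' @param variantA,variantB optional variant consensi; when supplied each
#'   copy is drawn from A or B (B with probability \code{shareB}) before
#'   mutation.
#' @param shareB share of copies drawn from variant B (default 0.5).
#' @return A \code{plantedFamily} list.
#' @export
plantedFamily <- function(name, monomer, arrays, subRate = 0,
                          indelRate = 0, variantA = NULL, variantB = NULL,
                          shareB = 0.5) {
  monomer <- .checkDNA(monomer, what = "monomer")
  if (primitivePeriod(monomer) != nchar(monomer))
    stop("ancestral monomer must be primitive")
  stopifnot(is.data.frame(arrays),
            all(c("contig", "start", "copies") %in% names(arrays)))
  structure(list(name = name, monomer = monomer, arrays = arrays,
                 subRate = subRate, indelRate = indelRate,
                 variantA = variantA, variantB = variantB, shareB = shareB),
            class = "plantedFamily")
}

#' Specify a synthetic genome
#'
#' @param contigs data.frame with \code{name}, \code{length} (background bp)
#'   and \code{gc}.
#' @param planted list of [plantedFamily()] objects. Array \code{start}
#'   positions index the background sequence; planted arrays are inserted
#'   there (they add to the contig length) and must not overlap.
#' @param lContigs character vector of contig names present only in the
#'   germ assembly (the L-chromosome emulation).
#' @param seed integer seed recorded in the manifest.
#' @return A validated \code{syntheticSpec} list.
#' @export
syntheticSpec <- function(contigs, planted = list(), lContigs = character(),
                          seed = 1L) {
  stopifnot(is.data.frame(contigs),
            all(c("name", "length", "gc") %in% names(contigs)),
            all(contigs$length > 0),
            all(lContigs %in% contigs$name))
  for (pf in planted) {
    stopifnot(inherits(pf, "plantedFamily"))
    if (!all(pf$arrays$contig %in% contigs$name))
      stop("planted family '", pf$name, "' references unknown contigs")
  }
  # overlap check in background coordinates
  allArr <- do.call(rbind, lapply(planted, function(pf)
    cbind(pf$arrays, fam = pf$name,
          nominal = pf$arrays$copies * nchar(pf$monomer))))
  if (!is.null(allArr)) {
    for (ctg in unique(allArr$contig)) {
      a <- allArr[allArr$contig == ctg, , drop = FALSE]
      a <- a[order(a$start), , drop = FALSE]
      if (nrow(a) > 1L && any(a$start[-1L] < head(a$start, -1L)))
        stop("planted arrays overlap on ", ctg)
      if (any(a$start > contigs$length[contigs$name == ctg]))
        stop("planted array start beyond contig background on ", ctg)
    }
  }
  structure(list(contigs = contigs, planted = planted,
                 lContigs = lContigs, seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Generate synthetic assemblies and a truth manifest
#'
#' Builds i.i.d. background at the stated GC per contig, inserts every
#' planted array with per-copy mutation, and returns the "germ" assembly
#' (all contigs) and the "soma" assembly (without \code{lContigs}) together
#' with a manifest recording realized (post-mutation) coordinates and bp.
#'
#' @param spec a [syntheticSpec()].
#' @return List with \code{germ} and \code{soma}
#'   (\linkS4class{DNAStringSet}), \code{manifest} (data.frame: family,
#'   contig, start, end 0-based half-open, realized_bp, copies) and
#'   \code{familyBp} (list with per-family totals in each assembly).
#' @export
generateGenome <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  set.seed(spec$seed)
  inserts <- list()  # per contig: data.frame(start, seq, fam, copies)
  for (pf in spec$planted) {
    for (i in seq_len(nrow(pf$arrays))) {
      a <- pf$arrays[i, ]
      copies <- lapply(seq_len(a$copies), function(j) {
        src <- pf$monomer
        if (!is.null(pf$variantA))
          src <- if (runif(1) < pf$shareB) pf$variantB else pf$variantA
        mutateMonomer(src, pf$subRate, pf$indelRate)
      })
      seqc <- paste(unlist(copies), collapse = "")
      inserts[[a$contig]] <- rbind(
        inserts[[a$contig]],
        data.frame(start = a$start, seq = seqc, fam = pf$name,
                   copies = a$copies, stringsAsFactors = FALSE))
    }
  }
  contigSeqs <- character(nrow(spec$contigs))
  names(contigSeqs) <- spec$contigs$name
  manifest <- list()
  for (k in seq_len(nrow(spec$contigs))) {
    nm <- spec$contigs$name[k]
    bg <- randomDNA(spec$contigs$length[k], spec$contigs$gc[k])
    ins <- inserts[[nm]]
    if (is.null(ins)) { contigSeqs[nm] <- bg; next }
    ins <- ins[order(ins$start), , drop = FALSE]
    pieces <- character(); cur <- 0L; shift <- 0L
    for (i in seq_len(nrow(ins))) {
      pieces <- c(pieces, substr(bg, cur + 1L, ins$start[i]))
      st <- ins$start[i] + shift
      manifest[[length(manifest) + 1L]] <- data.frame(
        family = ins$fam[i], contig = nm, start = st,
        end = st + nchar(ins$seq[i]),
        realized_bp = nchar(ins$seq[i]), copies = ins$copies[i],
        stringsAsFactors = FALSE)
      pieces <- c(pieces, ins$seq[i])
      shift <- shift + nchar(ins$seq[i])
      cur <- ins$start[i]
    }
    pieces <- c(pieces, substr(bg, cur + 1L, nchar(bg)))
    contigSeqs[nm] <- paste(pieces, collapse = "")
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(family = character(), contig = character(),
               start = integer(), end = integer(), realized_bp = integer(),
               copies = numeric(), stringsAsFactors = FALSE)
  germ <- Biostrings::DNAStringSet(contigSeqs)
  soma <- germ[setdiff(names(germ), spec$lContigs)]
  somaMan <- manifest[!(manifest$contig %in% spec$lContigs), , drop = FALSE]
  familyBp <- list(
    germ = tapply(manifest$realized_bp, manifest$family, sum),
    soma = tapply(somaMan$realized_bp, somaMan$family, sum))
  list(germ = germ, soma = soma, manifest = manifest, familyBp = familyBp)
}

#' Simulate uniform-coverage reads
#'
#' Uniform start positions within contigs (reads lie fully inside a
#' contig), both strands equiprobable, i.i.d. substitution errors. The read
#' count is \code{round(coverage * genomeBp / readLen)}; contigs shorter
#' than the read length are skipped with a warning.
#'
#' @param assembly \linkS4class{DNAStringSet} or named character vector.
#' @param coverage target mean coverage.
#' @param readLen read length in nt (default 100).
#' @param errRate per-base substitution error rate (default 0.002).
#' @param sampleIdent sample name used in read ids.
#' @param fastqPath optional path; when given, reads are written as FASTQ
#'   (flat quality "I").
#' @return \linkS4class{DNAStringSet} of reads (named
#'   "<sample>_<i>/<strand>").
#' @export
generateReads <- function(assembly, coverage, readLen = 100L,
                          errRate = 0.002, sampleIdent = "sample",
                          fastqPath = NULL) {
  stopifnot(coverage > 0)
  seqs <- .asContigSet(assembly)
  keep <- nchar(seqs) >= readLen
  if (!all(keep)) {
    warning("skipping ", sum(!keep), " contig(s) shorter than the read length")
    seqs <- seqs[keep]
  }
  genomeBp <- sum(nchar(seqs))
  nReads <- round(coverage * genomeBp / readLen)
  ctg <- sample(names(seqs), nReads, replace = TRUE,
                prob = nchar(seqs) / genomeBp)
  starts <- floor(runif(nReads) * (nchar(seqs)[ctg] - readLen + 1)) + 1L
  fwd <- runif(nReads) < 0.5
  reads <- substr(seqs[ctg], starts, starts + readLen - 1L)
  reads[!fwd] <- vapply(reads[!fwd], .revcomp, character(1),
                        USE.NAMES = FALSE)
  if (errRate > 0) {
    nErr <- rbinom(nReads, readLen, errRate)
    for (i in which(nErr > 0L)) {
      b <- strsplit(reads[i], "")[[1]]
      pos <- sample.int(readLen, nErr[i])
      for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
      reads[i] <- paste(b, collapse = "")
    }
  }
  names(reads) <- paste0(sampleIdent, "_", seq_len(nReads),
                         ifelse(fwd, "/fwd", "/rev"))
  out <- Biostrings::DNAStringSet(reads)
  if (!is.null(fastqPath)) {
    qual <- Biostrings::BStringSet(rep(strrep("I", readLen), nReads))
    Biostrings::writeXStringSet(out, fastqPath, format = "fastq",
                                qualities = qual)
  }
  out
}

#' Score discovery against the planted truth
#'
#' Matches each planted family's ancestral monomer to the reported family
#' with the highest [rotationalIdentity()] consensus identity (counted as
#' recovered at >= \code{matchIdentity}), and compares reported against
#' planted abundance.
#'
#' @param truthBp named numeric: planted family -> true bp.
#' @param truthMonomers named character: planted family -> ancestral
#'   monomer.
#' @param set reported \linkS4class{SatelliteFamilySet}.
#' @param abundance data.frame from [familyAbundance()] (optional; without
#'   it abundance errors are NA).
#' @param matchIdentity identity floor counting as recovery (default 0.9).
#' @return List with \code{perFamily} (data.frame: family, matched_id,
#'   consensus_identity, true_bp, reported_bp, rel_abundance_error),
#'   \code{precision} and \code{recall}.
#' @export
scoreRecovery <- function(truthBp, truthMonomers, set, abundance = NULL,
                          matchIdentity = 0.9) {
  fams <- names(truthMonomers)
  ids <- familyIds(set)
  cons <- as.character(consensusSeqs(set))
  usedReported <- character()
  rows <- lapply(fams, function(f) {
    if (!length(ids)) {
      return(data.frame(family = f, matched_id = NA_character_,
                        consensus_identity = NA_real_,
                        true_bp = as.numeric(truthBp[f]),
                        reported_bp = NA_real_,
                        rel_abundance_error = NA_real_,
                        stringsAsFactors = FALSE))
    }
    idv <- vapply(cons, .rotIdentityCapped, numeric(1), truthMonomers[f],
                  matchIdentity, USE.NAMES = FALSE)
    j <- which.max(idv)
    hit <- idv[j] >= matchIdentity
    rep_bp <- if (hit && !is.null(abundance)) {
      k <- match(ids[j], abundance$family_id)
      if (is.na(k)) NA_real_ else abundance$total_kb[k] * 1000
    } else NA_real_
    if (hit) usedReported <<- union(usedReported, ids[j])
    data.frame(family = f,
               matched_id = if (hit) ids[j] else NA_character_,
               consensus_identity = idv[j],
               true_bp = as.numeric(truthBp[f]),
               reported_bp = rep_bp,
               rel_abundance_error =
                 if (!is.na(rep_bp)) (rep_bp - as.numeric(truthBp[f])) /
                   as.numeric(truthBp[f]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  matched <- sum(!is.na(per$matched_id))
  list(perFamily = per,
       precision = if (length(ids)) length(usedReported) / length(ids)
                   else NA_real_,
       recall = matched / length(fams))
}
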