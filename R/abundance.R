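# Family-level genomic abundance accounting, BED6 output and the
# family-table report.

#' Assign detected arrays to families
#'
#' Maps each array to the family containing its canonical monomer.
#'
#' @param arrays array data.frame from [scanAssembly()].
#' @param set a \linkS4class{SatelliteFamilySet} built from these arrays.
#' @return \code{arrays} with an added \code{family} column (NA for arrays
#'   whose monomer is not a member of any family).
#' @export
assignArrays <- function(arrays, set) {
  if (!nrow(arrays)) { arrays$family <- character(0); return(arrays) }
  mono <- vapply(arrays$unit_seq, canonicalMonomer, character(1))
  m <- set@members
  arrays$family <- m$family_id[match(mono, m$monomer)]
  arrays
}

#' Arrays as BED6 records
#'
#' One BED6 line per array: 0-based half-open interval, name = family id,
#' score = \code{as.integer(100 * mean_identity)} clamped to [0, 1000],
#' strand "+". Records are sorted by (contig, start).
#'
#' @param arrays array data.frame with a \code{family} column
#'   (see [assignArrays()]).
#' @param path optional output file; a \code{#}-comment header is written
#'   when \code{header} is supplied.
#' @param header optional character vector of comment lines (without "#").
#' @return data.frame of the six BED columns, invisibly when writing.
#' @export
arraysToBed <- function(arrays, path = NULL, header = NULL) {
  if (!nrow(arrays)) {
    bed <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = integer(), strand = character())
  } else {
    if (any(arrays$start < 0) || any(arrays$end <= arrays$start))
      stop("array interval invalid (start/end out of order)")
    fam <- if ("family" %in% names(arrays)) arrays$family
           else rep("satellite", nrow(arrays))
    bed <- data.frame(
      chrom = arrays$contig,
      start = as.integer(arrays$start),
      end = as.integer(arrays$end),
      name = ifelse(is.na(fam), "unassigned", fam),
      score = pmin(pmax(as.integer(100 * arrays$mean_identity), 0L), 1000L),
      strand = "+", stringsAsFactors = FALSE)
    bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
    rownames(bed) <- NULL
  }
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    if (nrow(bed))
      writeLines(do.call(paste, c(bed, sep = "\t")), con)
    return(invisible(bed))
  }
  bed
}

# GRanges (1-based) of arrays for one family, for merge accounting.
.familyRanges <- function(arrays, fid) {
  sel <- which(arrays$family == fid)
  GenomicRanges::GRanges(arrays$contig[sel],
                         IRanges::IRanges(arrays$start[sel] + 1L,
                                          arrays$end[sel]))
}

#' Per-family genomic abundance
#'
#' For each family, merges overlapping/abutting same-family arrays and
#' reports total kb, fraction of the assembly, merged array-size range and
#' GC content of the consensus (and of each variant consensus when variants
#' were called). Records are ordered by decreasing total kb.
#'
#' @param set a \linkS4class{SatelliteFamilySet}.
#' @param arrays array data.frame with \code{family} assignments.
#' @param assemblyBp total assembly length in bp (N bases included).
#' @return data.frame with columns \code{family_id, unit_len, n_arrays,
#'   array_size_min_kb, array_size_max_kb, total_kb, pct_assembly,
#'   gc_content, gc_variants}.
#' @export
familyAbundance <- function(set, arrays, assemblyBp) {
  stopifnot(assemblyBp > 0)
  ids <- familyIds(set)
  rows <- lapply(ids, function(fid) {
    gr <- GenomicRanges::reduce(.familyRanges(arrays, fid))
    w <- GenomicRanges::width(gr)
    tot <- sum(as.numeric(w))
    cons <- as.character(set@consensus[[fid]])
    v <- set@variants[set@variants$family_id == fid, , drop = FALSE]
    gcv <- if (nrow(v))
      paste(sprintf("%.4f", vapply(v$consensus, gcContent, numeric(1))),
            collapse = ";") else ""
    data.frame(family_id = fid, unit_len = nchar(cons),
               n_arrays = sum(arrays$family == fid, na.rm = TRUE),
               array_size_min_kb = if (length(w)) min(w) / 1000 else NA_real_,
               array_size_max_kb = if (length(w)) max(w) / 1000 else NA_real_,
               total_kb = tot / 1000,
               pct_assembly = tot / assemblyBp,
               gc_content = gcContent(cons),
               gc_variants = gcv,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec <- rec[order(-rec$total_kb, rec$family_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Select abundant families
#'
#' Keeps records with \code{total_kb >= minKb} (boundary inclusive), order
#' preserved.
#'
#' @param records data.frame from [familyAbundance()].
#' @param minKb abundance threshold in kb (default 200, the conventional
#'   floor for "abundant" satellite families).
#' @return Subset of \code{records}.
#' @export
selectAbundant <- function(records, minKb = 200) {
  stopifnot(minKb >= 0)
  records[records$total_kb >= minKb, , drop = FALSE]
}

.fmtPct <- function(x, digits = 2) sprintf(paste0("%.", digits, "f%%"), 100 * x)

#' Render the family summary table
#'
#' One row per family: monomer length, merged array-size range
#' ("min–max" kb, one decimal on the minimum), amount in assembly as
#' "kb(x.xx%)", GC content as percentages (per variant when variants
#' exist), and probe sequences when supplied.
#'
#' @param records data.frame from [familyAbundance()].
#' @param probes optional probe data.frame with \code{family_id},
#'   \code{variant_label}, \code{probe_seq}.
#' @param path optional output file; lines in \code{header} are written as
#'   "#" comments.
#' @param header optional character vector of comment lines.
#' @return Character vector of TSV lines (invisibly when writing).
#' @export
renderFamilyTable <- function(records, probes = NULL, path = NULL,
                              header = NULL) {
  cols <- c("family", "monomer_length_bp", "array_size_kb",
            "amount_in_assembly_kb", "gc_content", "probes")
  lines <- paste(cols, collapse = "\t")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    sizes <- if (is.na(r$array_size_min_kb)) "n.f."
      else sprintf("%.1f–%s", r$array_size_min_kb,
                   format(round(r$array_size_max_kb), trim = TRUE))
    amount <- sprintf("%s(%s)",
                      formatC(round(r$total_kb), format = "d", big.mark = ","),
                      .fmtPct(r$pct_assembly))
    gc <- if (nzchar(r$gc_variants)) {
      paste(vapply(strsplit(r$gc_variants, ";")[[1]],
                   function(x) .fmtPct(as.numeric(x)), character(1)),
            collapse = " / ")
    } else .fmtPct(r$gc_content)
    pr <- ""
    if (!is.null(probes) && nrow(probes)) {
      sel <- probes$family_id == r$family_id
      if (any(sel)) {
        lab <- ifelse(is.na(probes$variant_label[sel]), "",
                      probes$variant_label[sel])
        pr <- paste(paste0(lab, ifelse(nzchar(lab), ":", ""),
                           probes$probe_seq[sel]), collapse = " ")
      }
    }
    lines <- c(lines, paste(r$family_id, r$unit_len, sizes, amount, gc, pr,
                            sep = "\t"))
  }
  if (!is.null(path)) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    writeLines(lines, con)
    return(invisible(lines))
  }
  lines
}
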