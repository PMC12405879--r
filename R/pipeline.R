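# Orchestration: configuration, provenance headers and the four pipeline
# stages (discover / compare / reads / probes) as plain functions. A thin
# command-line wrapper over these lives in inst/scripts/satmine-cli.R.

#' Pipeline run configuration
#'
#' Collects every stage parameter with its default. The object serializes
#' to/from JSON losslessly ([writeConfig()], [readConfig()]).
#'
#' @param ... overrides of the defaults, by name.
#' @return A named list of class \code{satmineConfig}.
#' @examples
#' cfg <- runConfig(unit_min = 10, cluster_id = 0.85)
#' @export
runConfig <- function(...) {
  cfg <- list(
    species_prefix = "Bcop",
    seed = 1L,
    unit_min = 20L, unit_max = 500L, min_copies = 5, min_identity = 0.8,
    match = 2L, mismatch = -3L, gap = -5L, min_array_score = 50L,
    cluster_id = 0.8,
    variant_id = 0.95, variant_min_share = 0.20,
    abundant_kb = 200,
    compare_match_id = 0.8, compare_min_kb = 200, compare_ratio_min = 5,
    reads_max_unit = 20L, reads_min_copies = 3, reads_min_span_frac = 0.5,
    reads_min_kb = 10, reads_ratio_min = 5,
    probe_len_min = 30L, probe_len_max = 40L,
    probe_gc_min = 0.15, probe_gc_max = 0.65, probe_min_disc = 3L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  for (nm in names(ov)) {      # keep each field's storage type stable
    cfg[[nm]] <- if (is.integer(cfg[[nm]])) as.integer(ov[[nm]])
                 else if (is.numeric(cfg[[nm]])) as.numeric(ov[[nm]])
                 else as.character(ov[[nm]])
  }
  structure(cfg, class = "satmineConfig")
}

#' @rdname runConfig
#' @param config a \code{satmineConfig}.
#' @param path JSON file path.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname runConfig
#' @export
readConfig <- function(path) {
  do.call(runConfig, jsonlite::read_json(path, simplifyVector = TRUE))
}

# Short polynomial hash of the serialized config, for provenance headers.
configHash <- function(config) {
  b <- utf8ToInt(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                  digits = NA))
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.version <- function() as.character(utils::packageVersion("satmine"))

.headerLines <- function(config) {
  c(paste0("satmine v", .version(),
           " config=", configHash(config),
           " seed=", config$seed))
}

.detectorFromConfig <- function(config) {
  detectorParams(unitMin = config$unit_min, unitMax = config$unit_max,
                 minCopies = config$min_copies,
                 minIdentity = config$min_identity,
                 matchScore = config$match, mismatchScore = config$mismatch,
                 gapScore = config$gap,
                 minArrayScore = config$min_array_score)
}

.writeTsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
  invisible(path)
}

.writeFastaWithInfo <- function(seqs, path, info) {
  # FASTA cannot carry comment lines; provenance goes into the first
  # record's description.
  nm <- names(seqs)
  if (length(nm)) nm[1] <- paste0(nm[1], " ", info)
  x <- Biostrings::DNAStringSet(as.character(seqs))
  names(x) <- nm
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Run satellite discovery on an assembly
#'
#' Full discovery stage: scan for tandem arrays, canonicalize monomers,
#' cluster into families, build consensi, call variants, name families,
#' and compute abundance. When \code{outDir} is given, writes
#' \code{arrays.tsv}, \code{arrays.bed}, \code{families.fasta} and
#' \code{family_table.tsv}, each starting with a provenance header (tool
#' version, config hash, seed).
#'
#' @param assembly FASTA path, \linkS4class{DNAStringSet} or named
#'   character vector.
#' @param config a [runConfig()].
#' @param outDir optional output directory.
#' @return List with \code{arrays} (family-assigned), \code{families}
#'   (\linkS4class{SatelliteFamilySet}), \code{abundance},
#'   \code{abundant} (subset at \code{abundant_kb}) and \code{assemblyBp}.
#' @export
runDiscovery <- function(assembly, config = runConfig(), outDir = NULL) {
  seqs <- .asContigSet(assembly)
  if (!length(seqs) || !sum(nchar(seqs))) stop("empty assembly")
  assemblyBp <- sum(nchar(seqs))
  params <- .detectorFromConfig(config)
  arrays <- scanAssembly(seqs, params)
  message("arrays detected: ", nrow(arrays))
  monomers <- monomersFromArrays(arrays)
  fams <- clusterMonomers(monomers, idThreshold = config$cluster_id)
  fams <- detectVariants(fams, config$variant_id, config$variant_min_share)
  fams <- nameFamilies(fams, config$species_prefix)
  message("families: ", length(fams))
  arrays <- assignArrays(arrays, fams)
  abundance <- familyAbundance(fams, arrays, assemblyBp)
  abundant <- selectAbundant(abundance, config$abundant_kb)
  message("abundant families (>= ", config$abundant_kb, " kb): ",
          nrow(abundant))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .headerLines(config)
    .writeTsv(arrays, file.path(outDir, "arrays.tsv"), hdr)
    arraysToBed(arrays, file.path(outDir, "arrays.bed"), header = hdr)
    seqsOut <- consensusSeqs(fams)
    v <- familyVariants(fams)
    if (nrow(v)) {
      vset <- Biostrings::DNAStringSet(v$consensus)
      names(vset) <- paste0(v$family_id, ".", v$label)
      seqsOut <- c(seqsOut, vset)
    }
    .writeFastaWithInfo(seqsOut, file.path(outDir, "families.fasta"), hdr)
    renderFamilyTable(abundance, path = file.path(outDir, "family_table.tsv"),
                      header = hdr)
  }
  list(arrays = arrays, families = fams, abundance = abundance,
       abundant = abundant, assemblyBp = assemblyBp)
}

#' Compare two discovery runs and flag restricted families
#'
#' @param discA,discB results of [runDiscovery()] on the two assemblies
#'   (e.g. core/soma as A, L-containing/germ as B).
#' @param config a [runConfig()].
#' @param outDir optional output directory (\code{matches.tsv},
#'   \code{flagged.fasta}).
#' @return List with \code{matches} and \code{flagged}.
#' @export
runCompare <- function(discA, discB, config = runConfig(), outDir = NULL) {
  abA <- setNames(discA$abundance$total_kb, discA$abundance$family_id)
  abB <- setNames(discB$abundance$total_kb, discB$abundance$family_id)
  m <- matchFamilies(discA$families, discB$families,
                     matchThreshold = config$compare_match_id,
                     abundanceA = abA, abundanceB = abB)
  fl <- flagRestricted(m, minKb = config$compare_min_kb,
                       ratioMin = config$compare_ratio_min)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hdr <- paste0(.headerLines(config),
                  " match_id=", config$compare_match_id,
                  " min_kb=", config$compare_min_kb,
                  " ratio_min=", config$compare_ratio_min)
    .writeTsv(m, file.path(outDir, "matches.tsv"), hdr)
    if (nrow(fl)) {
      cons <- consensusSeqs(discB$families)[fl$family_b_id]
      .writeFastaWithInfo(cons, file.path(outDir, "flagged.fasta"), hdr)
    }
  }
  list(matches = m, flagged = fl)
}

#' Profile short satellites in read sets
#'
#' @param fastqs named character vector of FASTQ paths (or a named list of
#'   read sets). With exactly two samples the first is treated as germline
#'   and the second as soma and [compareProfiles()] is run.
#' @param config a [runConfig()].
#' @param outDir optional output directory (one profile TSV per sample,
#'   plus \code{profile_comparison.tsv} for two samples).
#' @return List with \code{profiles} (list of
#'   \linkS4class{KmerSatProfile}) and \code{comparison} (or NULL).
#' @export
runReads <- function(fastqs, config = runConfig(), outDir = NULL) {
  if (!length(fastqs)) stop("at least one read set is required")
  if (is.null(names(fastqs)))
    names(fastqs) <- paste0("sample", seq_along(fastqs))
  profiles <- lapply(names(fastqs), function(nm)
    aggregateProfiles(fastqs[[nm]], nm,
                      maxUnit = config$reads_max_unit,
                      minCopies = config$reads_min_copies,
                      minSpanFrac = config$reads_min_span_frac))
  names(profiles) <- names(fastqs)
  comparison <- NULL
  if (length(profiles) == 2L)
    comparison <- compareProfiles(profiles[[1L]], profiles[[2L]],
                                  minTotalKb = config$reads_min_kb,
                                  ratioMin = config$reads_ratio_min)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .headerLines(config)
    for (nm in names(profiles))
      writeProfile(profiles[[nm]],
                   file.path(outDir, paste0("profile_", nm, ".tsv")), hdr)
    if (!is.null(comparison))
      .writeTsv(comparison$table,
                file.path(outDir, "profile_comparison.tsv"), hdr)
  }
  list(profiles = profiles, comparison = comparison)
}

#' Design probes for a discovered family set
#'
#' One conserved probe per family; a discriminating A/B pair wherever
#' variants were called. Families for which no feasible probe exists are
#' listed with the failure reason instead of aborting the run.
#'
#' @param families a \linkS4class{SatelliteFamilySet}.
#' @param config a [runConfig()].
#' @param outDir optional output directory (\code{probes.tsv}).
#' @return List with \code{probes} (data.frame) and \code{failures}
#'   (data.frame of family_id, reason).
#' @export
runProbes <- function(families, config = runConfig(), outDir = NULL) {
  lenRange <- c(config$probe_len_min, config$probe_len_max)
  gcRange <- c(config$probe_gc_min, config$probe_gc_max)
  probes <- list(); fails <- list()
  mem <- familyMembers(families)
  vars <- familyVariants(families)
  for (fid in familyIds(families)) {
    cons <- as.character(consensusSeqs(families)[[fid]])
    members <- mem$monomer[mem$family_id == fid]
    r <- tryCatch(designFamilyProbe(cons, members, lenRange, gcRange,
                                    familyId = fid),
                  error = function(e) conditionMessage(e))
    if (is.character(r))
      fails[[length(fails) + 1L]] <- data.frame(family_id = fid, reason = r)
    else probes[[length(probes) + 1L]] <- r
    v <- vars[vars$family_id == fid, , drop = FALSE]
    if (nrow(v) >= 2L) {
      r <- tryCatch(
        designVariantProbes(v$consensus[v$label == "A"],
                            v$consensus[v$label == "B"],
                            lenRange, gcRange,
                            minDiscrimination = config$probe_min_disc,
                            familyId = fid),
        error = function(e) conditionMessage(e))
      if (is.character(r))
        fails[[length(fails) + 1L]] <-
          data.frame(family_id = fid, reason = r)
      else probes[[length(probes) + 1L]] <- r
    }
  }
  probes <- if (length(probes)) do.call(rbind, probes) else
    data.frame(family_id = character(), variant_label = character(),
               probe_seq = character(), start = integer(),
               length = integer(), gc = numeric(),
               on_target_max_mismatch = numeric(),
               off_target_min_mismatch = numeric(),
               stringsAsFactors = FALSE)
  fails <- if (length(fails)) do.call(rbind, fails) else
    data.frame(family_id = character(), reason = character())
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeTsv(probes, file.path(outDir, "probes.tsv"),
              .headerLines(config))
  }
  list(probes = probes, failures = fails)
}
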