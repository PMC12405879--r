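test_that("scanRead reports the canonical unit of an exact tandem run", {
  v <- scanRead(strrep("AT", 50))
  expect_identical(names(v), canonicalMonomer("AT"))
  expect_equal(unname(v), 100)
  # reverse-complement reads fold onto the same canonical unit
  v2 <- scanRead(bruteRevcomp(strrep("ACT", 30)))
  expect_identical(names(v2), canonicalMonomer("ACT"))
})

test_that("only primitive units are counted (no double counting)", {
  v <- scanRead(strrep("ATAT", 25))
  expect_identical(names(v), canonicalMonomer("AT"))
  expect_equal(unname(v), 100)
})

test_that("minCopies and minSpanFrac thresholds gate the runs", {
  # 2 copies of a 10-mer in a 100 bp read: below both thresholds
  set.seed(41)
  u <- randPrimitive(10)
  read <- paste0(strrep(u, 2), randSeq(80, c("G", "T")))
  expect_length(scanRead(read), 0)
  # 4 copies = 40 bp of a 100 bp read: copies pass but span fraction fails
  read2 <- plantIn(randSeq(60, c("G", "T")), strrep(u, 4), 10)
  expect_length(scanRead(read2), 0)
  expect_gte(length(scanRead(read2, minSpanFrac = 0.3)), 1)
})

test_that("N terminates runs", {
  read <- paste0(strrep("ACT", 20), "N", strrep("ACT", 20))
  v <- scanRead(read, minSpanFrac = 0.4)
  expect_equal(unname(v[canonicalMonomer("ACT")]), 60)
})

test_that("scanReads totals bp across reads of mixed lengths", {
  reads <- c(strrep("AT", 50), strrep("AT", 60), strrep("ACT", 30))
  r <- scanReads(reads)
  expect_equal(r$readsScanned, 3)
  expect_equal(r$totalReadBp, 310)
  expect_equal(unname(r$unitBp[canonicalMonomer("AT")]), 220)
  expect_equal(unname(r$unitBp[canonicalMonomer("ACT")]), 90)
})

test_that("aggregateProfiles reads FASTQ and unitAbundance normalizes", {
  set.seed(42)
  genome <- c(chr = plantIn(randomDNA(5000), strrep("AAAACGTATT", 100), 2000))
  fq <- tempfile(fileext = ".fastq")
  generateReads(genome, coverage = 5, readLen = 100, errRate = 0,
                sampleIdent = "s1", fastqPath = fq)
  prof <- aggregateProfiles(fq, "s1")
  expect_s4_class(prof, "KmerSatProfile")
  expect_identical(sampleId(prof), "s1")
  u <- canonicalMonomer("AAAACGTATT")
  expect_true(u %in% names(unitAbundance(prof)))
  expect_equal(unname(unitAbundance(prof, perGb = TRUE)[u]),
               unname(unitAbundance(prof)[u]) * 1e9 / prof@totalReadBp)
  expect_error(aggregateProfiles(character(0), "empty"),
               "zero parseable reads")
})

test_that("compareProfiles applies the abundance floor and pseudocount ratio", {
  mk <- function(id, bp) new("KmerSatProfile", sampleId = id,
                             unitBp = bp, readsScanned = 1000,
                             totalReadBp = 1e6)
  germ <- mk("g", c(AAAAC = 50, AAAT = 11))
  soma <- mk("s", c(AAAAC = 49, AAAT = 1))
  # per-Gb: AAAAC 5e7 vs 4.9e7 (ratio ~1, not enriched);
  # AAAT 1.1e7 vs 1e6 (ratio ~11, abundance 11000 kb/Gb -> enriched)
  cmp <- compareProfiles(germ, soma)
  expect_identical(cmp$enriched, "AAAT")
  expect_true("AAAAC" %in% cmp$abundant_soma)
  expect_equal(cmp$table$ratio_germ_over_soma,
               cmp$table$germ_bp_per_gb / (cmp$table$soma_bp_per_gb + 1))
  # identical samples: nothing enriched at ratio >= 5
  cmp2 <- compareProfiles(germ, germ)
  expect_length(cmp2$enriched, 0)
  zero <- new("KmerSatProfile", sampleId = "z", unitBp = numeric(),
              readsScanned = 0, totalReadBp = 0)
  expect_error(compareProfiles(germ, zero), "empty sample")
})

test_that("writeProfile emits a parseable TSV with header comments", {
  prof <- new("KmerSatProfile", sampleId = "p", unitBp = c(AC = 1000),
              readsScanned = 10, totalReadBp = 2000)
  path <- tempfile(fileext = ".tsv")
  writeProfile(prof, path, header = "provenance")
  lines <- readLines(path)
  expect_identical(lines[1], "# provenance")
  expect_identical(lines[2], "unit\tbp\tbp_per_gb")
  f <- strsplit(lines[3], "\t")[[1]]
  expect_identical(f[1], "AC")
  expect_equal(as.numeric(f[3]), 1000 * 1e9 / 2000)
})
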