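test_that("randomDNA and mutateMonomer behave as documented", {
  set.seed(71)
  s <- randomDNA(10000, gc = 0.3)
  expect_identical(nchar(s), 10000L)
  expect_true(grepl("^[ACGT]+$", s))
  expect_equal(gcContent(s), 0.3, tolerance = 0.02)
  m <- randPrimitive(200)
  expect_identical(mutateMonomer(m, 0, 0), m)
  set.seed(72)
  muts <- vapply(1:50, function(i) {
    x <- mutateMonomer(m, subRate = 0.1)
    sum(strsplit(x, "")[[1]] != strsplit(m, "")[[1]])
  }, numeric(1))
  expect_equal(mean(muts) / 200, 0.1, tolerance = 0.15)
  expect_error(mutateMonomer(m, subRate = 0.5), "subRate")
})

test_that("plantedFamily and syntheticSpec validate their inputs", {
  arr <- data.frame(contig = "c1", start = 100L, copies = 10)
  expect_error(plantedFamily("f", strrep("AC", 5), arr), "primitive")
  pf <- plantedFamily("f", "AAAACGTATT", arr)
  expect_s3_class(pf, "plantedFamily")
  ctg <- data.frame(name = "c1", length = 1000L, gc = 0.4)
  expect_error(syntheticSpec(ctg, list(pf), lContigs = "missing"))
  pf2 <- plantedFamily("g", "ACGGT",
                       data.frame(contig = "nope", start = 1L, copies = 2))
  expect_error(syntheticSpec(ctg, list(pf2)), "unknown contigs")
})

test_that("generateGenome plants arrays at manifest coordinates", {
  mono <- "AAAACGTATT"
  pf <- plantedFamily("fam10", mono,
                      data.frame(contig = c("c1", "cL"),
                                 start = c(200L, 50L), copies = c(30, 20)))
  spec <- syntheticSpec(
    data.frame(name = c("c1", "cL"), length = c(1000L, 500L), gc = 0.4),
    planted = list(pf), lContigs = "cL", seed = 7L)
  g <- generateGenome(spec)
  expect_setequal(names(g$germ), c("c1", "cL"))
  expect_identical(names(g$soma), "c1")
  man <- g$manifest
  expect_equal(nrow(man), 2)
  for (i in 1:2) {
    ctg <- as.character(g$germ[[man$contig[i]]])
    planted <- substr(ctg, man$start[i] + 1L, man$end[i])  # 0-based half-open
    expect_identical(planted, strrep(mono, man$copies[i]))
  }
  expect_equal(unname(g$familyBp$germ["fam10"]), 500)
  expect_equal(unname(g$familyBp$soma["fam10"]), 300)
  # determinism under the manifest seed
  g2 <- generateGenome(spec)
  expect_identical(as.character(g$germ), as.character(g2$germ))
})

test_that("generateReads draws the documented number of reads", {
  set.seed(73)
  genome <- c(chr = randomDNA(20000))
  reads <- generateReads(genome, coverage = 3, readLen = 100, errRate = 0)
  expect_equal(length(reads), round(3 * 20000 / 100))
  expect_true(all(Biostrings::width(reads) == 100))
  # error-free reads are exact substrings of the genome or its RC
  both <- paste0(genome, "NN", bruteRevcomp(unname(genome)))
  idx <- sample(length(reads), 10)
  expect_true(all(vapply(as.character(reads[idx]), grepl, logical(1),
                         x = both, fixed = TRUE)))
  fq <- tempfile(fileext = ".fastq")
  set.seed(73)
  generateReads(genome, coverage = 1, fastqPath = fq)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(length(back), round(20000 / 100))
})

test_that("scoreRecovery scores matched families and abundance error", {
  set.seed(74)
  mono <- c(f1 = randPrimitive(30), f2 = randPrimitive(80))
  set <- clusterMonomers(S4Vectors::DataFrame(
    monomer = vapply(mono, canonicalMonomer, character(1),
                     USE.NAMES = FALSE),
    weight_bp = c(3000, 8000)))
  set <- nameFamilies(set)
  ab <- data.frame(family_id = familyIds(set),
                   total_kb = unname(familyTotalBp(set)) / 1000)
  truthBp <- c(f1 = 3000, f2 = 8000)
  sc <- scoreRecovery(truthBp, mono, set, ab)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_true(all(sc$perFamily$consensus_identity == 1))
  expect_true(all(abs(sc$perFamily$rel_abundance_error) < 1e-9))
  # one planted family missing from the report: recall drops, precision not
  truth2 <- c(truthBp, f3 = 1000)
  mono2 <- c(mono, f3 = randPrimitive(55))
  sc2 <- scoreRecovery(truth2, mono2, set, ab)
  expect_equal(sc2$recall, 2 / 3)
  expect_equal(sc2$precision, 1)
})
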