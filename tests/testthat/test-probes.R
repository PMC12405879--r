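test_that("validateProbes checks length, alphabet and homopolymers", {
  v <- validateProbes(c(strrep("ACT", 10),        # 30 nt, valid
                        strrep("ACT", 14),        # 42 nt, too long
                        paste0(strrep("A", 9), strrep("CGT", 7)),  # homo 9
                        paste0(strrep("AC", 14), "NX")))           # alphabet
  expect_identical(v$valid, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(v$length_ok, c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(v$alphabet_ok, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(v$homopolymer_ok, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(v$max_homopolymer[3], 9)
})

test_that("short units give whole-copy concatemer probes", {
  p <- designFamilyProbe("AAAACGTATT", familyId = "f")
  expect_identical(nchar(p$probe_seq), 30L)
  expect_identical(p$probe_seq, strrep("AAAACGTATT", 3))
  expect_equal(p$on_target_max_mismatch, 0)
})

test_that("designFamilyProbe picks a window minimizing worst-case mismatch", {
  set.seed(61)
  cons <- randPrimitive(120)
  members <- vapply(1:10, function(i) mutateMonomer(cons, subRate = 0.02),
                    character(1))
  p <- designFamilyProbe(cons, members, familyId = "f")
  expect_gte(nchar(p$probe_seq), 30)
  expect_lte(nchar(p$probe_seq), 40)
  expect_gte(p$gc, 0.15); expect_lte(p$gc, 0.65)
  # the probe window really is a circular window of the consensus
  expect_true(grepl(p$probe_seq, strrep(cons, 2), fixed = TRUE))
  # reported worst-case on-target mismatch is attained, not exceeded
  worst <- max(vapply(members, function(m)
    satmine:::.minTandemMismatch(p$probe_seq, m), numeric(1)))
  expect_equal(p$on_target_max_mismatch, worst)
  expect_error(designFamilyProbe(strrep("A", 100)), "no feasible probe")
})

test_that("designVariantProbes discriminates the printed 37 bp A/B pair", {
  probes <- bcopSatProbes()
  p37 <- probes[probes$family == "BcopSat-37", ]
  res <- designVariantProbes(p37$probe_seq[p37$variant == "A"],
                             p37$probe_seq[p37$variant == "B"],
                             familyId = "BcopSat-37")
  expect_identical(res$variant_label, c("A", "B"))
  expect_true(all(res$off_target_min_mismatch >= 3))
  # and errors when the variants cannot be told apart
  expect_error(designVariantProbes(strrep("ACGGT", 8), strrep("ACGGT", 8)),
               "not discriminable")
})

test_that("probeHitMap finds planted hits on both strands", {
  set.seed(62)
  probe <- randSeq(32)
  seqs <- c(s1 = plantIn(randSeq(300, c("G", "T")), probe, 100),
            s2 = plantIn(randSeq(300, c("G", "T")), bruteRevcomp(probe), 50))
  hits <- probeHitMap(probe, seqs)
  expect_equal(nrow(hits), 2)
  h1 <- hits[hits$seq_id == "s1", ]
  expect_equal(h1$position, 101)   # planted at 0-based 100
  expect_identical(h1$strand, "+")
  h2 <- hits[hits$seq_id == "s2", ]
  expect_identical(h2$strand, "-")
  expect_equal(h2$mismatches, 0)
  # mismatch tolerance
  probe2 <- probe; substr(probe2, 5, 5) <- "C"
  expect_equal(nrow(probeHitMap(probe2, seqs["s1"])), 0)
  expect_equal(probeHitMap(probe2, seqs["s1"], maxMismatch = 1)$mismatches, 1)
})

test_that("tandem mismatch counting is circular and strand-aware", {
  u <- "ACGGTTACGT"
  # a probe crossing the monomer junction still scores 0
  junction <- substr(strrep(u, 4), 6, 37)
  expect_equal(satmine:::.minTandemMismatch(junction, u), 0)
  expect_equal(satmine:::.minTandemMismatch(bruteRevcomp(junction), u), 0)
})

test_that("the published probe fixture loads completely", {
  probes <- bcopSatProbes()
  expect_equal(nrow(probes), 14)
  expect_identical(names(probes),
                   c("family", "variant", "unit_len", "probe_seq"))
  expect_true(all(grepl("^[ACGT]+$", probes$probe_seq)))
})
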