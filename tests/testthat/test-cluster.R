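test_that("monomersFromArrays canonicalizes and aggregates by weight", {
  arr <- data.frame(contig = "c", start = c(0L, 500L, 900L),
                    end = c(300L, 700L, 1000L),
                    unit_len = 10L, copies = 10,
                    mean_identity = 1, score = 100,
                    unit_seq = c("AAAACGTATT", "GTATTAAAAC", "ACGTTACGGT"),
                    stringsAsFactors = FALSE)
  m <- monomersFromArrays(arr)
  expect_equal(nrow(m), 2)     # two rotations of one monomer aggregate
  expect_identical(m$monomer[1], canonicalMonomer("AAAACGTATT"))
  expect_equal(m$weight_bp[1], 500)  # 300 + 200 bp
  expect_equal(m$weight_bp[2], 100)
})

test_that("clusterMonomers groups rotations/RCs and splits dissimilar units", {
  set.seed(31)
  a <- randPrimitive(30)
  b <- randPrimitive(60)
  mono <- c(canonicalMonomer(a),
            canonicalMonomer(mutateMonomer(a, subRate = 0.05)),
            canonicalMonomer(bruteRevcomp(a)),
            canonicalMonomer(b))
  set <- clusterMonomers(mono)
  expect_s4_class(set, "SatelliteFamilySet")
  expect_equal(length(set), 2)
  mem <- familyMembers(set)
  expect_equal(sum(mem$family_id == mem$family_id[mem$monomer ==
                                                    canonicalMonomer(a)][1]), 3)
})

test_that("families are ordered by decreasing total bp with provisional ids", {
  light <- strrep("ACGGT", 5)   # 25 bp unit
  heavy <- strrep("AACGGTT", 5) # 35 bp unit
  m <- S4Vectors::DataFrame(
    monomer = c(canonicalMonomer(light), canonicalMonomer(heavy)),
    weight_bp = c(100, 10000))
  set <- clusterMonomers(m)
  expect_identical(familyIds(set), c("F1", "F2"))
  expect_equal(unname(familyTotalBp(set)), c(10000, 100))
  expect_identical(as.character(consensusSeqs(set)[["F1"]]),
                   canonicalMonomer(heavy))
})

test_that("buildConsensus recovers the ancestor from mutated copies", {
  set.seed(32)
  anc <- randPrimitive(60)
  copies <- vapply(1:30, function(i) mutateMonomer(anc, subRate = 0.04),
                   character(1))
  cons <- buildConsensus(copies, representative = anc)
  expect_identical(cons, canonicalMonomer(anc))
  # and still recovers it when members arrive rotated
  rot <- vapply(copies, function(x) sample(bruteRotations(x), 1), character(1))
  cons2 <- buildConsensus(unname(rot), representative = anc)
  expect_identical(cons2, canonicalMonomer(anc))
})

test_that("splitVariants calls A/B only when both shares qualify", {
  set.seed(33)
  base <- randPrimitive(50)
  vb <- base
  for (p in c(5L, 20L, 35L))  # 3 fixed diagnostic positions
    substr(vb, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(base, p, p))[1]
  memA <- vapply(1:12, function(i)
    canonicalMonomer(mutateMonomer(base, subRate = 0.01)), character(1))
  memB <- vapply(1:8, function(i)
    canonicalMonomer(mutateMonomer(vb, subRate = 0.01)), character(1))
  v <- splitVariants(c(memA, memB), weights = rep(50, 20))
  expect_equal(nrow(v), 2)
  expect_identical(as.character(v$label), c("A", "B"))
  expect_gte(v$share[1], v$share[2])
  expect_true(all(v$share >= 0.2))
  expect_lte(sum(v$share), 1 + 1e-9)
  expect_gte(length(strsplit(v$diagnostic_positions[2], ",")[[1]]), 3)
  # a 10% minority does not qualify at the default 20% share floor
  v2 <- splitVariants(c(memA, memB), weights = c(rep(90, 12), rep(15, 8)))
  expect_equal(nrow(v2), 0)
})

test_that("detectVariants attaches family ids and validates", {
  set.seed(34)
  base <- randPrimitive(40)
  vb <- base
  for (p in c(5L, 18L, 31L))   # guarantee 3 real differences
    substr(vb, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(base, p, p))[1]
  mono <- c(canonicalMonomer(base), canonicalMonomer(vb))
  set <- clusterMonomers(S4Vectors::DataFrame(monomer = mono,
                                              weight_bp = c(600, 400)))
  expect_equal(length(set), 1)
  set <- detectVariants(set)
  v <- familyVariants(set)
  expect_equal(nrow(v), 2)
  expect_true(all(v$family_id == familyIds(set)[1]))
})

test_that("nameFamily and nameFamilies apply the naming convention", {
  expect_identical(nameFamily("Bcop", 145), "BcopSat-145")
  expect_identical(nameFamily("Bcop", 155, "BcopSat-155"), "BcopSat-155b")
  expect_identical(nameFamily("Bcop", 155, c("BcopSat-155", "BcopSat-155b")),
                   "BcopSat-155c")
  # one A/T-only and one G/C-only unit: rotational identity is 0 (the
  # reverse complement of a G/C string is still G/C-only)
  u1 <- "AATATTATAATTTATATTAAATATT"
  u2 <- "GGCGCCGCGGCCCGCGCCGGGCGCC"
  expect_lt(rotationalIdentity(u1, u2), 0.8)
  set <- clusterMonomers(S4Vectors::DataFrame(
    monomer = c(canonicalMonomer(u1), canonicalMonomer(u2)),
    weight_bp = c(1000, 500)))
  set <- nameFamilies(set, "Test")
  expect_identical(familyIds(set), c("TestSat-25", "TestSat-25b"))
  expect_true(all(familyMembers(set)$family_id %in% familyIds(set)))
})
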