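# A tiny hand-built family set + arrays used across several blocks.
.toyFamilies <- function() {
  u1 <- canonicalMonomer("AAAACGTATT")
  u2 <- canonicalMonomer("ACGGTTACCGTAACCGGTTA")
  set <- clusterMonomers(S4Vectors::DataFrame(monomer = c(u1, u2),
                                              weight_bp = c(2000, 1000)))
  nameFamilies(set, "Toy")
}

.toyArrays <- function() {
  data.frame(contig = c("c1", "c1", "c2"),
             start = c(100L, 800L, 0L),
             end = c(1100L, 1800L, 1000L),
             unit_len = c(10L, 10L, 20L),
             copies = c(100, 100, 50),
             mean_identity = c(0.98, 0.95, 1),
             score = 500,
             unit_seq = c("AAAACGTATT", "GTATTAAAAC",
                          "ACGGTTACCGTAACCGGTTA"),
             stringsAsFactors = FALSE)
}

test_that("assignArrays maps arrays onto their families", {
  set <- .toyFamilies()
  arr <- assignArrays(.toyArrays(), set)
  expect_identical(arr$family[1], arr$family[2])   # same canonical monomer
  expect_false(arr$family[1] == arr$family[3])
  expect_true(all(arr$family %in% familyIds(set)))
})

test_that("arraysToBed writes sorted 0-based BED6 with clamped scores", {
  set <- .toyFamilies()
  arr <- assignArrays(.toyArrays(), set)
  bed <- arraysToBed(arr)
  expect_identical(names(bed),
                   c("chrom", "start", "end", "name", "score", "strand"))
  expect_identical(bed$start, c(100L, 800L, 0L))
  expect_identical(bed$score, c(98L, 95L, 100L))
  expect_true(all(bed$strand == "+"))
  path <- tempfile(fileext = ".bed")
  arraysToBed(arr, path, header = "hdr line")
  lines <- readLines(path)
  expect_identical(lines[1], "# hdr line")
  fields <- strsplit(lines[-1], "\t")
  expect_true(all(lengths(fields) == 6))
  expect_identical(vapply(fields, `[`, character(1), 2), c("100", "800", "0"))
  expect_error(arraysToBed(data.frame(contig = "c", start = 5L, end = 5L,
                                      mean_identity = 1)),
               "interval invalid")
})

test_that("familyAbundance merges overlapping same-family arrays", {
  set <- .toyFamilies()
  arr <- assignArrays(.toyArrays(), set)
  # arrays 1 and 2 overlap on c1 (100-1100, 800-1800): merged width 1700
  rec <- familyAbundance(set, arr, assemblyBp = 100000)
  f10 <- rec[rec$unit_len == 10, ]
  expect_equal(f10$total_kb, 1.7)
  expect_equal(f10$n_arrays, 2)
  expect_equal(f10$array_size_min_kb, 1.7)
  expect_equal(f10$pct_assembly, 1700 / 100000)
  f20 <- rec[rec$unit_len == 20, ]
  expect_equal(f20$total_kb, 1)
  expect_equal(f20$gc_content, gcContent("ACGGTTACCGTAACCGGTTA"))
  expect_identical(rec$family_id, rec$family_id[order(-rec$total_kb)])
})

test_that("selectAbundant keeps the boundary", {
  rec <- data.frame(family_id = c("a", "b", "c"),
                    total_kb = c(199.99, 200, 200.01))
  expect_identical(selectAbundant(rec)$family_id, c("b", "c"))
  expect_equal(nrow(selectAbundant(rec, minKb = 1000)), 0)
})

test_that("renderFamilyTable formats sizes, amounts, GC and probes", {
  rec <- data.frame(family_id = "ToySat-37", unit_len = 37L, n_arrays = 5L,
                    array_size_min_kb = 0.8, array_size_max_kb = 122.4,
                    total_kb = 1923.4, pct_assembly = 0.0062,
                    gc_content = 9 / 37, gc_variants = "",
                    stringsAsFactors = FALSE)
  lines <- renderFamilyTable(rec)
  expect_identical(lines[1],
                   paste("family", "monomer_length_bp", "array_size_kb",
                         "amount_in_assembly_kb", "gc_content", "probes",
                         sep = "\t"))
  f <- strsplit(lines[2], "\t")[[1]]
  expect_identical(f[3], "0.8–122")
  expect_identical(f[4], "1,923(0.62%)")
  expect_identical(f[5], "24.32%")
  # variant GCs render side by side; probes listed with variant labels
  rec$gc_variants <- "0.2432;0.2432"
  probes <- data.frame(family_id = "ToySat-37", variant_label = c("A", "B"),
                       probe_seq = c("AAA", "CCC"))
  f2 <- strsplit(renderFamilyTable(rec, probes)[2], "\t")[[1]]
  expect_identical(f2[5], "24.32% / 24.32%")
  expect_identical(f2[6], "A:AAA B:CCC")
})
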