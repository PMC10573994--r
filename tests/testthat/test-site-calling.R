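test_that("k-mer index reports locus multiplicity faithfully", {
  g <- small_genome()
  idx <- small_index()
  # a 31-mer from single-copy sequence occurs once
  q <- substring(g$seq[["chrN1"]], 10001, 10031)
  expect_equal(length(idx$env[[q]]), 1L)
  # a 31-mer inside the p12 tandem repeat occurs once per copy
  rep_km <- substring(g$seq[["chrA1"]], 5101, 5131)
  expect_equal(length(idx$env[[rep_km]]), 20L)
})

test_that("mapping reports the junction TA coordinate on either strand", {
  g <- small_genome()
  idx <- small_index()
  ta <- g$ta[g$ta$chrom == "chrN1" & g$ta$pos > 16000 &
               g$ta$pos < 25000, ]
  pos <- ta$pos[1]
  fwd <- substring(g$seq[["chrN1"]], pos + 1L, pos + 120L)
  m <- map_junction(fwd, idx, "unique")
  expect_true(m$mapped)
  expect_equal(m$chrom, "chrN1")
  expect_equal(m$position, pos)
  expect_equal(m$strand, "+")
  expect_equal(m$far_end, pos + 120L)
  # the same junction read in the opposite orientation: a flank running
  # leftwards whose reverse complement starts with the duplicated TA
  rev <- sbsites:::revcomp1(substring(g$seq[["chrN1"]], pos - 117L, pos + 2L))
  m2 <- map_junction(rev, idx, "unique")
  expect_true(m2$mapped)
  expect_equal(m2$position, pos)
  expect_equal(m2$strand, "-")
  expect_equal(m2$far_end, pos - 118L)
})

test_that("unique mode rejects repeat reads that random mode resolves", {
  g <- small_genome()
  idx <- small_index()
  rd <- substring(g$seq[["chrA2"]], 5051, 5350) # inside the 20-copy repeat
  mu <- map_junction(rd, idx, "unique")
  expect_false(mu$mapped)
  expect_equal(mu$reason, "multimapping")
  expect_equal(mu$n_candidate_loci, 20L)
  withr::with_seed(1L, {
    mr <- map_junction(rd, idx, "random")
    expect_true(mr$mapped)
    expect_equal(mr$n_candidate_loci, 20L)
  })
  # random assignment is uniform over the tied loci
  withr::with_seed(2L, {
    picks <- vapply(1:2000, function(i)
      map_junction(rd, idx, "random")$position, integer(1))
  })
  tb <- table(picks)
  expect_equal(length(tb), 20L)
  expect_true(all(abs(tb - 100) <= 3 * sqrt(2000 * (1 / 20) * (19 / 20))))
})

test_that("mismatched reads map within the Hamming budget only", {
  g <- small_genome()
  idx <- small_index()
  rd <- substring(g$seq[["chrN2"]], 8001, 8150) # 150 nt, budget 7
  flipat <- function(s, at) {
    for (i in at) substr(s, i, i) <- chartr("ACGT", "TGCA", substr(s, i, i))
    s
  }
  ok <- map_junction(flipat(rd, 40:46), idx, "unique") # 7 mismatches
  expect_true(ok$mapped)
  expect_equal(ok$position, 8000L)
  bad <- map_junction(flipat(rd, 40:47), idx, "unique") # 8 mismatches
  expect_false(bad$mapped)
})

test_that("support counts distinct shear keys against the threshold", {
  g <- small_genome()
  pos <- g$ta$pos[g$ta$chrom == "chrN1"][10]
  mk <- function(n_keys, n_extra_dup = 0L) {
    keys <- c(sprintf("k%02d", seq_len(n_keys)),
              rep("k01", n_extra_dup))
    data.frame(id = sprintf("r%02d", seq_along(keys)), chrom = "chrN1",
               position = pos, strand = "+", n_candidate_loci = 1L,
               shear_key = keys, far_end = pos + 100L,
               stringsAsFactors = FALSE)
  }
  # 5 distinct shear keys: called at min_support = 5
  s5 <- call_sites(mk(5L), g, min_support = 5L, mode = "unique")
  expect_equal(nrow(s5), 1L)
  expect_equal(s5$support, 5L)
  expect_true(s5$on_ta)
  # 4 distinct keys are never enough, extra copies of one key don't help
  expect_equal(nrow(call_sites(mk(4L, 3L), g, min_support = 5L,
                               mode = "unique")), 0L)
  # the random regime accepts a single supporting read
  s1 <- call_sites(mk(1L), g, min_support = 1L, mode = "random")
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$mode, "random")
})

test_that("strands pool and off-TA positions are flagged", {
  g <- small_genome()
  pos <- g$ta$pos[g$ta$chrom == "chrN1"][20]
  mapped <- data.frame(
    id = c("a", "b", "c"),
    chrom = "chrN1",
    position = c(pos, pos, pos + 1L), # pos+1 is not a TA start
    strand = c("+", "-", "+"),
    n_candidate_loci = 1L,
    shear_key = c("x", "y", "z"),
    far_end = 1L, stringsAsFactors = FALSE)
  out <- call_sites(mapped, g, min_support = 2L, mode = "unique")
  expect_equal(nrow(out), 1L) # the off-TA singleton is below support 2
  expect_equal(out$support, 2L) # + and - reads pooled
  out1 <- call_sites(mapped, g, min_support = 1L, mode = "unique")
  expect_equal(nrow(out1), 2L)
  expect_equal(sum(!out1$on_ta), 1L)
})

test_that("site calling is invariant to read order", {
  g <- small_genome()
  idx <- small_index()
  p <- clean_params()
  truth <- unique_region_truth(g, 40L, 6L, seed = 61L)
  lib <- simulate_junction_library(truth, g, p, "SB100X", seed = 1)
  junc <- process_reads(lib, p, p$barcode_map[["SB100X"]])
  shuf <- junc[withr::with_seed(3L, sample.int(nrow(junc))), ]
  s1 <- call_sites(map_junctions(junc, idx, "unique", seed = 5), g, 5L,
                   "unique")
  s2 <- call_sites(map_junctions(shuf, idx, "unique", seed = 5), g, 5L,
                   "unique")
  expect_equal(s1, s2)
})
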