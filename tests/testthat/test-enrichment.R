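gr <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

test_that("peak expansion pads, clamps and merges", {
  g <- small_genome()
  out <- expand_peaks(gr("chrN1", 1000L, 1100L), 500L, g)
  expect_equal(GenomicRanges::start(out) - 1L, 500L)
  expect_equal(GenomicRanges::end(out), 1600L)
  # clamped at the chromosome start
  out2 <- expand_peaks(gr("chrN1", 100L, 200L), 500L, g)
  expect_equal(GenomicRanges::start(out2) - 1L, 0L)
  expect_equal(GenomicRanges::end(out2), 700L)
  # expansion-induced overlaps merge into one interval
  out3 <- expand_peaks(c(gr("chrN1", 0L, 100L), gr("chrN1", 900L, 1000L)),
                       500L, g)
  expect_equal(length(out3), 1L)
  expect_equal(GenomicRanges::end(out3), 1500L)
})

test_that("site counting is half-open and counts each site once", {
  sites <- data.frame(chrom = "chrN1", pos = c(499L, 500L))
  reg <- gr("chrN1", 0L, 500L)
  expect_equal(count_in_regions(sites, reg), 1L)
  # overlapping regions don't double-count
  reg2 <- c(gr("chrN1", 0L, 500L), gr("chrN1", 400L, 600L))
  expect_equal(count_in_regions(sites, reg2), 2L)
  g <- small_genome()
  expect_error(count_in_regions(data.frame(chrom = "chrX", pos = 1L),
                                reg, g), "chrX")
})

test_that("counts over random sites follow the regions' coverage", {
  g <- small_genome()
  ins <- simulate_insertions(g, target_model(), 1000, seed = 71L)
  reg <- region_by_label(g, "q") # the big uniform-density arms
  ta_in <- sum(sbsites:::site_in_region(g, reg))
  p <- ta_in / nrow(g$ta)
  expect_lt(abs(count_in_regions(ins, reg, g) - 1000 * p),
            3 * sqrt(1000 * p * (1 - p)) + 1)
  # subadditivity with equality iff disjoint
  r1 <- region_by_label(g, "p13")
  r2 <- region_by_label(g, "p11.2")
  expect_equal(count_in_regions(ins, c(r1, r2)),
               count_in_regions(ins, r1) + count_in_regions(ins, r2))
  rov <- c(gr("chrN1", 0L, 20000L), gr("chrN1", 10000L, 30000L))
  expect_lte(count_in_regions(ins, rov),
             count_in_regions(ins, rov[1]) + count_in_regions(ins, rov[2]))
})

test_that("the exact test reproduces its defining examples", {
  r <- enrichment_test(100, 1000, 100, 1000)
  expect_equal(r$pct_increase, 0)
  expect_equal(r$p_value, 1)
  expect_equal(enrichment_test(100, 10000, 164, 10000)$pct_increase, 64)
  # exhaustive enumeration oracle on a small table
  r2 <- enrichment_test(1, 20, 6, 20)
  expect_equal(r2$p_value, fisher_enum_oracle(1, 20, 6, 20),
               tolerance = 1e-12)
  # zero-in-A sentinel
  r3 <- enrichment_test(0, 50, 5, 50)
  expect_identical(r3$pct_increase, Inf)
  expect_true(r3$p_value > 0 && r3$p_value <= 1)
  # scale invariance of the effect size
  expect_equal(enrichment_test(30, 300, 45, 300)$pct_increase,
               enrichment_test(300, 3000, 450, 3000)$pct_increase)
})

test_that("the exact test agrees with the standard implementation", {
  withr::with_seed(11L, {
    for (i in 1:100) {
      tA <- sample(1:200, 1); tB <- sample(1:200, 1)
      a <- sample(0:tA, 1); b <- sample(0:tB, 1)
      expect_equal(enrichment_test(a, tA, b, tB)$p_value,
                   stats::fisher.test(matrix(c(a, tA - a, b, tB - b), 2,
                                             byrow = TRUE))$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("condition comparison spans the region sets and filters off-TA", {
  g <- small_genome()
  ins <- simulate_insertions(g, target_model(), 3000, seed = 72L)
  sets <- standard_region_sets(g)
  res <- compare_conditions(ins, ins, sets, g)
  expect_equal(res$region_label, names(sets))
  expect_true(all(res$pct_increase == 0 | is.na(res$pct_increase)))
  expect_true(all(res$p_value == 1))
  # off-TA flagged sites are excluded from totals
  sA <- data.frame(chrom = ins$chrom, pos = ins$pos,
                   on_ta = rep(c(TRUE, FALSE), length.out = nrow(ins)))
  res2 <- compare_conditions(sA, sA, sets["acro_p_arm"], g)
  expect_equal(res2$total_A, sum(sA$on_ta))
  expect_error(compare_conditions(ins[0, ], ins, sets, g), "empty")
})

test_that("expected percent increase is monotone in the region bias", {
  g <- small_genome()
  base <- simulate_insertions(g, target_model(), 20000, seed = 73L)
  reg <- list(acro_p_arm = region_by_label(g, "acro_p_arm"))
  pct <- vapply(c(1, 1.5, 2, 3), function(theta) {
    m <- target_model(region_bias = list(acro_p_arm = theta))
    ins <- simulate_insertions(g, m, 20000, seed = 74L + round(10 * theta))
    compare_conditions(base, ins, reg, g)$pct_increase
  }, numeric(1))
  expect_true(all(diff(pct) > 0))
})

test_that("RPKM profile implements its normalization exactly", {
  # all 100 sites in the first 1 kb window, total 10000 sites
  reg <- list(chrom = "c", start = 0L, end = 300000L)
  sites <- data.frame(chrom = "c", pos = rep(10L, 100))
  pr <- binned_rpkm_profile(sites, reg, n_bins = 300L, total_sites = 10000)
  expect_s3_class(pr, "BinnedProfile")
  expect_equal(nrow(pr), 300L)
  expect_equal(pr$rpkm[1], 100 / 1 / (10000 / 1e6)) # 10,000
  expect_true(all(pr$rpkm[-1] == 0))
  expect_equal(sum(pr$count), 100L)
  # remainder is spread over the leading windows
  reg2 <- list(chrom = "c", start = 0L, end = 301L)
  pr2 <- binned_rpkm_profile(data.frame(chrom = "c", pos = 0L), reg2,
                             n_bins = 300L, total_sites = 1)
  expect_equal(diff(pr2$end - pr2$start)[1], -1L) # first window is wider
  expect_equal(sum(pr2$end - pr2$start), 301L)
  expect_error(binned_rpkm_profile(sites, list(chrom = "c", start = 0L,
                                               end = 100L), 300L, 1),
               "fewer bins")
})

test_that("RPKM values are invariant under proportional depth scaling", {
  g <- small_genome()
  ins <- simulate_insertions(g, target_model(), 2000, seed = 75L)
  band <- g$cytobands[S4Vectors::mcols(g$cytobands)$label == "p13"][1]
  pr1 <- binned_rpkm_profile(ins, band, 300L, total_sites = 2000)
  doubled <- rbind(ins, ins)
  pr2 <- binned_rpkm_profile(doubled, band, 300L, total_sites = 4000)
  expect_equal(pr2$count, 2L * pr1$count)
  expect_equal(pr2$rpkm, pr1$rpkm)
})

test_that("TA density profile counts overlapping dinucleotides and scales", {
  # one chromosome of three 6-bp windows: TATATA | GGGGGG | TATATA
  g <- toy_genome(c(c1 = paste0("TATATA", "GGGGGG", "TATATA")))
  td <- suppressWarnings( # loess protests at so few windows
    ta_density_profile(g, list(chrom = "c1", start = 0L, end = 18L),
                       n_bins = 3L, loess_span = 1))
  expect_equal(td$count, c(3L, 0L, 3L))
  expect_equal(td$scaled, c(1, 0, 1))
  # constant density scales to 0.5 by convention
  g2 <- toy_genome(c(c1 = strrep("TAGG", 60)))
  td2 <- suppressWarnings(
    ta_density_profile(g2, list(chrom = "c1", start = 0L, end = 240L),
                       n_bins = 3L, loess_span = 1))
  expect_equal(td2$scaled, rep(0.5, 3))
})
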