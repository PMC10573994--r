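make_pairs <- function(seq1, seq2 = strrep("G", 150)) {
  n <- length(seq1)
  data.frame(id = sprintf("r%03d", seq_len(n)), seq1 = seq1,
             qual1 = strrep("I", nchar(seq1)),
             seq2 = rep_len(seq2, n), qual2 = strrep("I", nchar(seq2)),
             stringsAsFactors = FALSE)
}

test_that("demultiplexing assigns by exact barcode prefix", {
  bc <- c(S1 = "ACGTAC", S2 = "TGCATG")
  pairs <- make_pairs(c(paste0("ACGTAC", strrep("A", 50)),
                        paste0("TGCATG", strrep("A", 50)),
                        paste0("GGGGGG", strrep("A", 50))))
  out <- demultiplex(pairs, bc)
  expect_equal(attr(out, "counts"),
               c(S1 = 1L, S2 = 1L, undetermined = 1L))
  expect_equal(out$S1$id, "r001")
  expect_equal(out$undetermined$id, "r003")
  expect_error(demultiplex(pairs, c(S1 = "ACGTAC", S2 = "ACGTAC")),
               "duplicate")
  expect_error(demultiplex(pairs, c(S1 = "ACGTAC", S2 = "TG")),
               "equal length")
})

test_that("demultiplexing recovers a shuffled two-sample library fully", {
  g <- small_genome()
  p <- clean_params()
  t1 <- unique_region_truth(g, 50L, 2L, seed = 51L)
  t2 <- unique_region_truth(g, 50L, 2L, seed = 52L)
  l1 <- simulate_junction_library(t1, g, p, "SB100X", seed = 1)
  l2 <- simulate_junction_library(t2, g, p, "B23-SB100X", seed = 2)
  pool <- rbind(l1, l2)
  pool <- pool[withr::with_seed(9L, sample.int(nrow(pool))), ]
  out <- demultiplex(pool, p$barcode_map)
  expect_equal(nrow(out[["SB100X"]]), nrow(l1))
  expect_equal(nrow(out[["B23-SB100X"]]), nrow(l2))
  expect_equal(nrow(out$undetermined), 0L)
})

test_that("primer filter draws the line at exactly six mismatches", {
  primer <- strrep("ACGT", 5) # 20 nt
  flip <- function(s, k) {
    # flip the first k primer bases to their complement
    paste0(chartr("ACGT", "TGCA", substr(s, 1, k)),
           substr(s, k + 1, nchar(s)))
  }
  mk <- function(p) paste0(p, strrep("T", 80))
  expect_true(primer_filter(mk(primer), primer)$accept)
  expect_true(primer_filter(mk(flip(primer, 6)), primer)$accept)
  r7 <- primer_filter(mk(flip(primer, 7)), primer)
  expect_false(r7$accept)
  expect_equal(r7$reason, "primer_mismatch")
  expect_equal(primer_filter(mk(primer), primer)$end_offset, 20L)
  short <- primer_filter("ACGTACG", primer)
  expect_false(short$accept)
  expect_equal(short$reason, "too_short")
})

test_that("IR verification enforces amplification specificity", {
  ir <- sbsites:::DEFAULT_IR_SEQUENCE
  primer <- substr(ir, 1, 20)
  flank <- paste0("TA", strrep("C", 100))
  good <- paste0(ir, flank)
  res <- ir_verify_and_trim(good, ir, primer, max_mismatch = 2)
  expect_true(res$accept)
  expect_identical(res$flank, flank)
  expect_equal(res$trim_offset, nchar(ir))

  # one substitution inside the residual IR is inside a budget of 2
  sub1 <- good
  substr(sub1, 25, 25) <- chartr("ACGT", "TGCA", substr(good, 25, 25))
  res1 <- ir_verify_and_trim(sub1, ir, primer, max_mismatch = 2)
  expect_true(res1$accept)
  expect_identical(res1$flank, flank)

  # scrambled residual IR: nonspecific amplification
  scram <- paste0(primer, strrep("A", nchar(ir) - 20), flank)
  res2 <- ir_verify_and_trim(scram, ir, primer, max_mismatch = 2)
  expect_false(res2$accept)
  expect_equal(res2$reason, "nonspecific amplification")
})

test_that("backbone filter discards plasmid-derived flanks only", {
  backbone <- withr::with_seed(5L, sbsites:::random_dna(2000, rep(.25, 4)))
  genome_like <- withr::with_seed(6L, sbsites:::random_dna(500, rep(.25, 4)))
  bb_flank <- substr(backbone, 101, 220)
  bb_rc <- revcomp(substr(backbone, 501, 620))
  keep <- backbone_filter(c(bb_flank, bb_rc, substr(genome_like, 1, 120)),
                          backbone)
  expect_equal(keep, c(FALSE, FALSE, TRUE))
  # too short to judge -> kept
  expect_true(backbone_filter(substr(backbone, 1, 20), backbone))
})

test_that("contaminant fraction is removed at its simulated rate", {
  g <- small_genome()
  p <- library_params(error_rate = 0, pcr_duplication_rate = 0,
                      backbone_fraction = 0.1)
  truth <- unique_region_truth(g, 500L, 4L, seed = 53L)
  lib <- simulate_junction_library(truth, g, p, "SB100X", seed = 3)
  junc <- process_reads(lib, p, p$barcode_map[["SB100X"]])
  st <- attr(junc, "stats")
  frac <- st[["backbone_discard"]] / st[["input"]]
  expect_lt(abs(frac - 0.1), 0.01)
})

test_that("exact-sequence dedup collapses copies but not distinct shears", {
  pairs <- make_pairs(c("AAAA", "AAAA", "AAAA"),
                      c("CCCC", "CCCC", "CCCG"))
  out <- deduplicate_pairs(pairs)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_removed"), 1L)
})

test_that("pair merging reconstructs overlapping fragments exactly", {
  g <- small_genome()
  frag280 <- substring(g$seq[["chrN2"]], 2001, 2280)
  m <- merge_pair(substr(frag280, 1, 150),
                  revcomp(substr(frag280, 131, 280)))
  expect_true(m$merged)
  expect_identical(m$seq, frag280)

  # 400 bp fragment: mates do not overlap, read 1 kept alone
  frag400 <- substring(g$seq[["chrN2"]], 5001, 5400)
  m2 <- merge_pair(substr(frag400, 1, 150),
                   revcomp(substr(frag400, 251, 400)))
  expect_false(m2$merged)
  expect_identical(m2$seq, substr(frag400, 1, 150))
})

test_that("junctions shorter than the minimum length are dropped", {
  p <- clean_params()
  bc <- p$barcode_map[["SB100X"]]
  flank29 <- paste0("TA", strrep("C", 27))
  flank30 <- paste0("TA", strrep("C", 28))
  # mate sequence must not spuriously overlap the C-run of the flank
  pairs <- make_pairs(paste0(bc, p$ir_sequence, c(flank29, flank30)),
                      strrep("T", 40))
  junc <- process_reads(pairs, p, bc)
  expect_equal(nrow(junc), 1L)
  expect_identical(junc$junction, flank30)
  expect_equal(attr(junc, "stats")[["too_short"]], 1L)
})

test_that("processing conserves reads and ignores input order", {
  g <- small_genome()
  p <- library_params(error_rate = 0.001, pcr_duplication_rate = 0.5,
                      backbone_fraction = 0.05)
  truth <- unique_region_truth(g, 150L, 4L, seed = 55L)
  lib <- simulate_junction_library(truth, g, p, "SB100X", seed = 4)
  junc <- process_reads(lib, p, p$barcode_map[["SB100X"]])
  st <- attr(junc, "stats")
  expect_equal(st[["input"]],
               st[["surviving"]] + st[["primer_reject"]] +
                 st[["ir_reject"]] + st[["backbone_discard"]] +
                 st[["duplicate"]] + st[["too_short"]])
  shuf <- lib[withr::with_seed(8L, sample.int(nrow(lib))), ]
  junc2 <- process_reads(shuf, p, p$barcode_map[["SB100X"]])
  expect_equal(junc2[order(junc2$id), ], junc[order(junc$id), ],
               ignore_attr = TRUE)
  # noiseless libraries survive (identical-twin fragments — same site,
  # strand and shear point — legitimately collapse in dedup) and every
  # junction starts at its TA
  p0 <- clean_params()
  lib0 <- simulate_junction_library(truth, g, p0, "SB100X", seed = 5)
  junc0 <- process_reads(lib0, p0, p0$barcode_map[["SB100X"]])
  expect_gte(nrow(junc0), 0.97 * nrow(truth))
  site_of <- function(ids) unique(sub("^mol[0-9]+:", "", ids))
  expect_setequal(site_of(junc0$id),
                  site_of(sprintf("mol%06d:%s:%d:%s", truth$molecule_id,
                                  truth$chrom, truth$pos, truth$strand)))
  expect_true(all(startsWith(junc0$junction, "TA")))
})
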