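# Shared fixtures. Genomes are built once per test run and memoised; all
# other fixtures are cheap and built in place.

.fixtures <- new.env(parent = emptyenv())

# Compact five-chromosome genome for mapping/pipeline tests: same band
# structure as the default (20 kb acrocentric p-arms, 20 x 500 bp p12
# tandem repeat) on short chromosomes, with annotation intervals scaled
# down to fit.
small_genome_config <- function(seed = 7L) {
  genome_config(
    chromosomes = data.frame(
      name = c("chrA1", "chrA2", "chrA3", "chrN1", "chrN2"),
      length = c(40000L, 40000L, 40000L, 30000L, 30000L),
      acrocentric = c(TRUE, TRUE, TRUE, FALSE, FALSE)
    ),
    nad_length = 4000L, lad_length = 3000L, peak_length = 200L,
    seed = seed)
}

small_genome <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- build_genome(small_genome_config())
  .fixtures$small
}

small_index <- function() {
  if (is.null(.fixtures$small_idx)) .fixtures$small_idx <- build_index(small_genome())
  .fixtures$small_idx
}

default_genome <- function() {
  if (is.null(.fixtures$default)) .fixtures$default <- build_genome(genome_config())
  .fixtures$default
}

# Hand-built minimal GenomeModel (no annotations) from raw sequences;
# used where exact TA layout must be known.
toy_genome <- function(seqs, acrocentric = NULL) {
  if (is.null(acrocentric))
    acrocentric <- stats::setNames(rep(FALSE, length(seqs)), names(seqs))
  cyto <- GenomicRanges::GRanges(
    names(seqs), IRanges::IRanges(1L, nchar(seqs)))
  S4Vectors::mcols(cyto)$label <- "q"
  g <- structure(list(seq = seqs, acrocentric = acrocentric,
                      cytobands = cyto, annotations = list(), ta = NULL,
                      config = NULL),
                 class = "GenomeModel")
  g$ta <- sbsites:::ta_site_table(g)
  g
}

# Noiseless library parameters (errors, duplication and contamination off).
clean_params <- function(...) {
  library_params(error_rate = 0, pcr_duplication_rate = 0,
                 backbone_fraction = 0, ...)
}

# Truth set with a guaranteed number of fragment molecules per distinct
# site, placed on unique (non-p12) sequence away from chromosome ends.
unique_region_truth <- function(genome, n_sites = 120L, per_site = 7L,
                                seed = 31L) {
  p12 <- region_by_label(genome, "p12")
  ta <- genome$ta
  margin <- 600L
  len <- nchar(genome$seq)[ta$chrom]
  in_p12 <- sbsites:::site_in_region(genome, p12)
  ok <- !in_p12 & ta$pos >= margin & ta$pos <= len - margin
  cand <- which(ok)
  withr::with_seed(seed, {
    pick <- sort(sample(cand, n_sites))
    events <- data.frame(chrom = ta$chrom[pick], pos = ta$pos[pick],
                         strand = sample(c("+", "-"), n_sites, replace = TRUE),
                         molecule_id = seq_len(n_sites),
                         stringsAsFactors = FALSE)
  })
  expand_insertions(events, mean_fragments = per_site + 2,
                    min_fragments = per_site, seed = seed)
}

# Exhaustive two-sided Fisher oracle: enumerates every 2x2 table with the
# observed margins and sums the probabilities (computed directly from
# binomial coefficients) of tables no more probable than the observed one.
fisher_enum_oracle <- function(a, total_a, b, total_b) {
  k <- a + b
  xs <- max(0L, k - total_b):min(k, total_a)
  probs <- vapply(xs, function(x) {
    choose(total_a, x) * choose(total_b, k - x) / choose(total_a + total_b, k)
  }, numeric(1))
  obs <- probs[match(a, xs)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
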