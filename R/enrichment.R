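#' Expand peak intervals and merge overlaps
#'
#' Grows each interval by `pad` on both sides, clamps to chromosome
#' bounds, and merges the result (ChIP-Seq peaks are expanded by 500 nt
#' before counting insertions in them).
#'
#' @param peaks `GRanges`.
#' @param pad expansion in nt (default 500).
#' @param genome a `GenomeModel` supplying chromosome lengths.
#' @return merged `GRanges`.
#' @export
expand_peaks <- function(peaks, pad = 500L, genome = NULL) {
  s <- pmax(GenomicRanges::start(peaks) - pad, 1L)
  e <- GenomicRanges::end(peaks) + pad
  if (!is.null(genome)) {
    lens <- nchar(genome$seq)
    e <- pmin(e, lens[as.character(GenomicRanges::seqnames(peaks))])
  }
  GenomicRanges::reduce(GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks), IRanges::IRanges(s, e)))
}

#' Count insertion sites falling in a region set
#'
#' A site is counted once if its TA coordinate lies inside the half-open
#' union of the regions, regardless of how many regions overlap it.
#'
#' @param sites data.frame with `chrom` and 0-based `pos`.
#' @param regions `GRanges`.
#' @param genome optional `GenomeModel`; when given, any site or region
#'   chromosome absent from the genome is an error (offenders listed).
#' @return integer count.
#' @export
count_in_regions <- function(sites, regions, genome = NULL) {
  if (!is.null(genome)) {
    universe <- names(genome$seq)
    bad <- setdiff(unique(c(sites$chrom,
                            as.character(GenomicRanges::seqnames(regions)))),
                   universe)
    if (length(bad))
      stop("chromosome name(s) not in genome: ", paste(bad, collapse = ", "))
  }
  if (!nrow(sites)) return(0L)
  hits <- GenomicRanges::findOverlaps(sites_to_granges(sites),
                                      GenomicRanges::reduce(regions))
  length(unique(S4Vectors::queryHits(hits)))
}

#' Two-condition enrichment test for one region
#'
#' Builds the 2x2 table `[in_A, out_A; in_B, out_B]` and computes the
#' two-sided Fisher exact probability by hypergeometric enumeration: the
#' sum of the probabilities of all tables with the observed margins whose
#' probability does not exceed the observed table's (relative tolerance
#' 1e-7, the usual tie convention). The headline effect size is
#' `pct_increase = 100 * ((in_B/total_B) / (in_A/total_A) - 1)` — the
#' percent change of condition B's normalized insertion share relative to
#' condition A — plus the sample odds ratio oriented the same way.
#'
#' @param count_in_A,total_A condition A: sites in the region, total
#'   sites.
#' @param count_in_B,total_B condition B likewise.
#' @param region_label optional label carried into the result.
#' @return one-row data.frame of class `EnrichmentResult`: counts,
#'   `pct_increase` (`Inf` when A has zero in-region sites but B does
#'   not; `NA` when both are zero), `odds_ratio`, `p_value`.
#' @export
enrichment_test <- function(count_in_A, total_A, count_in_B, total_B,
                            region_label = NA_character_) {
  stopifnot(total_A > 0, total_B > 0,
            count_in_A >= 0, count_in_A <= total_A,
            count_in_B >= 0, count_in_B <= total_B)
  k <- count_in_A + count_in_B
  lo <- max(0L, k - total_B)
  hi <- min(k, total_A)
  d <- dhyper(lo:hi, total_A, total_B, k)
  incl <- d <= d[count_in_A - lo + 1L] * (1 + 1e-7)
  # when no table is more probable than the observed one, p is exactly 1
  p <- if (all(incl)) 1 else min(1, sum(d[incl]))

  rate_A <- count_in_A / total_A
  rate_B <- count_in_B / total_B
  pct <- if (count_in_A == 0 && count_in_B == 0) NA_real_
         else if (count_in_A == 0) Inf
         else 100 * (rate_B / rate_A - 1)
  or <- (count_in_B / (total_B - count_in_B)) /
        (count_in_A / (total_A - count_in_A))
  out <- data.frame(region_label = region_label,
                    count_in_A = count_in_A, total_A = total_A,
                    count_in_B = count_in_B, total_B = total_B,
                    pct_increase = pct, odds_ratio = or, p_value = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Compare insertion-site distributions of two conditions over region sets
#'
#' One [enrichment_test()] per labelled region set: counts of sites inside
#' the region in each condition against the condition totals. Sites
#' flagged `on_ta = FALSE` (sequencing-error artefacts) are excluded.
#' Raw per-region p-values are reported; `adjust = TRUE` adds a
#' Benjamini-Hochberg column.
#'
#' @param sites_A,sites_B site data.frames (called sites or truth
#'   insertions) of the two conditions.
#' @param region_sets named list of `GRanges` (see
#'   [standard_region_sets()]).
#' @param genome optional `GenomeModel` for chromosome-name validation.
#' @param adjust add a BH-adjusted p-value column.
#' @return data.frame, one row per region label.
#' @export
compare_conditions <- function(sites_A, sites_B, region_sets,
                               genome = NULL, adjust = FALSE) {
  if (!nrow(sites_A) || !nrow(sites_B))
    stop("empty site set")
  if ("on_ta" %in% names(sites_A)) sites_A <- sites_A[sites_A$on_ta, ]
  if ("on_ta" %in% names(sites_B)) sites_B <- sites_B[sites_B$on_ta, ]
  total_A <- nrow(sites_A)
  total_B <- nrow(sites_B)
  rows <- lapply(names(region_sets), function(lab) {
    enrichment_test(count_in_regions(sites_A, region_sets[[lab]], genome),
                    total_A,
                    count_in_regions(sites_B, region_sets[[lab]], genome),
                    total_B,
                    region_label = lab)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}

# Window boundaries splitting a region of length L into n near-equal
# bins; the remainder is spread over the leading windows. Returns 0-based
# offsets of window starts plus the terminal offset L.
bin_edges <- function(L, n_bins) {
  base <- L %/% n_bins
  rem <- L %% n_bins
  widths <- rep(base, n_bins)
  if (rem > 0) widths[seq_len(rem)] <- base + 1L
  cumsum(c(0L, widths))
}

#' Binned RPKM insertion-density profile over a region
#'
#' Splits the region into `n_bins` near-equal windows and normalizes
#' per-window site counts by the RPKM principle: count per kilobase of
#' window per million total sites.
#'
#' @param sites site data.frame (`chrom`, 0-based `pos`).
#' @param region single-interval `GRanges` (or list with `chrom`,
#'   0-based `start`, `end`).
#' @param n_bins number of windows (default 300); region length must be
#'   at least `n_bins`.
#' @param total_sites library total used for the per-million scaling
#'   (defaults to `nrow(sites)`).
#' @return data.frame of class `BinnedProfile`: `bin`, `start`, `end`
#'   (0-based half-open), `count`, `rpkm`.
#' @export
binned_rpkm_profile <- function(sites, region, n_bins = 300L,
                                total_sites = nrow(sites)) {
  reg <- as_region(region)
  L <- reg$end - reg$start
  if (L < n_bins)
    stop("region length ", L, " < n_bins = ", n_bins,
         "; use fewer bins for so short a region")
  edges <- bin_edges(L, n_bins)
  pos <- sites$pos[sites$chrom == reg$chrom &
                     sites$pos >= reg$start & sites$pos < reg$end]
  counts <- tabulate(findInterval(pos - reg$start, edges,
                                  left.open = FALSE), nbins = n_bins)
  widths <- diff(edges)
  rpkm <- counts / (widths / 1000) / (total_sites / 1e6)
  out <- data.frame(bin = seq_len(n_bins) - 1L,
                    start = reg$start + edges[-length(edges)],
                    end = reg$start + edges[-1L],
                    count = counts, rpkm = rpkm)
  class(out) <- c("BinnedProfile", "data.frame")
  attr(out, "region_label") <- reg$label
  attr(out, "total_sites") <- total_sites
  out
}

# Normalize the different region representations to a 0-based triple.
as_region <- function(region) {
  if (is(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    lab <- if ("label" %in% names(S4Vectors::mcols(region)))
      S4Vectors::mcols(region)$label else NA_character_
    list(chrom = as.character(GenomicRanges::seqnames(region)),
         start = GenomicRanges::start(region) - 1L,
         end = GenomicRanges::end(region),
         label = lab)
  } else {
    if (is.null(region$label)) region$label <- NA_character_
    region
  }
}

#' TA-dinucleotide density profile over a region
#'
#' Per-window TA occurrence counts normalized by window length, min-max
#' scaled to [0, 1] over the region's windows, then loess-smoothed — the
#' companion track showing how TA availability shapes the insertion
#' landscape (the NOR-like p12 band is TA-poor by construction).
#'
#' @param genome a `GenomeModel`.
#' @param region single-interval region (as in [binned_rpkm_profile()]).
#' @param n_bins number of windows (default 300).
#' @param loess_span loess smoothing span (default 0.3).
#' @return data.frame: `bin`, `count`, `density`, `scaled`, `smoothed`.
#'   A constant density track scales to 0.5 everywhere by convention.
#' @export
ta_density_profile <- function(genome, region, n_bins = 300L,
                               loess_span = 0.3) {
  reg <- as_region(region)
  L <- reg$end - reg$start
  if (L < n_bins)
    stop("region length ", L, " < n_bins = ", n_bins)
  edges <- bin_edges(L, n_bins)
  ta <- ta_positions(substring(genome$seq[[reg$chrom]], reg$start + 1L,
                               reg$end))
  counts <- tabulate(findInterval(ta, edges, left.open = FALSE),
                     nbins = n_bins)
  dens <- counts / diff(edges)
  rng <- range(dens)
  scaled <- if (rng[1] == rng[2]) rep(0.5, n_bins)
            else (dens - rng[1]) / (rng[2] - rng[1])
  bin <- seq_len(n_bins) - 1L
  smoothed <- predict(loess(scaled ~ bin, span = loess_span))
  data.frame(bin = bin, count = counts, density = dens, scaled = scaled,
             smoothed = smoothed)
}
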