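#' SB insertion target model
#'
#' The Sleeping Beauty transposase integrates exclusively at TA
#' dinucleotides. This model assigns every genomic TA site a sampling
#' weight: the product of multiplicative region weights (one per region
#' set containing the site) times a palindromic-context weight for sites
#' whose 8-mer window centred on the TA is exactly `ATATATAT` — the
#' consensus the SB target-site logo shows. Insertion probabilities are
#' the normalized weights; positions that are not the first base of a TA
#' have probability zero.
#'
#' @param region_bias named list/vector of multiplicative weights
#'   (theta >= 0) keyed by region labels understood by
#'   [region_by_label()]; unlisted regions have weight 1. A
#'   nucleolar-retargeted (B23-fused) transposase is emulated with, e.g.,
#'   `list(acro_p_arm = 1.64)`.
#' @param palindrome_weight weight w >= 1 multiplying sites with exact
#'   `ATATATAT` context.
#' @param condition_label condition name, e.g. `"SB100X"` or
#'   `"B23-SB100X"`.
#' @return object of class `TargetModel`.
#' @export
target_model <- function(region_bias = list(), palindrome_weight = 1,
                         condition_label = "SB100X") {
  rb <- unlist(region_bias)
  if (length(rb) && (any(!is.finite(rb)) || any(rb < 0)))
    stop("region_bias weights must be finite and non-negative")
  if (!is.finite(palindrome_weight) || palindrome_weight < 1)
    stop("palindrome_weight must be finite and >= 1")
  structure(list(region_bias = as.list(rb),
                 palindrome_weight = palindrome_weight,
                 condition_label = condition_label),
            class = "TargetModel")
}

#' @export
print.TargetModel <- function(x, ...) {
  cat("TargetModel [", x$condition_label, "] palindrome weight ",
      x$palindrome_weight, "\n", sep = "")
  if (length(x$region_bias))
    cat("  region bias:",
        paste(names(x$region_bias), unlist(x$region_bias), sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}

# Logical membership of each TA site in a region set.
site_in_region <- function(genome, region) {
  hits <- GenomicRanges::findOverlaps(sites_to_granges(genome$ta),
                                      GenomicRanges::reduce(region))
  member <- logical(nrow(genome$ta))
  member[S4Vectors::queryHits(hits)] <- TRUE
  member
}

# Logical: does the 8-mer window centred on each TA equal ATATATAT?
site_palindromic <- function(genome) {
  ta <- genome$ta
  out <- logical(nrow(ta))
  for (ch in unique(ta$chrom)) {
    idx <- which(ta$chrom == ch)
    pos <- ta$pos[idx] # 0-based T
    len <- nchar(genome$seq[[ch]])
    ok <- pos >= 3L & pos + 4L < len
    ctx <- substring(genome$seq[[ch]], pos[ok] + 1L - 3L, pos[ok] + 1L + 4L)
    out[idx[ok]] <- ctx == "ATATATAT"
  }
  out
}

# Per-TA-site sampling weights under a target model.
site_weights <- function(genome, model) {
  w <- rep(1, nrow(genome$ta))
  for (lab in names(model$region_bias)) {
    theta <- model$region_bias[[lab]]
    member <- site_in_region(genome, region_by_label(genome, lab))
    w[member] <- w[member] * theta
  }
  if (model$palindrome_weight != 1)
    w[site_palindromic(genome)] <- w[site_palindromic(genome)] *
      model$palindrome_weight
  w
}

#' Sample ground-truth SB insertions
#'
#' Draws `n` insertions i.i.d. over the genome's TA sites with
#' probabilities proportional to the [target_model()] weights. Sites may
#' recur (independent transposition events). The insertion coordinate is
#' always the 0-based offset of the T of the target TA on the + strand,
#' regardless of insertion orientation: SB duplicates the TA so both
#' orientations share one canonical coordinate.
#'
#' @param genome a `GenomeModel`.
#' @param model a `TargetModel`.
#' @param n number of insertions (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `molecule_id`; the site-weight vector is attached as attribute
#'   `"weights"`.
#' @export
simulate_insertions <- function(genome, model, n, seed = 1L) {
  stopifnot(n >= 1)
  if (is.null(genome$ta) || nrow(genome$ta) == 0L)
    stop("genome contains no TA dinucleotide")
  w <- site_weights(genome, model)
  withr::with_seed(derive_seed(seed, 2L), {
    idx <- sample_weighted(n, w)
    strand <- sample(c("+", "-"), n, replace = TRUE)
  })
  out <- data.frame(chrom = genome$ta$chrom[idx],
                    pos = genome$ta$pos[idx],
                    strand = strand,
                    molecule_id = seq_len(n),
                    stringsAsFactors = FALSE)
  attr(out, "weights") <- w
  out
}

#' Write truth insertions as BED6
#'
#' Interval is the TA dinucleotide (`[pos, pos+2)`), name carries the
#' molecule id.
#'
#' @param insertions data.frame from [simulate_insertions()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_insertions_bed <- function(insertions, path) {
  df <- data.frame(chrom = insertions$chrom,
                   start = insertions$pos,
                   end = insertions$pos + 2L,
                   name = paste0("mol", insertions$molecule_id),
                   score = 0L,
                   strand = insertions$strand)
  write_bed(df, path)
}
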