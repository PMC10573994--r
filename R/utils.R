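#' @importFrom stats rnorm rpois runif rbinom dhyper loess predict p.adjust
#'   ks.test chisq.test
#' @importFrom utils write.table head
#' @importFrom methods is
NULL

.datatable.aware <- TRUE

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character DNA sequences
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character vectors, which is how sequences travel through this pipeline.
#'
#' @param x character vector of DNA sequences over \{A,C,G,T\}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Scalar reverse complement without XString overhead; hot path of the
# mapper.
revcomp1 <- function(s) {
  r <- rev(charToRaw(chartr("ACGT", "TGCA", s)))
  rawToChar(r)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# i.i.d. random DNA string with given base probabilities (A,C,G,T order).
random_dna <- function(n, probs) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

# Base probabilities whose i.i.d. sequence has expected TA-dinucleotide
# density `d` per bp: P(T)·P(A) = d with P(A) = P(T) = sqrt(d).
ta_probs <- function(d) {
  if (d < 0 || d > 0.25)
    stop("TA density target ", d, " unreachable: must be in [0, 0.25]")
  at <- sqrt(d)
  gc <- (1 - 2 * at) / 2
  c(at, gc, gc, at) # A, C, G, T
}

# Measured TA-dinucleotide density (start positions per bp) of a sequence.
ta_density <- function(seq) {
  count_ta(seq) / nchar(seq)
}

# Number of TA dinucleotide occurrences (TA cannot overlap itself).
count_ta <- function(seq) {
  length(ta_positions(seq))
}

# 0-based start positions of every TA dinucleotide in a sequence.
ta_positions <- function(seq) {
  m <- gregexpr("TA", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# Weighted sampling with replacement by inverse CDF; O((n+K) log K) and
# well-behaved for near-uniform weights over tens of thousands of sites.
sample_weighted <- function(n, w) {
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and non-negative")
  tot <- sum(w)
  if (tot <= 0) stop("all sampling weights are zero")
  if (all(w == w[1])) return(sample.int(length(w), n, replace = TRUE))
  cw <- cumsum(w)
  findInterval(runif(n, 0, tot), cw, left.open = TRUE) + 1L
}

# Derive a stream-specific seed from a master seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}

#' Write intervals as a BED file
#'
#' Emits BED4 (chrom, start, end, name) or BED6 (adding score and strand)
#' with 0-based half-open coordinates. Accepts a `GRanges` (1-based, closed)
#' or a data frame already holding 0-based `start`/`end`.
#'
#' @param x `GRanges` or data.frame with columns chrom/start/end and
#'   optionally name, score, strand.
#' @param path output file.
#' @param name,score optional vectors overriding name/score columns.
#' @return invisibly, the path.
#' @export
write_bed <- function(x, path, name = NULL, score = NULL) {
  if (is(x, "GRanges")) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(x)),
      start = GenomicRanges::start(x) - 1L,
      end = GenomicRanges::end(x),
      stringsAsFactors = FALSE
    )
    mc <- as.data.frame(S4Vectors::mcols(x))
    if ("label" %in% names(mc)) df$name <- mc$label
    if ("name" %in% names(mc)) df$name <- mc$name
    if ("score" %in% names(mc)) df$score <- mc$score
    st <- as.character(GenomicRanges::strand(x))
    if (any(st != "*")) df$strand <- st
  } else {
    df <- as.data.frame(x)
  }
  if (!is.null(name)) df$name <- name
  if (!is.null(score)) df$score <- score
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  # BED columns are positional: fill gaps so later columns stay in place
  if ("strand" %in% cols && !"score" %in% cols) df$score <- 0L
  if (("score" %in% names(df) || "strand" %in% cols) && !"name" %in% cols)
    df$name <- "."
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  write.table(df[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Read a BED file into a GRanges (1-based internal coordinates).
#' Read a BED file
#'
#' @param path BED4/BED6 file with 0-based half-open coordinates.
#' @return `GRanges` with `label` (and `score`, `strand` when present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]),
    strand = if (ncol(df) >= 6) df[[6]] else "*"
  )
  if (ncol(df) >= 4) S4Vectors::mcols(gr)$label <- df[[4]]
  if (ncol(df) >= 5) S4Vectors::mcols(gr)$score <- df[[5]]
  gr
}

# Sites data.frame (chrom, pos 0-based) -> width-1 GRanges at the T of TA.
sites_to_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
}
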