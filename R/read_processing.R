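#' Demultiplex read pairs by exact barcode prefix
#'
#' Assigns each pair to the sample whose barcode matches the read-1 prefix
#' exactly; non-matching pairs go to the `"undetermined"` bin.
#'
#' @param pairs read-pair data.frame (`id`, `seq1`, ...).
#' @param barcode_map named character vector (sample -> barcode); barcodes
#'   must be equal length and mutually distinct.
#' @return named list of per-sample pair data.frames (plus
#'   `undetermined`), with a `counts` attribute.
#' @export
demultiplex <- function(pairs, barcode_map) {
  bl <- unique(nchar(barcode_map))
  if (length(bl) != 1L) stop("barcodes must be of equal length")
  if (anyDuplicated(barcode_map)) stop("duplicate barcode sequences")
  prefix <- substr(pairs$seq1, 1L, bl)
  assign <- names(barcode_map)[match(prefix, barcode_map)]
  assign[is.na(assign)] <- "undetermined"
  out <- split(pairs, factor(assign, levels = c(names(barcode_map),
                                                "undetermined")))
  counts <- vapply(out, nrow, integer(1))
  attr(out, "counts") <- counts
  out
}

#' Filter read 1 for the IR-specific primer
#'
#' Accepts a read iff the Hamming distance between the primer and the
#' read segment at the expected offset (immediately after the barcode) is
#' at most `max_mismatch`.
#'
#' @param read1 character vector of read-1 sequences.
#' @param primer primer sequence.
#' @param max_mismatch allowed mismatches (default 6).
#' @param offset 0-based offset of the primer in read 1 (barcode length).
#' @return data.frame with `accept`, `end_offset` (0-based offset one past
#'   the primer) and `reason` (`""`, `"primer_mismatch"` or
#'   `"too_short"`).
#' @export
primer_filter <- function(read1, primer, max_mismatch = 6L, offset = 0L) {
  plen <- nchar(primer)
  seg <- substr(read1, offset + 1L, offset + plen)
  too_short <- nchar(seg) < plen
  mism <- rep(NA_integer_, length(read1))
  mism[!too_short] <- vapply(seg[!too_short],
                             function(s) hamming(s, primer), integer(1),
                             USE.NAMES = FALSE)
  accept <- !too_short & mism <= max_mismatch
  data.frame(accept = accept,
             end_offset = ifelse(accept, offset + plen, NA_integer_),
             reason = ifelse(too_short, "too_short",
                             ifelse(accept, "", "primer_mismatch")),
             stringsAsFactors = FALSE)
}

#' Verify the residual IR sequence and trim to the genomic flank
#'
#' Amplification specificity check: the IR bases between the primer end
#' and the genome junction must match the expected IR tail within
#' `max_mismatch`. Accepted reads are trimmed of barcode + IR, leaving the
#' sequence that starts at the genomic TA.
#'
#' @param read1 character vector of read-1 sequences.
#' @param ir_tail full IR tail (primer included).
#' @param primer primer whose presence was already enforced.
#' @param max_mismatch allowed mismatches in the residual IR (default 2).
#' @param offset 0-based barcode length.
#' @return data.frame with `accept`, `flank`, `trim_offset` (0-based
#'   offset of the flank in read 1) and `reason` (`"nonspecific
#'   amplification"` on rejection).
#' @export
ir_verify_and_trim <- function(read1, ir_tail, primer, max_mismatch = 2L,
                               offset = 0L) {
  plen <- nchar(primer)
  residual <- substr(ir_tail, plen + 1L, nchar(ir_tail))
  rlen <- nchar(residual)
  seg <- substr(read1, offset + plen + 1L, offset + plen + rlen)
  too_short <- nchar(seg) < rlen
  mism <- rep(NA_integer_, length(read1))
  mism[!too_short] <- vapply(seg[!too_short],
                             function(s) hamming(s, residual), integer(1),
                             USE.NAMES = FALSE)
  accept <- !too_short & mism <= max_mismatch
  trim_offset <- offset + nchar(ir_tail)
  data.frame(accept = accept,
             flank = ifelse(accept,
                            substr(read1, trim_offset + 1L, nchar(read1)),
                            NA_character_),
             trim_offset = ifelse(accept, trim_offset, NA_integer_),
             reason = ifelse(accept, "", "nonspecific amplification"),
             stringsAsFactors = FALSE)
}

# k-mer set (both strands) of a backbone sequence.
backbone_kmer_set <- function(backbone, k = 25L) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }
  unique(c(kmers(backbone), kmers(revcomp(backbone))))
}

#' Discard flanks matching the plasmid backbone
#'
#' A flank is discarded iff any k-mer of its first 50 nt occurs in the
#' backbone (either strand). Flanks shorter than `k` are kept (too short
#' to judge).
#'
#' @param flank character vector of genomic-flank sequences.
#' @param backbone plasmid backbone sequence (or a precomputed k-mer set
#'   from `backbone_kmer_set`).
#' @param k seed k-mer length (default 25).
#' @param window number of leading flank bases examined (default 50).
#' @return logical vector, `TRUE` = keep.
#' @export
backbone_filter <- function(flank, backbone, k = 25L, window = 50L) {
  set <- if (length(backbone) > 1L) backbone else backbone_kmer_set(backbone, k)
  keep <- rep(TRUE, length(flank))
  s <- substr(flank, 1L, window)
  n_km <- nchar(s) - k + 1L
  idx <- which(n_km >= 1L) # shorter flanks are kept: too short to judge
  if (!length(idx)) return(keep)
  fi <- rep(idx, n_km[idx])
  st <- sequence(n_km[idx])
  km <- substring(s[fi], st, st + k - 1L)
  keep[unique(fi[km %in% set])] <- FALSE
  keep
}

#' Remove PCR duplicates by exact sequence identity
#'
#' Pairs with byte-identical (`seq1`, `seq2`) are collapsed to one
#' representative (the first in a canonical id ordering, so the surviving
#' set does not depend on input order).
#'
#' @param pairs read-pair data.frame.
#' @return deduplicated data.frame with attribute `n_removed`.
#' @export
deduplicate_pairs <- function(pairs) {
  pairs <- pairs[order(pairs$id), , drop = FALSE]
  key <- paste(pairs$seq1, pairs$seq2, sep = "\r")
  out <- pairs[!duplicated(key), , drop = FALSE]
  attr(out, "n_removed") <- nrow(pairs) - nrow(out)
  out
}

#' Merge a read pair by 3' overlap
#'
#' If the reverse complement of read 2 overlaps the end of read 1 by at
#' least `min_overlap` bases with a mismatch fraction of at most
#' `max_overlap_mismatch_frac`, the full fragment is reconstructed
#' (read 1's base wins inside the overlap); otherwise read 1 is returned
#' alone. The largest acceptable overlap is used.
#'
#' @param seq1,seq2 the two mate sequences.
#' @param min_overlap minimum overlap length (default 10).
#' @param max_overlap_mismatch_frac maximum mismatch fraction inside the
#'   overlap (default 0.1).
#' @return list with `seq` (merged fragment or read 1) and `merged`
#'   (logical).
#' @export
merge_pair <- function(seq1, seq2, min_overlap = 10L,
                       max_overlap_mismatch_frac = 0.1) {
  rc2 <- revcomp1(seq2)
  r1 <- charToRaw(seq1)
  r2 <- charToRaw(rc2)
  n1 <- length(r1); n2 <- length(r2)
  for (o in seq(min(n1, n2), min_overlap)) {
    # cheap prefilter: a true overlap cannot be wrong in most of its
    # first bases, while a random one almost always is
    w <- min(10L, o)
    if (sum(r1[(n1 - o + 1L):(n1 - o + w)] != r2[1:w]) >
        max(2L, floor(w * max_overlap_mismatch_frac)))
      next
    if (sum(r1[(n1 - o + 1L):n1] != r2[1:o]) <=
        floor(o * max_overlap_mismatch_frac))
      return(list(seq = paste0(seq1, substr(rc2, o + 1L, n2)),
                  merged = TRUE))
  }
  list(seq = seq1, merged = FALSE)
}

#' Clean one sample's read pairs into mappable junction sequences
#'
#' The pre-mapping stage: primer filter (6 mismatches), residual-IR
#' verification, backbone discard, exact-sequence PCR-duplicate removal,
#' then pair merging; the first read of non-mergeable pairs is kept. The
#' surviving sequence is trimmed of barcode + IR so it begins at the
#' genomic TA; anything shorter than `min_len` after trimming is dropped.
#'
#' @param pairs read-pair data.frame of one sample (barcode still
#'   attached).
#' @param params a [library_params()] (supplies primer, IR, backbone).
#' @param barcode the sample's barcode (its length sets the primer
#'   offset).
#' @param primer_max_mismatch,ir_max_mismatch,backbone_k mismatch budgets
#'   and backbone k-mer size.
#' @param min_len minimum junction length kept (default 30).
#' @param min_overlap,max_overlap_mismatch_frac merge parameters.
#' @return data.frame with `id`, `junction`, `merged`, `shear_key`
#'   (fragment-identity key used for independent-read support counting),
#'   and attribute `stats`, a named vector whose categories partition the
#'   input (`input = surviving + rejected`).
#' @export
process_reads <- function(pairs, params, barcode,
                          primer_max_mismatch = 6L,
                          ir_max_mismatch = 2L,
                          backbone_k = 25L,
                          min_len = 30L,
                          min_overlap = 10L,
                          max_overlap_mismatch_frac = 0.1) {
  n_input <- nrow(pairs)
  off <- nchar(barcode)

  pf <- primer_filter(pairs$seq1, params$primer, primer_max_mismatch, off)
  n_primer <- sum(!pf$accept)
  pairs <- pairs[pf$accept, , drop = FALSE]

  iv <- ir_verify_and_trim(pairs$seq1, params$ir_sequence, params$primer,
                           ir_max_mismatch, off)
  n_ir <- sum(!iv$accept)
  pairs <- pairs[iv$accept, , drop = FALSE]
  flank <- iv$flank[iv$accept]

  keep <- backbone_filter(flank, params$backbone, backbone_k)
  n_backbone <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]

  pairs <- deduplicate_pairs(pairs)
  n_dup <- attr(pairs, "n_removed")

  trim_offset <- off + nchar(params$ir_sequence)
  res <- lapply(seq_len(nrow(pairs)), function(i)
    merge_pair(pairs$seq1[i], pairs$seq2[i], min_overlap,
               max_overlap_mismatch_frac))
  full <- vapply(res, `[[`, character(1), "seq")
  was_merged <- vapply(res, `[[`, logical(1), "merged")
  junction <- substr(full, trim_offset + 1L, nchar(full))

  long_enough <- nchar(junction) >= min_len
  n_short <- sum(!long_enough)
  keep_j <- which(long_enough)
  out <- data.frame(id = pairs$id[keep_j],
                    junction = junction[keep_j],
                    merged = was_merged[keep_j],
                    shear_key = if (length(keep_j))
                      paste0(nchar(junction[keep_j]), ":",
                             pairs$seq2[keep_j]) else character(0),
                    stringsAsFactors = FALSE)
  attr(out, "stats") <- c(input = n_input,
                          primer_reject = n_primer,
                          ir_reject = n_ir,
                          backbone_discard = n_backbone,
                          duplicate = n_dup,
                          too_short = n_short,
                          surviving = nrow(out))
  out
}
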