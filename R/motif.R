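#' Extract target-site sequence contexts
#'
#' For each insertion site, the + strand window
#' `[pos - flank, pos + 2 + flank)` — the TA plus `flank` bases on either
#' side. Site coordinates are strand-pooled and the SB target motif is an
#' AT palindrome (strand-symmetric), so + strand windows suffice. Sites
#' too close to a chromosome end for a full window are skipped and
#' counted.
#'
#' @param sites site data.frame (`chrom`, 0-based `pos`).
#' @param genome a `GenomeModel`.
#' @param flank flanking bases on each side (default 10).
#' @return character vector of contexts with attribute `n_skipped`.
#' @export
extract_contexts <- function(sites, genome, flank = 10L) {
  len <- nchar(genome$seq)[sites$chrom]
  ok <- sites$pos - flank >= 0L & sites$pos + 2L + flank <= len
  ctx <- substring(genome$seq[sites$chrom[ok]],
                   sites$pos[ok] - flank + 1L,
                   sites$pos[ok] + 2L + flank)
  attr(ctx, "n_skipped") <- sum(!ok)
  ctx
}

#' Position frequency matrix and information content of site contexts
#'
#' Column base frequencies over the contexts plus the standard sequence-
#' logo column height: `IC_j = 2 + sum_b f_bj log2 f_bj` bits (with
#' `0 log 0 = 0`). For SB-called sites the two centre columns are the
#' invariant TA (`f(T) = f(A) = 1`, 2 bits).
#'
#' @param contexts equal-length character vector from
#'   [extract_contexts()].
#' @return list of class `pfm`: `matrix` (4 x L, rows A/C/G/T, columns
#'   summing to 1), `ic` (bits per column), `n_sites`, `flank`.
#' @export
build_pfm <- function(contexts) {
  if (!length(contexts)) stop("no contexts")
  L <- unique(nchar(contexts))
  if (length(L) != 1L) stop("contexts of unequal length")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(contexts))
  m <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
  present <- intersect(rownames(cm), DNA_BASES)
  m[present, ] <- cm[present, , drop = FALSE]
  freq <- sweep(m, 2L, colSums(m), "/")
  ic <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  structure(list(matrix = freq, ic = ic, n_sites = length(contexts),
                 flank = (L - 2L) / 2L),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix over", x$n_sites, "sites, width",
      ncol(x$matrix), "(flank", x$flank, ")\n")
  cat("Centre columns:",
      sprintf("f(T)=%.3f f(A)=%.3f", x$matrix["T", x$flank + 1L],
              x$matrix["A", x$flank + 2L]), "\n")
  invisible(x)
}

#' Write a PFM (and its information content) as TSV
#'
#' @param pfm a [build_pfm()] result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pfm_tsv <- function(pfm, path) {
  df <- data.frame(position = seq_len(ncol(pfm$matrix)) - 1L,
                   t(pfm$matrix), ic_bits = pfm$ic)
  write.table(format(df, digits = 6, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
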