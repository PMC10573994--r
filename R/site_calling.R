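#' Build an exact k-mer seed index over the genome
#'
#' Desk-scale replacement for a short-read aligner: every + strand k-mer
#' is recorded with its locus; reverse-strand hits are found at query time
#' by also seeding the reverse complement of the read.
#'
#' @param genome a `GenomeModel`.
#' @param k seed length (default 31).
#' @return list of class `kmer_index`: a hashed k-mer -> locus map plus
#'   the reference sequences used for full-length verification.
#' @export
build_index <- function(genome, k = 31L) {
  lens <- nchar(genome$seq)
  goff <- cumsum(c(0, as.numeric(lens))) # global offset per chromosome
  tabs <- lapply(seq_along(genome$seq), function(i) {
    s <- genome$seq[[i]]
    n <- nchar(s)
    if (n < k) return(NULL)
    data.table::data.table(kmer = substring(s, 1:(n - k + 1L), k:n),
                           gpos = goff[i] + 0:(n - k)) # 0-based global
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  r <- rle(dt$kmer)
  ends <- cumsum(r$lengths)
  lst <- vector("list", length(r$values))
  single <- r$lengths == 1L
  lst[single] <- as.list(dt$gpos[ends[single]])
  for (i in which(!single))
    lst[[i]] <- dt$gpos[(ends[i] - r$lengths[i] + 1L):ends[i]]
  names(lst) <- r$values
  env <- list2env(lst, hash = TRUE, size = max(2L * length(lst), 29L))
  structure(list(k = k, env = env, seqs = genome$seq,
                 chrom_names = names(genome$seq), chrom_len = lens,
                 goff = goff),
            class = "kmer_index")
}

# Candidate alignment starts (0-based, per chromosome) of `query` on the
# + strand of the reference, from exact k-mer seeds at the given offsets.
seed_candidates <- function(query, index, offsets) {
  k <- index$k
  qn <- nchar(query)
  offsets <- offsets[offsets + k <= qn]
  if (!length(offsets)) return(NULL)
  starts <- numeric(0)
  for (off in offsets) {
    g <- index$env[[substr(query, off + 1L, off + k)]]
    if (!is.null(g)) starts <- c(starts, g - off)
  }
  starts <- unique(starts[starts >= 0])
  if (!length(starts)) return(NULL)
  ci <- findInterval(starts, index$goff) # chromosome of each global start
  local <- starts - index$goff[ci]
  ok <- local >= 0 & local + qn <= index$chrom_len[ci]
  if (!any(ok)) return(NULL)
  list(chrom = index$chrom_names[ci[ok]], start = as.integer(local[ok]))
}

#' Map one junction sequence to the genome
#'
#' Seed-and-verify: exact k-mer seeds (at query offsets 0 and 32, both
#' orientations) propose candidate loci, each verified by full-length
#' Hamming comparison within `max_mismatch_frac`. Ties at the best
#' distance define the multimapping candidate set. In `unique` mode a
#' read maps only if exactly one best locus exists; in `random` mode one
#' best locus is drawn uniformly (caller controls the RNG state). The
#' reported position is the 0-based coordinate of the junction's first
#' genomic base — the T of the target TA on the + strand — for either
#' orientation.
#'
#' @param seq junction sequence (length >= k).
#' @param index a [build_index()] result.
#' @param mode `"unique"` or `"random"`.
#' @param max_mismatch_frac Hamming budget as a fraction of read length.
#' @return list with `mapped` (logical), and when mapped: `chrom`,
#'   `position`, `strand`, `n_candidate_loci`, `far_end` (shear-side
#'   coordinate); otherwise `reason`.
#' @export
map_junction <- function(seq, index, mode = c("unique", "random"),
                         max_mismatch_frac = 0.05) {
  mode <- match.arg(mode)
  qn <- nchar(seq)
  if (qn < index$k) return(list(mapped = FALSE, reason = "too_short"))
  budget <- floor(qn * max_mismatch_frac)
  offsets <- c(0L, 32L)

  h_chrom <- character(0); h_start <- integer(0)
  h_dist <- integer(0); h_strand <- character(0)
  for (strand in c("+", "-")) {
    query <- if (strand == "+") seq else revcomp1(seq)
    cand <- seed_candidates(query, index, offsets)
    if (is.null(cand)) next
    d <- vapply(seq_along(cand$start), function(i) {
      ref <- substr(index$seqs[[cand$chrom[i]]], cand$start[i] + 1L,
                    cand$start[i] + qn)
      hamming(query, ref)
    }, integer(1))
    ok <- d <= budget
    h_chrom <- c(h_chrom, cand$chrom[ok])
    h_start <- c(h_start, cand$start[ok])
    h_dist <- c(h_dist, d[ok])
    h_strand <- c(h_strand, rep(strand, sum(ok)))
  }
  if (!length(h_start))
    return(list(mapped = FALSE, reason = "no_hit"))
  best <- which(h_dist == min(h_dist))
  # canonical candidate order so random draws are reproducible
  best <- best[order(h_chrom[best], h_start[best], h_strand[best])]
  n_best <- length(best)
  if (mode == "unique" && n_best > 1L)
    return(list(mapped = FALSE, reason = "multimapping",
                n_candidate_loci = n_best))
  b <- best[if (n_best == 1L) 1L else sample.int(n_best, 1L)]
  if (h_strand[b] == "+") {
    position <- h_start[b]
    far_end <- h_start[b] + qn
  } else {
    position <- h_start[b] + qn - 2L
    far_end <- h_start[b]
  }
  list(mapped = TRUE, chrom = h_chrom[b], position = position,
       strand = h_strand[b], n_candidate_loci = n_best, far_end = far_end)
}

#' Map a table of junction sequences
#'
#' Reads are put into a canonical order (by id) before mapping so that
#' `random`-mode draws under a fixed seed do not depend on input order.
#'
#' @param junctions data.frame from [process_reads()] (`id`, `junction`,
#'   `shear_key`).
#' @param index a [build_index()] result.
#' @param mode `"unique"` or `"random"`.
#' @param max_mismatch_frac Hamming budget fraction.
#' @param seed integer seed for `random`-mode draws.
#' @return data.frame of mapped reads (`id`, `chrom`, `position`,
#'   `strand`, `n_candidate_loci`, `shear_key`, `far_end`) with attribute
#'   `stats` (mapped / multimapping-discarded / unmapped counts).
#' @export
map_junctions <- function(junctions, index, mode = c("unique", "random"),
                          max_mismatch_frac = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  junctions <- junctions[order(junctions$id), , drop = FALSE]
  withr::with_seed(derive_seed(seed, 4L), {
    res <- lapply(junctions$junction, map_junction, index = index,
                  mode = mode, max_mismatch_frac = max_mismatch_frac)
  })
  ok <- vapply(res, `[[`, logical(1), "mapped")
  reasons <- vapply(res[!ok], `[[`, character(1), "reason")
  out <- data.frame(
    id = junctions$id[ok],
    chrom = vapply(res[ok], `[[`, character(1), "chrom"),
    position = vapply(res[ok], `[[`, integer(1), "position"),
    strand = vapply(res[ok], `[[`, character(1), "strand"),
    n_candidate_loci = vapply(res[ok], `[[`, integer(1), "n_candidate_loci"),
    shear_key = junctions$shear_key[ok],
    far_end = vapply(res[ok], `[[`, integer(1), "far_end"),
    stringsAsFactors = FALSE
  )
  attr(out, "stats") <- c(input = nrow(junctions),
                          mapped = sum(ok),
                          multimapping = sum(reasons == "multimapping"),
                          no_hit = sum(reasons == "no_hit"),
                          too_short = sum(reasons == "too_short"))
  out
}

#' Call insertion sites from mapped junction reads
#'
#' Groups mapped reads by (chromosome, position); support is the number
#' of distinct shear keys in the group — deduplicated reads with distinct
#' sonication shear points are the independent evidence for a site.
#' Strand does not split sites: the TA is duplicated on insertion, so
#' both orientations share one coordinate. Sites whose reference
#' dinucleotide is not TA (sequencing-error artefacts) are retained but
#' flagged `on_ta = FALSE` and excluded from enrichment by default.
#'
#' @param mapped data.frame from [map_junctions()].
#' @param genome a `GenomeModel` (reference TA check).
#' @param min_support minimum distinct-shear-key support (default 5; the
#'   repetitive/random regime uses 1).
#' @param mode label recorded on the sites (`"unique"` or `"random"`).
#' @return data.frame of sites: `chrom`, `pos` (0-based T of TA),
#'   `support`, `mode`, `on_ta`, sorted by coordinate.
#' @export
call_sites <- function(mapped, genome, min_support = 5L,
                       mode = c("unique", "random")) {
  mode <- match.arg(mode)
  if (!nrow(mapped))
    return(data.frame(chrom = character(0), pos = integer(0),
                      support = integer(0), mode = character(0),
                      on_ta = logical(0)))
  dt <- data.table::as.data.table(mapped)
  grp <- dt[, .(support = data.table::uniqueN(shear_key)),
            by = .(chrom, position)]
  grp <- grp[support >= min_support]
  data.table::setorder(grp, chrom, position)
  ref <- substring(genome$seq[grp$chrom], grp$position + 1L,
                   grp$position + 2L)
  data.frame(chrom = grp$chrom, pos = grp$position,
             support = grp$support,
             mode = rep(mode, nrow(grp)),
             on_ta = ref == "TA", stringsAsFactors = FALSE)
}

#' Write called sites as BED6
#'
#' Name carries the mapping mode, score the read support.
#'
#' @param sites data.frame from [call_sites()].
#' @param path output path.
#' @param header_comment optional `#` comment line (e.g. recording the
#'   mapping seed).
#' @return invisibly, the path.
#' @export
write_sites_bed <- function(sites, path, header_comment = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  if (nrow(sites))
    writeLines(paste(sites$chrom, sites$pos, sites$pos + 2L, sites$mode,
                     sites$support, "+", sep = "\t"), con)
  invisible(path)
}
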