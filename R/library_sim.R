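# Transposon inverted-repeat (IR) tail retained on the genomic junction
# after the nested PCR; the IR-specific primer anchors in its first 20 nt.
DEFAULT_IR_SEQUENCE <- "CAGTTGAAGTCGGAAGTTTACATACACTTAGGCTAAGGTA"
DEFAULT_PRIMER <- substr(DEFAULT_IR_SEQUENCE, 1L, 20L)
DEFAULT_BARCODES <- c("SB100X" = "ACGTAC", "B23-SB100X" = "TGCATG")

#' Junction-library simulation parameters
#'
#' Parameters of the sequencing-library emulation: sonication shear with
#' 600 bp mean, gel size selection to 200-500 bp, 2x150 paired-end reads,
#' PCR duplication, per-base substitution error and plasmid-backbone
#' contamination.
#'
#' @param ir_sequence transposon IR tail retained at the genome junction
#'   (read-side presentation); the primer must be its prefix.
#' @param primer IR-specific primer the reads begin with (after barcode).
#' @param barcode_map named character vector, sample label -> barcode.
#' @param shear_mean mean sonication fragment length (bp).
#' @param size_select numeric length 2: gel size-selection window (bp).
#' @param read_length read length of each mate.
#' @param pcr_duplication_rate mean number of extra PCR copies per
#'   molecule (Poisson).
#' @param error_rate per-base substitution probability.
#' @param backbone_fraction fraction of molecules whose post-IR sequence
#'   derives from the plasmid backbone rather than the genome.
#' @param backbone plasmid backbone sequence; generated from `seed` when
#'   `NULL`.
#' @param backbone_length length of the generated backbone.
#' @param seed integer seed.
#' @return list of class `LibraryParams`.
#' @export
library_params <- function(ir_sequence = DEFAULT_IR_SEQUENCE,
                           primer = NULL,
                           barcode_map = DEFAULT_BARCODES,
                           shear_mean = 600,
                           size_select = c(200, 500),
                           read_length = 150L,
                           pcr_duplication_rate = 0.3,
                           error_rate = 0.001,
                           backbone_fraction = 0.05,
                           backbone = NULL,
                           backbone_length = 2000L,
                           seed = 1L) {
  if (is.null(primer)) primer <- substr(ir_sequence, 1L, 20L)
  if (!startsWith(ir_sequence, primer))
    stop("primer must be a prefix of ir_sequence")
  stopifnot(size_select[1] <= size_select[2],
            pcr_duplication_rate >= 0,
            error_rate >= 0, error_rate <= 1,
            backbone_fraction >= 0, backbone_fraction <= 1)
  if (is.null(backbone))
    backbone <- withr::with_seed(derive_seed(seed, 7L),
                                 random_dna(backbone_length, rep(0.25, 4)))
  structure(list(ir_sequence = ir_sequence, primer = primer,
                 barcode_map = barcode_map, shear_mean = shear_mean,
                 size_select = size_select, read_length = read_length,
                 pcr_duplication_rate = pcr_duplication_rate,
                 error_rate = error_rate,
                 backbone_fraction = backbone_fraction,
                 backbone = backbone, seed = seed),
            class = "LibraryParams")
}

# Rejection-sample sonication shear lengths Normal(mean, mean/4) into the
# size-selection window.
sample_shear_lengths <- function(n, mean, window) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * (n - length(out)) + 10L, mean, mean / 4)
    out <- c(out, draw[draw >= window[1] & draw <= window[2]])
  }
  round(out[seq_len(n)])
}

# Substitution errors: each base flips to one of the other three bases
# with probability `rate`; vectorized over reads.
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(lens[i], nerr[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate a paired-end junction sequencing library
#'
#' Each truth molecule yields a fragment `barcode + IR tail + genomic
#' flank`, where the flank starts at the target TA and extends in the
#' insertion orientation for `shear length - |IR|` bases (truncated at the
#' chromosome end). Read 1 is the first `read_length` bases of the
#' fragment, read 2 the reverse complement of its last `read_length`
#' bases. A `backbone_fraction` of molecules carries plasmid backbone
#' instead of genome after the IR. Substitution errors are injected at
#' `error_rate`; PCR duplicates (Poisson extra copies) are emitted as
#' copies of the already-error-bearing parent, each gaining further errors
#' at `error_rate / 10` so that exact-sequence deduplication remains the
#' correct removal strategy.
#'
#' @param truth data.frame from [simulate_insertions()].
#' @param genome a `GenomeModel`.
#' @param params a [library_params()].
#' @param sample_label which barcode/sample this library belongs to.
#' @param seed integer seed.
#' @return data.frame of read pairs (`id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, `sample`) with attributes `n_molecules` (pairs before PCR
#'   duplication), `n_dropped` and `params`.
#' @export
simulate_junction_library <- function(truth, genome, params,
                                      sample_label = names(params$barcode_map)[1],
                                      seed = params$seed) {
  stopifnot(nrow(truth) >= 1, nchar(params$ir_sequence) > 0)
  barcode <- params$barcode_map[[sample_label]]
  if (is.null(barcode)) stop("unknown sample label: ", sample_label)
  ir <- params$ir_sequence
  rl <- params$read_length

  withr::with_seed(derive_seed(seed, 3L), {
    n <- nrow(truth)
    shear <- sample_shear_lengths(n, params$shear_mean, params$size_select)
    flank_target <- shear - nchar(ir)
    keep <- flank_target > 0L
    if (any(!keep))
      warning(sum(!keep), " molecule(s) dropped: shear length does not ",
              "exceed the IR tail")
    tr <- truth[keep, , drop = FALSE]
    flank_target <- flank_target[keep]
    is_bb <- runif(nrow(tr)) < params$backbone_fraction

    flank <- character(nrow(tr))
    chrom_len <- nchar(genome$seq)[tr$chrom]
    plus <- tr$strand == "+" & !is_bb
    if (any(plus)) {
      fl <- pmin(flank_target[plus], chrom_len[plus] - tr$pos[plus])
      flank[plus] <- substring(genome$seq[tr$chrom[plus]],
                               tr$pos[plus] + 1L, tr$pos[plus] + fl)
    }
    minus <- tr$strand == "-" & !is_bb
    if (any(minus)) {
      fl <- pmin(flank_target[minus], tr$pos[minus] + 2L)
      flank[minus] <- revcomp(substring(genome$seq[tr$chrom[minus]],
                                        tr$pos[minus] + 2L - fl + 1L,
                                        tr$pos[minus] + 2L))
    }
    if (any(is_bb)) {
      fl <- pmin(flank_target[is_bb], nchar(params$backbone))
      start <- floor(runif(sum(is_bb), 0, nchar(params$backbone) - fl)) + 1L
      bbseq <- substring(params$backbone, start, start + fl - 1L)
      flip <- runif(sum(is_bb)) < 0.5
      bbseq[flip] <- revcomp(bbseq[flip])
      flank[is_bb] <- bbseq
    }

    frag <- paste0(barcode, ir, flank)
    flen <- nchar(frag)
    seq1 <- substring(frag, 1L, pmin(rl, flen))
    seq2 <- revcomp(substring(frag, pmax(1L, flen - rl + 1L), flen))
    seq1 <- inject_errors(seq1, params$error_rate)
    seq2 <- inject_errors(seq2, params$error_rate)
    id <- ifelse(is_bb,
                 sprintf("bb%06d", tr$molecule_id),
                 sprintf("mol%06d:%s:%d:%s", tr$molecule_id, tr$chrom,
                         tr$pos, tr$strand))

    # PCR duplicates: exact copies of the post-error parent, plus rare
    # polymerase/sequencing errors of their own.
    extra <- rpois(length(id), params$pcr_duplication_rate)
    di <- rep(seq_along(id), extra)
    if (length(di)) {
      dup1 <- inject_errors(seq1[di], params$error_rate / 10)
      dup2 <- inject_errors(seq2[di], params$error_rate / 10)
      dupid <- paste0(id[di], ":dup",
                      unlist(lapply(extra[extra > 0L], seq_len)))
      seq1 <- c(seq1, dup1); seq2 <- c(seq2, dup2); id <- c(id, dupid)
    }

    out <- data.frame(id = id,
                      seq1 = seq1,
                      qual1 = strrep("I", nchar(seq1)),
                      seq2 = seq2,
                      qual2 = strrep("I", nchar(seq2)),
                      sample = sample_label,
                      stringsAsFactors = FALSE)
    attr(out, "n_molecules") <- nrow(tr)
    attr(out, "n_dropped") <- sum(!keep)
    attr(out, "params") <- params
    out
  })
}

#' Expand insertion events into recoverable genomic fragments
#'
#' In the wet protocol every insertion clone is expanded by two weeks of
#' antibiotic selection before gDNA isolation, so sonication recovers
#' many independent fragments — distinct shear points — per insertion
#' site. This step turns each truth insertion event into a
#' Poisson-distributed number of fragment molecules; distinct shear
#' points are what the site caller later counts as independent read
#' support. Junctions are amplified from both transposon ends, so each
#' fragment's orientation is drawn afresh.
#'
#' @param insertions truth events from [simulate_insertions()].
#' @param mean_fragments mean fragments recovered per event (Poisson).
#' @param min_fragments lower truncation of the per-event count; events
#'   drawing fewer fragments than this are raised to it (0 allows
#'   unrecovered events, mirroring real library dropout).
#' @param seed integer seed.
#' @return data.frame of fragment molecules: `chrom`, `pos`, `strand`,
#'   `molecule_id` (renumbered), `event_id` (the originating event).
#' @export
expand_insertions <- function(insertions, mean_fragments = 8,
                              min_fragments = 0L, seed = 1L) {
  withr::with_seed(derive_seed(seed, 8L), {
    k <- pmax(rpois(nrow(insertions), mean_fragments), min_fragments)
    idx <- rep(seq_len(nrow(insertions)), k)
    out <- data.frame(chrom = insertions$chrom[idx],
                      pos = insertions$pos[idx],
                      strand = sample(c("+", "-"), length(idx),
                                      replace = TRUE),
                      molecule_id = seq_along(idx),
                      event_id = insertions$molecule_id[idx],
                      stringsAsFactors = FALSE)
  })
  out
}

#' Write read pairs as paired FASTQ files
#'
#' @param pairs data.frame from [simulate_junction_library()].
#' @param r1_path,r2_path output paths; a `.gz` suffix gzip-compresses.
#' @return invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  emit <- function(path, ids, seqs, quals, mate) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    txt <- paste0("@", ids, "/", mate, "\n", seqs, "\n+\n", quals)
    writeLines(txt, con)
  }
  emit(r1_path, pairs$id, pairs$seq1, pairs$qual1, 1L)
  emit(r2_path, pairs$id, pairs$seq2, pairs$qual2, 2L)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a pair table
#'
#' @param r1_path,r2_path FASTQ paths (optionally gzipped).
#' @return data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  # Biostrings warns that FASTQ metadata columns are dropped; they carry
  # nothing this pipeline uses
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
  stopifnot(length(r1) == length(r2))
  id <- sub("/1$", "", names(r1))
  if (!identical(id, sub("/2$", "", names(r2))))
    stop("read pair ids of the two FASTQ files do not match")
  data.frame(id = id,
             seq1 = as.character(r1),
             qual1 = as.character(Biostrings::quality(r1)),
             seq2 = as.character(r2),
             qual2 = as.character(Biostrings::quality(r2)),
             stringsAsFactors = FALSE)
}
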