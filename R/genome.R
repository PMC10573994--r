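#' Genome-spec configuration for the synthetic genome builder
#'
#' Defines a desk-scale multi-chromosome genome with nucleolus-like
#' structure: acrocentric chromosomes carry a p13 / p12 / p11.2 / q band
#' layout in which the central p12-like band emulates a nucleolus organizer
#' region (NOR) — TA-poor and built from exact tandem copies of one repeat
#' unit so that multi-mapping reads arise there. Non-acrocentric
#' chromosomes carry a plain p / q layout.
#'
#' TA-dinucleotide density is controlled per band through the base
#' composition of an i.i.d. sequence (`P(A) = P(T) = sqrt(density)`).
#' Outside the p12-like band the builder additionally plants short
#' `ATATATAT` AT-microsatellite runs at `at_runs_per_kb` per kb, mirroring
#' the (AT)n microsatellites of real genomes; these create TA sites whose
#' +/-3 bp context matches the palindromic pattern the SB transposase
#' favours, so that a palindrome-weighted target model has realistic
#' substrate.
#'
#' @param chromosomes data.frame with columns `name`, `length`,
#'   `acrocentric` (logical). At least two acrocentric and one
#'   non-acrocentric chromosome of >= 30 kb each.
#' @param p_arm_length length in bp of the acrocentric p-arm.
#' @param band_fractions named numeric (p13, p12, p11.2) fractions of the
#'   acrocentric p-arm; must sum to 1.
#' @param p_fraction fraction of a non-acrocentric chromosome forming its
#'   p-arm.
#' @param repeat_unit_length length of the tandem repeat unit tiling the
#'   p12-like band; the p12 length is forced to an exact multiple.
#' @param ta_density named list of per-band TA-density targets (per bp).
#' @param at_runs_per_kb rate of planted ATATATAT runs outside p12.
#' @param nad_length,lad_length,peak_length interval lengths for the
#'   NAD-like, LAD-like and TF-peak-like annotation sets.
#' @param seed integer seed; the builder is deterministic given the config.
#' @return a list of class `genome_config`.
#' @export
genome_config <- function(
    chromosomes = data.frame(
      name = c("chrA1", "chrA2", "chrA3", "chrN1", "chrN2"),
      length = c(150000L, 150000L, 150000L, 200000L, 200000L),
      acrocentric = c(TRUE, TRUE, TRUE, FALSE, FALSE)
    ),
    p_arm_length = 20000L,
    band_fractions = c(p13 = 0.25, p12 = 0.5, p11.2 = 0.25),
    p_fraction = 0.3,
    repeat_unit_length = 500L,
    ta_density = list(p13 = 0.05, p12 = 0.01, p11.2 = 0.05, q = 0.05,
                      p = 0.05),
    at_runs_per_kb = 0.2,
    nad_length = 15000L,
    lad_length = 10000L,
    peak_length = 400L,
    seed = 1L) {
  cfg <- list(chromosomes = chromosomes, p_arm_length = p_arm_length,
              band_fractions = band_fractions, p_fraction = p_fraction,
              repeat_unit_length = repeat_unit_length,
              ta_density = ta_density, at_runs_per_kb = at_runs_per_kb,
              nad_length = nad_length, lad_length = lad_length,
              peak_length = peak_length, seed = seed)
  class(cfg) <- "genome_config"
  validate_genome_config(cfg)
  cfg
}

validate_genome_config <- function(cfg) {
  ch <- cfg$chromosomes
  if (sum(ch$acrocentric) < 2L || sum(!ch$acrocentric) < 1L)
    stop("need >= 2 acrocentric and >= 1 non-acrocentric chromosome")
  if (any(ch$length < 30000L))
    stop("chromosome lengths must be >= 30 kb")
  if (abs(sum(cfg$band_fractions) - 1) > 1e-8)
    stop("acrocentric p-arm band fractions must sum to 1")
  if (!all(c("p13", "p12", "p11.2") %in% names(cfg$band_fractions)))
    stop("band_fractions must name p13, p12 and p11.2")
  for (d in cfg$ta_density) ta_probs(d) # errors if unreachable
  invisible(cfg)
}

# Band coordinate layout (0-based half-open) for one chromosome.
band_layout <- function(cfg, acro, chrom_len) {
  if (acro) {
    pl <- cfg$p_arm_length
    p12 <- cfg$repeat_unit_length *
      round(pl * cfg$band_fractions[["p12"]] / cfg$repeat_unit_length)
    p13 <- round(pl * cfg$band_fractions[["p13"]])
    p112 <- pl - p13 - p12
    if (min(p13, p12, p112) <= 0)
      stop("band fractions produce an empty acrocentric band")
    data.frame(
      label = c("p13", "p12", "p11.2", "q"),
      start = cumsum(c(0L, p13, p12, p112)),
      end = cumsum(c(p13, p12, p112, chrom_len - pl))
    )
  } else {
    p <- round(chrom_len * cfg$p_fraction)
    data.frame(label = c("p", "q"), start = c(0L, p), end = c(p, chrom_len))
  }
}

# Generate one band sequence; p12-like bands are exact tandem repeats of a
# single low-TA unit, other bands are i.i.d. with planted ATATATAT runs.
band_sequence <- function(cfg, label, len) {
  d <- cfg$ta_density[[label]]
  if (is.null(d)) d <- cfg$ta_density[["q"]]
  if (label == "p12") {
    unit <- random_dna(cfg$repeat_unit_length, ta_probs(d))
    return(paste(rep(unit, len / cfg$repeat_unit_length), collapse = ""))
  }
  s <- random_dna(len, ta_probs(d))
  n_runs <- floor(len / 1000 * cfg$at_runs_per_kb)
  if (n_runs > 0 && len > 20) {
    at <- "ATATATAT"
    pos <- sample.int(len - 12L, n_runs) + 2L # keep off band edges
    for (p in pos) substr(s, p, p + 7L) <- at
  }
  s
}

#' Build a synthetic genome with nucleolus-like structure
#'
#' Assembles chromosome sequences band by band from a [genome_config()],
#' guaranteeing that each acrocentric p12-like band (the NOR emulation) has
#' strictly lower TA-dinucleotide density than its flanking p13/p11.2-like
#' bands, and that it consists of exact tandem copies of one repeat unit.
#' Annotation interval sets (NAD, LAD_A, LAD_B, UBTF_peak, POL2_peak,
#' POL3_peak) are placed preferentially on the acrocentric chromosomes so
#' region-level targeting bias propagates to them as it does in real
#' nucleolar chromatin.
#'
#' @param config a [genome_config()].
#' @return an object of class `GenomeModel`: list with `seq` (named
#'   character vector), `acrocentric` (named logical), `cytobands`
#'   (`GRanges` with a `label` column), `annotations` (named list of
#'   `GRanges`), `ta` (data.frame of 0-based TA positions) and `config`.
#' @export
build_genome <- function(config = genome_config()) {
  validate_genome_config(config)
  withr::with_seed(derive_seed(config$seed, 1L), {
    ch <- config$chromosomes
    seqs <- character(nrow(ch))
    names(seqs) <- ch$name
    bands <- vector("list", nrow(ch))
    for (i in seq_len(nrow(ch))) {
      lay <- band_layout(config, ch$acrocentric[i], ch$length[i])
      lay$chrom <- ch$name[i]
      for (attempt in 1:100) {
        parts <- vapply(seq_len(nrow(lay)), function(j) {
          band_sequence(config, lay$label[j], lay$end[j] - lay$start[j])
        }, character(1))
        if (!ch$acrocentric[i]) break
        dens <- vapply(parts, ta_density, numeric(1))
        names(dens) <- lay$label
        if (dens[["p12"]] < min(dens[["p13"]], dens[["p11.2"]])) break
      }
      seqs[i] <- paste(parts, collapse = "")
      bands[[i]] <- lay
    }
    bands <- do.call(rbind, bands)
    cyto <- GenomicRanges::GRanges(
      seqnames = bands$chrom,
      ranges = IRanges::IRanges(start = bands$start + 1L, end = bands$end)
    )
    S4Vectors::mcols(cyto)$label <- bands$label
    genome <- structure(
      list(seq = seqs,
           acrocentric = stats::setNames(ch$acrocentric, ch$name),
           cytobands = cyto,
           annotations = list(),
           ta = NULL,
           config = config),
      class = "GenomeModel")
    genome$annotations <- place_annotations(genome, config)
    genome$ta <- ta_site_table(genome)
    genome
  })
}

# Enumerate all TA sites of the genome (0-based position of the T).
ta_site_table <- function(genome) {
  out <- lapply(names(genome$seq), function(ch) {
    pos <- ta_positions(genome$seq[[ch]])
    if (length(pos) == 0L) return(NULL)
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# Place the NAD/LAD/TF-peak annotation sets, mostly on acrocentric
# chromosomes (NADs adjacent to the p-arm, peaks inside p13/p11.2).
place_annotations <- function(genome, cfg) {
  ch <- cfg$chromosomes
  acro <- ch$name[ch$acrocentric]
  nonacro <- ch$name[!ch$acrocentric]
  lens <- stats::setNames(ch$length, ch$name)
  # consistent seqlevels across chromosomes so set concatenation is clean
  gr1 <- function(chrom, start1, end1) {
    GenomicRanges::GRanges(factor(chrom, levels = ch$name),
                           IRanges::IRanges(start1, end1))
  }
  rand_iv <- function(chrom, lo, hi, w) {
    if (hi - w <= lo)
      stop("annotation interval of width ", w, " does not fit in ",
           chrom, ":[", lo, ",", hi, "); shrink nad/lad/peak lengths ",
           "for so small a genome")
    s <- floor(runif(1, lo, hi - w))
    gr1(chrom, s + 1L, s + w)
  }
  # NADs: one domain immediately distal to each acrocentric p-arm, plus one
  # interior domain on the first non-acrocentric chromosome.
  nad <- c(
    do.call(c, lapply(acro, function(a) {
      gr1(a, cfg$p_arm_length + 1L, cfg$p_arm_length + cfg$nad_length)
    })),
    rand_iv(nonacro[1], lens[nonacro[1]] * 0.5, lens[nonacro[1]], cfg$nad_length)
  )
  # LADs: several domains, two thirds on acrocentric q-arms.
  lad_set <- function() {
    ivs <- c(
      lapply(acro, function(a)
        rand_iv(a, cfg$p_arm_length + cfg$nad_length, lens[a], cfg$lad_length)),
      lapply(nonacro, function(a)
        rand_iv(a, 0, lens[a], cfg$lad_length))
    )
    sort(do.call(c, ivs))
  }
  # TF peaks: UBTF-like concentrated in the NOR-flanking bands,
  # Pol II/III-like scattered over non-acrocentric chromosomes.
  peak_in_band <- function(chrom, label) {
    cb <- genome$cytobands
    sel <- cb[as.character(GenomicRanges::seqnames(cb)) == chrom &
                S4Vectors::mcols(cb)$label == label]
    rand_iv(chrom, GenomicRanges::start(sel) - 1L,
            GenomicRanges::end(sel), cfg$peak_length)
  }
  ubtf <- do.call(c, c(
    lapply(rep(acro, each = 2), function(a) peak_in_band(a, "p13")),
    lapply(rep(acro, each = 2), function(a) peak_in_band(a, "p11.2")),
    lapply(nonacro, function(a) rand_iv(a, 0, lens[a], cfg$peak_length))
  ))
  scatter_peaks <- function(n_per_chrom) {
    do.call(c, lapply(rep(nonacro, each = n_per_chrom), function(a)
      rand_iv(a, 0, lens[a], cfg$peak_length)))
  }
  list(NAD = sort(nad), LAD_A = lad_set(), LAD_B = lad_set(),
       UBTF_peak = sort(ubtf), POL2_peak = sort(scatter_peaks(8L)),
       POL3_peak = sort(scatter_peaks(8L)))
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat("GenomeModel:", length(x$seq), "chromosomes,",
      sum(nchar(x$seq)), "bp,", nrow(x$ta), "TA sites\n")
  cat("  acrocentric:", paste(names(x$seq)[x$acrocentric], collapse = ", "),
      "\n")
  cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Load a genome model from FASTA and BED files
#'
#' Real-data entry point: reconstructs a `GenomeModel` from a genome
#' FASTA, a BED4 cytoband file and optional named annotation BEDs, so
#' that the downstream analysis runs identically on simulated and real
#' inputs. A chromosome is flagged acrocentric when its cytobands include
#' a p12 label.
#'
#' @param fasta_path genome FASTA.
#' @param cytoband_path BED4 cytoband file (chrom, start, end, label).
#' @param annotation_paths named character vector of BED paths (e.g.
#'   `c(NAD = "nad.bed", ...)`).
#' @return a `GenomeModel`.
#' @export
load_genome <- function(fasta_path, cytoband_path, annotation_paths = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  seqv <- stats::setNames(as.character(seqs), names(seqs))
  cyto <- read_bed(cytoband_path)
  cb_chrom <- as.character(GenomicRanges::seqnames(cyto))
  acro <- vapply(names(seqv), function(ch)
    any(S4Vectors::mcols(cyto)$label[cb_chrom == ch] == "p12"), logical(1))
  ann <- list()
  for (nm in names(annotation_paths))
    ann[[nm]] <- read_bed(annotation_paths[[nm]])
  genome <- structure(
    list(seq = seqv, acrocentric = acro, cytobands = cyto,
         annotations = ann, ta = NULL, config = NULL),
    class = "GenomeModel")
  genome$ta <- ta_site_table(genome)
  genome
}

#' Resolve a region label to genomic intervals
#'
#' Labels understood: `"acro_p_arm"` (union of p13/p12/p11.2 on acrocentric
#' chromosomes), any cytoband label (`p13`, `p12`, `p11.2`, `p`, `q`),
#' `"<chrom>_p_arm"` for a single acrocentric p-arm, or the name of an
#' annotation set (`NAD`, `LAD_A`, `LAD_B`, `UBTF_peak`, `POL2_peak`,
#' `POL3_peak`).
#'
#' @param genome a `GenomeModel`.
#' @param label region label.
#' @return `GRanges`.
#' @export
region_by_label <- function(genome, label) {
  cb <- genome$cytobands
  cb_chrom <- as.character(GenomicRanges::seqnames(cb))
  acro_names <- names(genome$acrocentric)[genome$acrocentric]
  if (label == "acro_p_arm") {
    sel <- cb[cb_chrom %in% acro_names &
                S4Vectors::mcols(cb)$label %in% c("p13", "p12", "p11.2")]
    return(GenomicRanges::reduce(sel))
  }
  if (grepl("_p_arm$", label)) {
    chrom <- sub("_p_arm$", "", label)
    sel <- cb[cb_chrom == chrom &
                S4Vectors::mcols(cb)$label %in% c("p13", "p12", "p11.2", "p")]
    if (length(sel) == 0L) stop("unknown chromosome in region label: ", label)
    return(GenomicRanges::reduce(sel))
  }
  if (label %in% S4Vectors::mcols(cb)$label)
    return(cb[S4Vectors::mcols(cb)$label == label])
  if (label %in% names(genome$annotations))
    return(genome$annotations[[label]])
  stop("unknown region label: ", label)
}

#' Standard region sets for condition comparison
#'
#' The labelled interval sets over which the analysis compares two
#' transposase conditions: the pooled acrocentric p-arms, the three
#' acrocentric cytobands, each individual acrocentric p-arm, and the
#' NAD/LAD/TF-peak annotation sets (TF peaks expanded by `pad`).
#'
#' @param genome a `GenomeModel`.
#' @param pad expansion applied to TF-peak sets (see [expand_peaks()]).
#' @return named list of `GRanges`.
#' @export
standard_region_sets <- function(genome, pad = 500L) {
  acro <- names(genome$acrocentric)[genome$acrocentric]
  sets <- c(
    list(acro_p_arm = region_by_label(genome, "acro_p_arm"),
         p13 = region_by_label(genome, "p13"),
         p12 = region_by_label(genome, "p12"),
         p11.2 = region_by_label(genome, "p11.2")),
    stats::setNames(
      lapply(acro, function(a) region_by_label(genome, paste0(a, "_p_arm"))),
      paste0(acro, "_p_arm")),
    list(NAD = genome$annotations$NAD,
         LAD_A = genome$annotations$LAD_A,
         LAD_B = genome$annotations$LAD_B,
         UBTF_peak = expand_peaks(genome$annotations$UBTF_peak, pad, genome),
         POL2_peak = expand_peaks(genome$annotations$POL2_peak, pad, genome),
         POL3_peak = expand_peaks(genome$annotations$POL3_peak, pad, genome))
  )
  sets
}

#' Write the genome as FASTA
#'
#' @param genome a `GenomeModel`.
#' @param path output FASTA path (80-column wrapped).
#' @return invisibly, the path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path,
                              width = 80L)
  invisible(path)
}

#' Write cytobands and annotation sets as BED
#'
#' Cytobands go to `<prefix>cytobands.bed` (BED4), each annotation set to
#' `<prefix><name>.bed`.
#'
#' @param genome a `GenomeModel`.
#' @param prefix path prefix for the emitted files.
#' @return character vector of written paths.
#' @export
write_genome_beds <- function(genome, prefix) {
  paths <- paste0(prefix, "cytobands.bed")
  write_bed(genome$cytobands, paths)
  for (nm in names(genome$annotations)) {
    p <- paste0(prefix, nm, ".bed")
    write_bed(genome$annotations[[nm]], p, name = nm)
    paths <- c(paths, p)
  }
  invisible(paths)
}
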