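#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the genome spec, the two
#' transposase condition models, insertion counts, library parameters,
#' read-processing thresholds and the site-calling regime.
#'
#' The default condition pair emulates the fusion-transposase experiment:
#' condition A is an unbiased SB100X transposase, condition B a
#' nucleolar-retargeted B23-SB100X fusion with a 1.64-fold per-TA-site
#' bias on the acrocentric p-arms and milder biases on the NAD/LAD/UBTF
#' annotation sets.
#'
#' @param genome_cfg a [genome_config()].
#' @param model_A,model_B [target_model()]s for the two conditions.
#' @param n_insertions truth insertion events per condition.
#' @param fragments_per_insertion mean sonication fragments recovered per
#'   insertion event (clonal expansion; see [expand_insertions()]).
#' @param library a [library_params()]; its `barcode_map` must contain
#'   both condition labels.
#' @param mode mapping/calling regime: `"unique"` or `"random"`.
#' @param min_support minimum distinct-shear-key support per called site.
#' @param min_len,primer_max_mismatch,ir_max_mismatch read-processing
#'   thresholds.
#' @param peak_pad TF-peak expansion (nt).
#' @param n_bins windows per cytoband profile.
#' @param seed master seed; every stage derives its own stream from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(
    genome_cfg = genome_config(),
    model_A = target_model(condition_label = "SB100X"),
    model_B = target_model(
      region_bias = list(acro_p_arm = 1.64, NAD = 1.35, LAD_A = 1.3,
                         LAD_B = 1.3, UBTF_peak = 1.46),
      condition_label = "B23-SB100X"),
    n_insertions = 2000L,
    fragments_per_insertion = 8,
    library = library_params(),
    mode = c("unique", "random"),
    min_support = 5L,
    min_len = 30L,
    primer_max_mismatch = 6L,
    ir_max_mismatch = 2L,
    peak_pad = 500L,
    n_bins = 300L,
    seed = 1L) {
  mode <- match.arg(mode)
  labs <- c(model_A$condition_label, model_B$condition_label)
  if (!all(labs %in% names(library$barcode_map)))
    stop("library barcode_map must contain both condition labels")
  structure(list(genome_cfg = genome_cfg, model_A = model_A,
                 model_B = model_B, n_insertions = n_insertions,
                 fragments_per_insertion = fragments_per_insertion,
                 library = library, mode = mode, min_support = min_support,
                 min_len = min_len,
                 primer_max_mismatch = primer_max_mismatch,
                 ir_max_mismatch = ir_max_mismatch, peak_pad = peak_pad,
                 n_bins = n_bins, seed = seed),
            class = "pipeline_config")
}

#' Run the full integration-site analysis pipeline
#'
#' Executes genome construction, truth simulation, junction-library
#' simulation, demultiplexing, read processing, mapping, site calling,
#' region enrichment and the target-site logo, writing all artifacts
#' under `outdir` together with a machine-readable run manifest. Output
#' is byte-deterministic given (`config`, `seed`).
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if absent).
#' @param seed master seed, defaulting to the config's.
#' @param write_fastq write the simulated FASTQ pair (default TRUE).
#' @param write_profiles write per-cytoband RPKM and TA-density profile
#'   tables (default TRUE).
#' @return invisibly, a list with the genome, truth sets, called site
#'   sets, enrichment table, PFMs and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, seed = config$seed,
                         write_fastq = TRUE, write_profiles = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pathto <- function(...) file.path(outdir, paste0(...))
  labs <- c(A = config$model_A$condition_label,
            B = config$model_B$condition_label)

  # --- genome ---------------------------------------------------------
  gcfg <- config$genome_cfg
  gcfg$seed <- derive_seed(seed, 11L)
  genome <- build_genome(gcfg)
  write_genome_fasta(genome, pathto("genome.fa"))
  write_genome_beds(genome, file.path(outdir, ""))

  # --- truth + libraries ----------------------------------------------
  models <- list(A = config$model_A, B = config$model_B)
  truth <- list(); libs <- list()
  for (cc in c("A", "B")) {
    truth[[cc]] <- simulate_insertions(genome, models[[cc]],
                                       config$n_insertions,
                                       seed = derive_seed(seed, 20L + match(cc, c("A", "B"))))
    write_insertions_bed(truth[[cc]], pathto("truth_", labs[[cc]], ".bed"))
    molecules <- expand_insertions(
      truth[[cc]], config$fragments_per_insertion,
      seed = derive_seed(seed, 25L + match(cc, c("A", "B"))))
    libs[[cc]] <- simulate_junction_library(
      molecules, genome, config$library, sample_label = labs[[cc]],
      seed = derive_seed(seed, 30L + match(cc, c("A", "B"))))
  }
  pooled <- rbind(libs$A, libs$B)
  if (write_fastq)
    write_fastq_pairs(pooled, pathto("reads_R1.fastq.gz"),
                      pathto("reads_R2.fastq.gz"))

  # --- processing + mapping + calling ---------------------------------
  demux <- demultiplex(pooled, config$library$barcode_map)
  index <- build_index(genome)
  sites <- list(); stage_counts <- list()
  for (cc in c("A", "B")) {
    lab <- labs[[cc]]
    junc <- process_reads(demux[[lab]], config$library,
                          config$library$barcode_map[[lab]],
                          primer_max_mismatch = config$primer_max_mismatch,
                          ir_max_mismatch = config$ir_max_mismatch,
                          min_len = config$min_len)
    if (nrow(junc) == 0L)
      stop("no junction reads survived processing for condition ", lab)
    mapped <- map_junctions(junc, index, mode = config$mode,
                            seed = derive_seed(seed, 40L + match(cc, c("A", "B"))))
    sites[[cc]] <- call_sites(mapped, genome,
                              min_support = config$min_support,
                              mode = config$mode)
    write_sites_bed(sites[[cc]], pathto("sites_", lab, ".bed"),
                    header_comment = paste0("mode=", config$mode,
                                            " min_support=", config$min_support,
                                            " seed=", seed))
    stage_counts[[lab]] <- list(
      library_pairs = nrow(demux[[lab]]),
      processing = as.list(attr(junc, "stats")),
      mapping = as.list(attr(mapped, "stats")),
      called_sites = nrow(sites[[cc]]),
      called_sites_on_ta = sum(sites[[cc]]$on_ta))
  }
  if (!nrow(sites$A) || !nrow(sites$B))
    stop("no junction reads survived: a condition produced zero sites")

  # --- enrichment ------------------------------------------------------
  region_sets <- standard_region_sets(genome, pad = config$peak_pad)
  enr <- compare_conditions(sites$A, sites$B, region_sets, genome)
  write.table(format(enr, digits = 6, scientific = TRUE, trim = TRUE),
              pathto("enrichment.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(enr, pathto("enrichment.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "string")

  # --- profiles --------------------------------------------------------
  if (write_profiles) {
    cb <- genome$cytobands
    acro <- names(genome$acrocentric)[genome$acrocentric]
    sel <- cb[as.character(GenomicRanges::seqnames(cb)) %in% acro &
                S4Vectors::mcols(cb)$label != "q"]
    prof <- list(); tad <- list()
    for (i in seq_along(sel)) {
      band <- sel[i]
      chrom <- as.character(GenomicRanges::seqnames(band))
      blab <- S4Vectors::mcols(band)$label
      for (cc in c("A", "B")) {
        pr <- binned_rpkm_profile(sites[[cc]], band, n_bins = config$n_bins,
                                  total_sites = nrow(sites[[cc]]))
        prof[[length(prof) + 1L]] <- data.frame(
          chrom = chrom, band = blab, condition = labs[[cc]], pr)
      }
      td <- ta_density_profile(genome, band, n_bins = config$n_bins)
      tad[[length(tad) + 1L]] <- data.frame(chrom = chrom, band = blab, td)
    }
    write.table(format(do.call(rbind, prof), digits = 6, trim = TRUE),
                pathto("cytoband_rpkm_profiles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(format(do.call(rbind, tad), digits = 6, trim = TRUE),
                pathto("cytoband_ta_density.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # --- target-site logo ------------------------------------------------
  pfms <- list()
  for (cc in c("A", "B")) {
    on_ta <- sites[[cc]][sites[[cc]]$on_ta, ]
    ctx <- extract_contexts(on_ta, genome)
    pfms[[cc]] <- build_pfm(ctx)
    write_pfm_tsv(pfms[[cc]], pathto("pfm_", labs[[cc]], ".tsv"))
  }

  # --- manifest --------------------------------------------------------
  manifest <- list(
    package = "sbsites",
    version = as.character(utils::packageVersion("sbsites")),
    seed = seed,
    mode = config$mode,
    min_support = config$min_support,
    n_insertions = config$n_insertions,
    fragments_per_insertion = config$fragments_per_insertion,
    conditions = as.vector(labs),
    region_bias_B = config$model_B$region_bias,
    library = config$library[c("shear_mean", "size_select", "read_length",
                               "pcr_duplication_rate", "error_rate",
                               "backbone_fraction")],
    genome = list(chromosomes = gcfg$chromosomes,
                  p_arm_length = gcfg$p_arm_length,
                  repeat_unit_length = gcfg$repeat_unit_length),
    stage_counts = stage_counts)
  jsonlite::write_json(manifest, pathto("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(genome = genome, truth = truth, sites = sites,
                 enrichment = enr, pfms = pfms, manifest = manifest,
                 outdir = outdir))
}
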