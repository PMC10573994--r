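#!/usr/bin/env Rscript

# Stage 1 — simulate the study's raw materials.
#
# Builds the synthetic genome (three acrocentric chromosomes whose p12
# bands emulate TA-poor, internally repetitive NORs, plus two
# non-acrocentric chromosomes), then simulates the two transposase
# conditions: unbiased SB100X and the nucleolar-retargeted B23-SB100X
# fusion (1.64-fold per-TA-site bias on the acrocentric p-arms, milder
# bias on NAD/LAD/UBTF domains). Each insertion event is expanded into
# sonication fragments and sequenced as a 2x150 junction library with
# PCR duplicates, sequencing errors and plasmid-backbone contamination.

suppressMessages(library(sbsites))

seed <- 1234L
outdir <- "results/01_simulate"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- build_genome(genome_config(seed = seed))
write_genome_fasta(genome, file.path(outdir, "genome.fa"))
write_genome_beds(genome, file.path(outdir, ""))
cat("genome:", length(genome$seq), "chromosomes,",
    sum(nchar(genome$seq)), "bp,", nrow(genome$ta), "TA sites\n")

models <- list(
  "SB100X" = target_model(condition_label = "SB100X"),
  "B23-SB100X" = target_model(
    region_bias = list(acro_p_arm = 1.64, NAD = 1.35, LAD_A = 1.3,
                       LAD_B = 1.3, UBTF_peak = 1.46),
    condition_label = "B23-SB100X")
)
params <- library_params(seed = seed)

n_events <- 3000L
libs <- list()
for (lab in names(models)) {
  truth <- simulate_insertions(genome, models[[lab]], n_events,
                               seed = seed + match(lab, names(models)))
  write_insertions_bed(truth, file.path(outdir, paste0("truth_", lab, ".bed")))
  molecules <- expand_insertions(truth, mean_fragments = 8,
                                 seed = seed + 10L + match(lab, names(models)))
  libs[[lab]] <- simulate_junction_library(
    molecules, genome, params, sample_label = lab,
    seed = seed + 20L + match(lab, names(models)))
  cat(sprintf("%-12s %d events -> %d fragment molecules -> %d read pairs\n",
              lab, n_events, attr(libs[[lab]], "n_molecules"),
              nrow(libs[[lab]])))
}

pooled <- do.call(rbind, libs)
write_fastq_pairs(pooled, file.path(outdir, "reads_R1.fastq.gz"),
                  file.path(outdir, "reads_R2.fastq.gz"))

jsonlite::write_json(
  list(ir_sequence = params$ir_sequence, primer = params$primer,
       barcode_map = as.list(params$barcode_map),
       backbone = params$backbone, shear_mean = params$shear_mean,
       size_select = params$size_select, read_length = params$read_length,
       pcr_duplication_rate = params$pcr_duplication_rate,
       error_rate = params$error_rate,
       backbone_fraction = params$backbone_fraction, seed = seed),
  file.path(outdir, "library_params.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat("wrote", nrow(pooled), "pooled read pairs and the params record to",
    outdir, "\n")
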