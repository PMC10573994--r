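#!/usr/bin/env Rscript

# Stage 2 — from raw reads to called insertion sites.
#
# Reads the stage-1 FASTQ pair back in, demultiplexes by barcode,
# enforces the junction structure (IR primer within 6 mismatches,
# residual IR within 2), discards plasmid-backbone reads, removes PCR
# duplicates by exact sequence, merges overlapping mates and maps the
# junctions with the k-mer seed-and-verify aligner. Sites are called
# under both regimes the analysis uses: unique mapping with >= 5
# independent (distinct-shear) supporting reads, and random multimapper
# assignment with single-read support for the repetitive NOR-like bands.

suppressMessages(library(sbsites))

seed <- 1234L
indir <- "results/01_simulate"
outdir <- "results/02_sites"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- load_genome(
  file.path(indir, "genome.fa"), file.path(indir, "cytobands.bed"),
  stats::setNames(file.path(indir, paste0(c("NAD", "LAD_A", "LAD_B",
                                            "UBTF_peak", "POL2_peak",
                                            "POL3_peak"), ".bed")),
                  c("NAD", "LAD_A", "LAD_B", "UBTF_peak", "POL2_peak",
                    "POL3_peak")))
pj <- jsonlite::read_json(file.path(indir, "library_params.json"),
                          simplifyVector = TRUE)
params <- library_params(ir_sequence = pj$ir_sequence, primer = pj$primer,
                         barcode_map = unlist(pj$barcode_map),
                         backbone = pj$backbone, seed = pj$seed)

pairs <- read_fastq_pairs(file.path(indir, "reads_R1.fastq.gz"),
                          file.path(indir, "reads_R2.fastq.gz"))
demux <- demultiplex(pairs, params$barcode_map)
cat("demultiplexed:", paste(names(attr(demux, "counts")),
                            attr(demux, "counts"), collapse = ", "), "\n")

index <- build_index(genome)
stats_rows <- list()
for (lab in names(params$barcode_map)) {
  junc <- process_reads(demux[[lab]], params, params$barcode_map[[lab]])
  st <- attr(junc, "stats")
  cat(sprintf("%-12s %d pairs -> %d junctions (dups %d, backbone %d)\n",
              lab, st[["input"]], st[["surviving"]], st[["duplicate"]],
              st[["backbone_discard"]]))
  for (mode in c("unique", "random")) {
    mapped <- map_junctions(junc, index, mode = mode,
                            seed = seed + 30L + match(mode, c("unique", "random")))
    min_sup <- if (mode == "unique") 5L else 1L
    sites <- call_sites(mapped, genome, min_support = min_sup, mode = mode)
    write_sites_bed(sites, file.path(outdir,
                                     paste0("sites_", lab, "_", mode, ".bed")),
                    header_comment = paste0("mode=", mode, " min_support=",
                                            min_sup, " seed=", seed))
    ms <- attr(mapped, "stats")
    cat(sprintf("  %-7s mapped %d/%d (multi %d) -> %d sites (support >= %d)\n",
                mode, ms[["mapped"]], ms[["input"]], ms[["multimapping"]],
                nrow(sites), min_sup))
    stats_rows[[paste(lab, mode)]] <- data.frame(
      condition = lab, mode = mode, t(as.matrix(st)), t(as.matrix(ms)),
      called_sites = nrow(sites))
  }
}
write.table(do.call(rbind, stats_rows), file.path(outdir, "stage_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote site BEDs and stage_stats.tsv to", outdir, "\n")
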