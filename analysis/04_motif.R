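#!/usr/bin/env Rscript

# Stage 4 — target-site sequence logo QC.
#
# Extracts the +/-10 bp sequence context of every called (unique-mode)
# insertion site, builds the position frequency matrix and per-column
# information content, and reports the centre of the motif. SB's
# absolute TA requirement shows as two 2-bit centre columns; the
# flanking columns lean towards the palindromic AT pattern.

suppressMessages(library(sbsites))

indir1 <- "results/01_simulate"
indir2 <- "results/02_sites"
outdir <- "results/04_motif"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- load_genome(file.path(indir1, "genome.fa"),
                      file.path(indir1, "cytobands.bed"))

for (lab in c("SB100X", "B23-SB100X")) {
  gr <- read_bed(file.path(indir2, paste0("sites_", lab, "_unique.bed")))
  sites <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      pos = GenomicRanges::start(gr) - 1L)
  ctx <- extract_contexts(sites, genome, flank = 10L)
  pf <- build_pfm(ctx)
  write_pfm_tsv(pf, file.path(outdir, paste0("pfm_", lab, ".tsv")))
  centre8 <- paste(rownames(pf$matrix)[apply(pf$matrix[, 8:15], 2,
                                             which.max)], collapse = "")
  cat(sprintf("%-12s %4d sites  centre f(T)=%.3f f(A)=%.3f  8-bp consensus %s\n",
              lab, pf$n_sites, pf$matrix["T", 11], pf$matrix["A", 12],
              centre8))
}
cat("wrote PFM tables to", outdir, "\n")
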