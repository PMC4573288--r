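#!/usr/bin/env Rscript
# Stage 1: generate the synthetic three-pool cfDNA methylome study.
#
# Three pooled plasma methylomes are simulated on a 2 Mb chromosome with 200
# CpG islands: H-like and DFS-like pools at their study depths (7.4 and 9.6
# reads per strand-cytosine), and an MBC-like pool (depth 16.9) carrying a
# global background hypomethylation shift plus 10 planted island
# hypermethylation hotspots. Writes Bismark-style cytosine reports, context
# BED tracks, and the ground-truth manifest under results/sim/.

suppressPackageStartupMessages(library(cfmeth))

seed <- 1L
outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

study <- simulate_study(seed = seed)

for (lab in names(study$pools)) {
  write_cytosine_report(study$pools[[lab]],
                        file.path(outdir, paste0(lab, ".CpG_report.txt")))
}
for (cat in names(study$tracks)) {
  write_bed_track(study$tracks[[cat]], file.path(outdir, paste0(cat, ".bed")))
}
write_truth(study$truth, file.path(outdir, "truth.json"))

depths <- vapply(study$pools, function(p) mean(coverage_of(p)), numeric(1))
cat(sprintf("simulated %d CpG dyads (%d strand loci per pool) on %s\n",
            nrow(study$cpgs), 2L * nrow(study$cpgs),
            study$genome$chromosomes$name[1]))
cat(sprintf("islands: %d (%d planted as hotspots at level %.2f in %s)\n",
            nrow(study$genome$islands),
            nrow(study$truth$planted_hotspot_islands),
            study$truth$planted_hyper_level,
            study$truth$affected_pool_label))
cat("mean per-strand coverage:",
    paste(sprintf("%s=%.2f", names(depths), depths), collapse = ", "), "\n")
cat("wrote cytosine reports, BED tracks and truth manifest to", outdir, "\n")
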