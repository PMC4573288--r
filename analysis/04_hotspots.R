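#!/usr/bin/env Rscript
# Stage 4: CpG-island hypermethylation hotspot calling — islands with at
# least 8 hypermethylated DML at DMV >= 50 — for both case comparisons, the
# consensus across the two, and recovery scoring against the planted truth.
# Writes hotspot BEDs and recovery metrics under results/hotspots/.

suppressPackageStartupMessages(library(cfmeth))

simdir <- "results/sim"
dmldir <- "results/dml"
outdir <- "results/hotspots"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

islands <- read_bed_track(file.path(simdir, "CPGI.bed"), "CPGI")
truth <- read_truth(file.path(simdir, "truth.json"))
params <- hotspot_params()  # min_dml 8, min_dmv 50, hyper only

calls <- list()
for (tag in c("MBC_vs_H", "MBC_vs_DFS")) {
  rec <- read_dml_table(file.path(dmldir, paste0(tag, ".dml.tsv")))
  class(rec) <- c("dml_records", class(rec))
  h <- call_hotspots(rec, islands, params)
  calls[[tag]] <- h
  write_hotspot_bed(h, file.path(outdir, paste0(tag, ".hotspots.bed")))
  sc <- score_recovery(h, truth)
  cat(sprintf("%s: %d hotspot island(s); recovery %d/%d planted, %d false positive(s)\n",
              tag, nrow(h), sc$n_recovered, sc$n_planted,
              sc$n_false_positive))
}

consensus <- intersect(calls$MBC_vs_H$name, calls$MBC_vs_DFS$name)
keep <- calls$MBC_vs_H[calls$MBC_vs_H$name %in% consensus, ]
write_hotspot_bed(structure(keep, class = class(calls$MBC_vs_H)),
                  file.path(outdir, "consensus.hotspots.bed"))
write_summary_json(
  list(per_comparison = lapply(calls, function(h) h$name),
       consensus = consensus,
       recovery = lapply(calls, score_recovery, truth = truth)),
  file.path(outdir, "recovery.json"))
cat(sprintf("consensus hotspot signature (both case comparisons): %d island(s)\n",
            length(consensus)))
cat(" ", paste(consensus, collapse = ", "), "\n")
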