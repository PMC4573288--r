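#!/usr/bin/env Rscript
# Stage 3: genomic-context annotation of the DML calls (CPGI, TSS1500, UTR5,
# Exon1, GeneBody) and per-context hyper/hypo summaries — the pie-chart
# statistics of the study design. Reads stage-1 tracks and stage-2 DML
# tables; writes annotated tables and context summaries under results/dml/.

suppressPackageStartupMessages(library(cfmeth))

simdir <- "results/sim"
dmldir <- "results/dml"

cats <- c("CPGI", "TSS1500", "UTR5", "Exon1", "GeneBody")
tracks <- lapply(stats::setNames(cats, cats), function(cc) {
  read_bed_track(file.path(simdir, paste0(cc, ".bed")), cc)
})

for (tag in c("MBC_vs_H", "MBC_vs_DFS", "H_vs_DFS")) {
  rec <- read_dml_table(file.path(dmldir, paste0(tag, ".dml.tsv")))
  class(rec) <- c("dml_records", class(rec))
  ann <- annotate_dml(rec, tracks)
  write_dml_table(ann, file.path(dmldir, paste0(tag, ".annotated.tsv")))
  ctx <- summarize_contexts(ann)
  write_summary_json(ctx, file.path(dmldir, paste0(tag, ".contexts.json")))
  cat(tag, "\n")
  print(ctx, digits = 3)
  top <- ctx[ctx$category != "genome_wide" & ctx$n_dml > 0, ]
  cat(sprintf("  -> largest hypermethylated fraction: %s (%.0f%%)\n",
              top$category[which.max(top$pct_hyper)], max(top$pct_hyper)))
}
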