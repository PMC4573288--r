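#!/usr/bin/env Rscript
# Stage 2: per-base differential methylation for the three pairwise
# comparisons (case listed first): MBC vs H, MBC vs DFS, H vs DFS.
#
# Pools are destranded, united at a minimum coverage of 5 in each group, and
# tested per locus with the two-sided Fisher exact test; loci with |DMV| >=
# 20 percentage points and P <= 0.05 are reported as DML (no q-value bound
# for the genome-wide call). Reads the stage-1 reports; writes DML tables
# and a direction summary under results/dml/.

suppressPackageStartupMessages(library(cfmeth))

indir <- "results/sim"
outdir <- "results/dml"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

pools <- lapply(c(H = "H", DFS = "DFS", MBC = "MBC"), function(lab) {
  read_cytosine_report(file.path(indir, paste0(lab, ".CpG_report.txt")),
                       label = lab)
})

params <- diffmeth_params()  # coverage 5, DMV 20, P 0.05, destrand, no q
summaries <- list()
for (cmp in list(c("MBC", "H"), c("MBC", "DFS"), c("H", "DFS"))) {
  tag <- paste0(cmp[1], "_vs_", cmp[2])
  rec <- call_dml(pools[[cmp[1]]], pools[[cmp[2]]], params)
  write_dml_table(rec, file.path(outdir, paste0(tag, ".dml.tsv")),
                  params = list(case = cmp[1], control = cmp[2]))
  s <- dml_summary(rec)
  summaries[[tag]] <- s
  cat(sprintf("%s: %d united loci, %d DML (%.1f%% hypomethylated in %s)\n",
              tag, s$n_united, s$n_dml, s$pct_hypo, cmp[1]))
}
write_summary_json(do.call(rbind, summaries),
                   file.path(outdir, "dml_summary.json"))

n_mbc <- summaries$MBC_vs_H$n_dml
n_hd <- summaries$H_vs_DFS$n_dml
cat(sprintf(paste0("the case-pool comparisons yield ~%.0fx the DML of the\n",
                   "H vs DFS comparison (%d and %d vs %d), the similarity/\n",
                   "divergence structure expected of the three pools\n"),
            n_mbc / max(1, n_hd), n_mbc, summaries$MBC_vs_DFS$n_dml, n_hd))
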