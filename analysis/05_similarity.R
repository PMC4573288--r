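#!/usr/bin/env Rscript
# Stage 5: pool-level similarity — pairwise Pearson correlation of percent
# methylation profiles on the common covered loci, Ward clustering on
# correlation distance, PCA, and per-pool percent methylation histograms.
# Writes results/similarity.json and a summary figure (PDF).

suppressPackageStartupMessages(library(cfmeth))

indir <- "results/sim"
dir.create("results", showWarnings = FALSE)

pools <- lapply(c(H = "H", DFS = "DFS", MBC = "MBC"), function(lab) {
  destrand_merge(read_cytosine_report(
    file.path(indir, paste0(lab, ".CpG_report.txt")), label = lab))
})

rep <- similarity_report(pools, min_coverage = 5)
write_summary_json(
  list(pearson = as.data.frame(rep$pearson), clustering = rep$clustering,
       pca = list(scores = as.data.frame(rep$pca$scores),
                  explained = rep$pca$explained),
       histograms = rep$histograms, n_loci = rep$n_loci),
  "results/similarity.json")

cat(sprintf("common loci at coverage >= 5 in all pools: %d\n", rep$n_loci))
cat("pairwise Pearson r:\n")
print(round(rep$pearson, 3))
first <- rep$clustering$labels[-rep$clustering$merge[1, ]]
cat("first merge in Ward clustering:", paste(first, collapse = " + "), "\n")
sc1 <- rep$pca$scores[, 1]
cat(sprintf("PC1 extreme pool: %s (%.0f%% of variance on PC1)\n",
            names(which.max(abs(sc1 - stats::median(sc1)))),
            100 * rep$pca$explained[1]))
mass50 <- vapply(rep$histograms, function(h) {
  100 * sum(h$count[h$bin_high <= 50]) / sum(h$count)
}, numeric(1))
cat("percent of loci below 50% methylation:",
    paste(sprintf("%s=%.1f%%", names(mass50), mass50), collapse = ", "), "\n")

pdf("results/similarity.pdf", width = 9, height = 3.2)
op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
for (lab in names(rep$histograms)) {
  h <- rep$histograms[[lab]]
  barplot(h$count / sum(h$count), names.arg = h$bin_low, las = 2,
          main = paste(lab, "% methylation"), ylab = "frequency",
          cex.names = 0.6)
}
par(op)
dev.off()
cat("wrote results/similarity.json and results/similarity.pdf\n")
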