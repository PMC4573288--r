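#!/usr/bin/env Rscript
# Stage 6: cross-platform validation. Four hotspot islands are treated as
# targeted amplicons and re-measured at deep coverage (a targeted bisulfite
# amplicon assay of the same material); per-locus percent methylation is
# paired between the platforms across all three pools, and each amplicon is
# tested case vs control on aggregated counts (Fisher exact, BH q <= 0.5).
# Writes results/concordance/.

suppressPackageStartupMessages(library(cfmeth))

seed <- 1L
outdir <- "results/concordance"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

# deep platform replicates need the underlying true proportions: re-simulate
# the stage-1 study (same seed, byte-identical pools)
study <- simulate_study(seed = seed)
amp <- study$truth$planted_hotspot_islands[1:4, ]
cat("amplicon targets (planted hotspot islands):",
    paste(amp$name, collapse = ", "), "\n")

pairs <- do.call(rbind, lapply(names(study$pools), function(lab) {
  deep <- sim_pool_params(paste0(lab, "_deep"), depth_mean = 250 * 17)
  rep2 <- simulate_platform_replicate(
    study$pools[[lab]], deep, target_regions = amp,
    seed = derive_seed(seed, paste0("platform2_", lab)))
  p <- pair_platforms(destrand_merge(study$pools[[lab]]),
                      destrand_merge(rep2), amp)
  p$pool <- lab
  p
}))
utils::write.table(pairs, file.path(outdir, "paired_measurements.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

st <- concordance_stats(pairs)
write_summary_json(st[c("n_loci", "pearson_r", "r_squared", "depth")],
                   file.path(outdir, "concordance.json"))
cat(sprintf("paired loci: %d; Pearson r = %.3f, R^2 = %.3f\n",
            st$n_loci, st$pearson_r, st$r_squared))
cat(sprintf("mean depth: %.1f (platform 1) vs %.0f (platform 2)\n",
            st$depth$mean_cov_p1, st$depth$mean_cov_p2))

# per-amplicon exact tests on the deep platform, MBC vs each control
deep_pools <- lapply(names(study$pools), function(lab) {
  deep <- sim_pool_params(paste0(lab, "_deep"), depth_mean = 250 * 17)
  simulate_platform_replicate(study$pools[[lab]], deep, target_regions = amp,
                              seed = derive_seed(seed,
                                                 paste0("platform2_", lab)))
})
names(deep_pools) <- names(study$pools)
agg <- lapply(deep_pools, aggregate_amplicon_counts, target_regions = amp)
for (control in c("H", "DFS")) {
  res <- per_group_test(agg$MBC, agg[[control]])
  res$significant <- res$p_value < 0.05 & res$q_value <= 0.5
  write_summary_json(res, file.path(outdir, paste0("amplicon_tests_MBC_vs_",
                                                   control, ".json")))
  cat(sprintf("MBC vs %s: %d/%d amplicons significant (P < 0.05, q <= 0.5)\n",
              control, sum(res$significant), nrow(res)))
}
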