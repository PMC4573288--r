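# Synthetic methylome generator: determinism, marginal calibration,
# landscape shape, planted signal, truth round trips.

test_that("CpG placement is deterministic and respects the island density ratio", {
  gen <- simulate_genome(chrom_length = 2e6, n_islands = 200, seed = 3L)
  a <- place_cpgs(gen$genome, seed = 7L)
  b <- place_cpgs(gen$genome, seed = 7L)
  expect_identical(a, b)
  c2 <- place_cpgs(gen$genome, seed = 8L)
  expect_false(identical(a$pos, c2$pos))

  isl <- gen$genome$islands
  expect_gte(nrow(isl), 100)
  island_bp <- sum(isl$end - isl$start + 1)
  bg_bp <- sum(gen$genome$chromosomes$length) - island_bp
  dens_isl <- sum(!is.na(a$island)) / island_bp
  dens_bg <- sum(is.na(a$island)) / bg_bp
  expect_equal(dens_isl / dens_bg, 4, tolerance = 0.1)
})

test_that("degenerate genome models are rejected", {
  expect_error(sim_genome_model(data.frame(name = "c", length = 0),
                                islands = data.frame(chrom = character(0),
                                                     start = integer(0),
                                                     end = integer(0))),
               "positive")
  g <- sim_genome_model(data.frame(name = "c", length = 50),
                        islands = data.frame(chrom = character(0),
                                             start = integer(0),
                                             end = integer(0)),
                        cpg_spacing_mean = 125)
  expect_error(place_cpgs(g, seed = 1), "shorter")
  expect_error(sim_genome_model(data.frame(name = "c", length = 1000),
                                islands = data.frame(chrom = "c",
                                                     start = c(10, 50),
                                                     end = c(60, 90))),
               "non-overlapping")
})

test_that("pool simulation is a pure function of (model, params, seed)", {
  gen <- simulate_genome(chrom_length = 2e5, n_islands = 20, n_genes = 10,
                         seed = 5L)
  cpgs <- place_cpgs(gen$genome, seed = 5L)
  prm <- sim_pool_params("H", depth_mean = 10)
  p1 <- simulate_pool(cpgs, gen$genome, prm, seed = 11L)
  p2 <- simulate_pool(cpgs, gen$genome, prm, seed = 11L)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- simulate_pool(cpgs, gen$genome, prm, seed = 12L)
  expect_false(identical(p1$meth, p3$meth))
  # both strands of each dyad are present
  expect_equal(sum(p1$strand == "+"), sum(p1$strand == "-"))
  expect_equal(nrow(p1), 2L * nrow(cpgs))
})

test_that("mean coverage matches depth_mean within 5% at 1e5 strand loci", {
  gen <- simulate_genome(chrom_length = 2e6, n_islands = 100,
                         cpg_spacing_mean = 40, seed = 2L)
  cpgs <- place_cpgs(gen$genome, seed = 2L)
  expect_gte(2L * nrow(cpgs), 1e5)
  prm <- sim_pool_params("H", depth_mean = 9.6)
  pool <- simulate_pool(cpgs, gen$genome, prm, seed = 21L)
  expect_equal(mean(coverage_of(pool)), 9.6, tolerance = 0.05)
})

test_that("unshifted landscape is bimodal: modal bin above 80%, island mass below 20%", {
  study <- tiny_study(seed = 19L, genome_args = list(chrom_length = 1e6,
                                                     n_islands = 100,
                                                     n_genes = 50))
  pool <- suppressMessages(destrand_merge(study$pools$H))
  pct <- percent_methylation(pool)
  pct <- pct[coverage_of(pool) >= 10]
  h <- methylation_histogram(pct, n_bins = 10)
  expect_gt(h$bin_low[which.max(h$count)], 80 - 1e-9)
  low_mass <- sum(h$count[h$bin_high <= 20]) / sum(h$count)
  expect_gt(low_mass, 0.05)
  expect_lt(low_mass, 0.5)
})

test_that("increasing the global shift strictly decreases background methylation", {
  gen <- simulate_genome(chrom_length = 2e6, n_islands = 100,
                         cpg_spacing_mean = 40, seed = 2L)
  cpgs <- place_cpgs(gen$genome, seed = 2L)
  means <- vapply(c(0, 0.1, 0.2, 0.3), function(sh) {
    prm <- sim_pool_params("S", depth_mean = 10, global_hypo_shift = sh)
    pool <- simulate_pool(cpgs, gen$genome, prm, seed = 33L)
    dyad <- ifelse(pool$strand == "-", pool$pos - 1L, pool$pos)
    bg <- is.na(cpgs$island[match(dyad, cpgs$pos)])  # single chromosome
    pct <- percent_methylation(pool)
    mean(pct[bg & coverage_of(pool) > 0])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("null pools from identical parameters correlate strongly", {
  gen <- simulate_genome(chrom_length = 2e6, n_islands = 200, seed = 4L)
  cpgs <- place_cpgs(gen$genome, seed = 4L)
  expect_gte(nrow(cpgs), 1e4)
  prm <- sim_pool_params("A", depth_mean = 10)
  prm2 <- sim_pool_params("B", depth_mean = 10)
  pa <- suppressMessages(destrand_merge(simulate_pool(cpgs, gen$genome, prm,
                                                      seed = 101L)))
  pb <- suppressMessages(destrand_merge(simulate_pool(cpgs, gen$genome, prm2,
                                                      seed = 102L)))
  prof <- suppressMessages(build_profiles(list(A = pa, B = pb),
                                          min_coverage = 10))
  r <- pairwise_pearson(prof)
  expect_gt(r["A", "B"], 0.9)
})

test_that("planted islands separate affected from unaffected pools by > 50 points", {
  study <- tiny_study(seed = 23L, planted_hyper_level = 0.9)
  planted <- study$truth$planted_hotspot_islands
  in_planted <- function(pool) {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(pool$chrom, IRanges::IRanges(pool$pos, pool$pos)),
      GenomicRanges::GRanges(planted$chrom,
                             IRanges::IRanges(planted$start, planted$end)))
    sel <- rep(FALSE, nrow(pool))
    sel[S4Vectors::queryHits(hits)] <- TRUE
    sel & coverage_of(pool) > 0
  }
  mbc <- study$pools$MBC; h <- study$pools$H
  mean_mbc <- mean(percent_methylation(mbc)[in_planted(mbc)])
  mean_h <- mean(percent_methylation(h)[in_planted(h)])
  expect_gt(mean_mbc - mean_h, 50)
})

test_that("a vanishing depth yields a covered-locus desert and zero DML", {
  gen <- simulate_genome(chrom_length = 2e5, n_islands = 20, n_genes = 10,
                         seed = 6L)
  cpgs <- place_cpgs(gen$genome, seed = 6L)
  prm_a <- sim_pool_params("A", depth_mean = 1e-4)
  prm_b <- sim_pool_params("B", depth_mean = 1e-4)
  pa <- simulate_pool(cpgs, gen$genome, prm_a, seed = 1L)
  pb <- simulate_pool(cpgs, gen$genome, prm_b, seed = 2L)
  expect_gt(mean(coverage_of(pa) == 0), 0.99)
  rec <- quiet_dml(pa, pb)
  expect_equal(nrow(rec), 0L)
})

test_that("simulation truth round-trips through JSON with an integer seed", {
  study <- tiny_study(seed = 9L)
  path <- withr::local_tempfile()
  write_truth(study$truth, path)
  back <- read_truth(path)
  expect_equal(back$planted_hotspot_islands,
               study$truth$planted_hotspot_islands)
  expect_identical(back$seed, 9L)
  expect_true(is.integer(back$seed))
  expect_equal(back$planted_hyper_level, study$truth$planted_hyper_level)
  expect_equal(back$pool_params$MBC$global_hypo_shift,
               study$truth$pool_params$MBC$global_hypo_shift)
  # empty planted set serializes to an empty list and back
  t0 <- simulation_truth(data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), name = character(0)),
                         0.9, "MBC", seed = 3L)
  write_truth(t0, path)
  expect_equal(nrow(read_truth(path)$planted_hotspot_islands), 0L)
})

test_that("planting an island absent from the genome is an error", {
  gen <- simulate_genome(chrom_length = 2e5, n_islands = 20, n_genes = 10,
                         seed = 5L)
  cpgs <- place_cpgs(gen$genome, seed = 5L)
  truth <- simulation_truth(data.frame(chrom = "chr1", start = 10L,
                                       end = 20L, name = "NOT_A_CGI"),
                            0.9, "MBC", seed = 1L)
  prm <- sim_pool_params("MBC", depth_mean = 10)
  expect_error(simulate_pool(cpgs, gen$genome, prm, truth = truth, seed = 1L),
               "absent from the genome")
})
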