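# Cross-platform concordance: pairing over targets, correlation identities,
# per-amplicon tests.

targets2 <- function() {
  data.frame(chrom = "chr1", start = c(100L, 500L), end = c(199L, 599L),
             name = c("amp1", "amp2"))
}

test_that("pairing keeps target loci covered on both platforms and reports drops", {
  p1 <- make_pool("chr1", c(110L, 120L, 510L, 900L), "+",
                  c(5L, 3L, 8L, 2L), c(5L, 7L, 2L, 2L), label = "H",
                  destranded = TRUE)
  p2 <- make_pool("chr1", c(110L, 510L, 520L), "+", c(50L, 80L, 10L),
                  c(50L, 20L, 90L), label = "H", destranded = TRUE)
  pairs <- pair_platforms(p1, p2, targets2())
  expect_equal(pairs$pos, c(110L, 510L))
  expect_equal(pairs$amplicon, c("amp1", "amp2"))
  expect_equal(pairs$pct_p1, c(50, 80))
  expect_equal(pairs$pct_p2, c(50, 80))
  drops <- attr(pairs, "drop_report")
  expect_setequal(drops$pos[drops$platform == "p1_only"], 120L)
  expect_setequal(drops$pos[drops$platform == "p2_only"], 520L)
  # 900 is outside every target: not paired, not in the drop report
  expect_false(900L %in% c(pairs$pos, drops$pos))
  far <- make_pool("chr1", 900L, "+", 1L, 1L, destranded = TRUE)
  expect_error(pair_platforms(far, far, targets2()), "no loci inside")
})

test_that("concordance identities: r = 1 on identical, r = -1 mirrored, R^2 = r^2", {
  p1 <- make_pool("chr1", c(110L, 120L, 130L), "+", c(1L, 5L, 9L),
                  c(9L, 5L, 1L), destranded = TRUE)
  pairs <- pair_platforms(p1, p1, targets2())
  st <- concordance_stats(pairs)
  expect_equal(st$pearson_r, 1)
  expect_equal(st$r_squared, 1)
  mirrored <- make_pool("chr1", c(110L, 120L, 130L), "+", c(9L, 5L, 1L),
                        c(1L, 5L, 9L), destranded = TRUE)
  st2 <- concordance_stats(pair_platforms(p1, mirrored, targets2()))
  expect_equal(st2$pearson_r, -1)
  expect_equal(st2$r_squared, 1)
})

test_that("pooled Pearson matches the hand-computed three-pair value", {
  p1 <- make_pool("chr1", c(110L, 120L, 130L), "+", c(0L, 5L, 10L),
                  c(10L, 5L, 0L), destranded = TRUE)
  p2 <- make_pool("chr1", c(110L, 120L, 130L), "+", c(1L, 4L, 9L),
                  c(9L, 6L, 1L), destranded = TRUE)
  st <- concordance_stats(pair_platforms(p1, p2, targets2()))
  # pairs (0,10), (50,40), (100,90): r = 0.9897433, R^2 = 0.9795918
  expect_equal(st$pearson_r, 0.9897433, tolerance = 1e-6)
  expect_equal(st$r_squared, 0.9795918, tolerance = 1e-6)
  expect_equal(st$n_loci, 3L)
})

test_that("R^2 equals r^2 on random paired measurements", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 30L
    pos <- 100L + seq_len(n)
    t <- data.frame(chrom = "chr1", start = 100L, end = 200L, name = "amp")
    m1 <- rbinom(n, 50, 0.5); m2 <- rbinom(n, 50, 0.5)
    p1 <- make_pool("chr1", pos, "+", m1, 50L - m1, destranded = TRUE)
    p2 <- make_pool("chr1", pos, "+", m2, 50L - m2, destranded = TRUE)
    st <- concordance_stats(pair_platforms(p1, p2, t))
    expect_equal(st$r_squared, st$pearson_r^2, tolerance = 1e-12)
  }
})

test_that("deep platform replicates over hotspot amplicons agree strongly", {
  # mirrors the validation design: amplicons on a handful of hotspot islands,
  # re-measured deeply in every pool on a second platform, pairs pooled
  study <- tiny_study(seed = 37L)
  amp <- study$truth$planted_hotspot_islands
  pairs <- do.call(rbind, lapply(names(study$pools), function(lab) {
    wgbs <- study$pools[[lab]]
    deep <- sim_pool_params(paste0(lab, "_deep"),
                            depth_mean = 250 * 17)
    miseq <- simulate_platform_replicate(wgbs, deep, target_regions = amp,
                                         seed = 91L + match(lab,
                                                            names(study$pools)))
    pair_platforms(suppressMessages(destrand_merge(wgbs)),
                   suppressMessages(destrand_merge(miseq)), amp)
  }))
  st <- concordance_stats(pairs)
  expect_gt(st$pearson_r, 0.9)
  expect_equal(st$r_squared, st$pearson_r^2)
  expect_gt(st$depth$mean_cov_p2, 50 * st$depth$mean_cov_p1)
})

test_that("per-amplicon aggregation and exact tests behave on extreme and null tables", {
  agg_case <- data.frame(amplicon = c("a", "b", "c", "d"),
                         meth = c(90L, 10L, 50L, 30L),
                         unmeth = c(10L, 90L, 50L, 70L))
  agg_ctrl <- data.frame(amplicon = c("a", "b", "c", "d"),
                         meth = c(5L, 10L, 50L, 2L),
                         unmeth = c(95L, 90L, 50L, 98L))
  res <- per_group_test(agg_case, agg_ctrl)
  expect_lt(res$p_value[res$amplicon == "a"], 1e-15)
  expect_equal(res$p_value[res$amplicon == "b"], 1)
  expect_equal(res$p_value[res$amplicon == "c"], 1)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  # equal p-values share the same BH q
  eq <- per_group_test(
    data.frame(amplicon = letters[1:4], meth = 9L, unmeth = 1L),
    data.frame(amplicon = letters[1:4], meth = 1L, unmeth = 9L))
  expect_equal(length(unique(eq$p_value)), 1L)
  expect_equal(eq$q_value, eq$p_value)
})

test_that("amplicon aggregation sums counts inside each target", {
  pool <- make_pool("chr1", c(110L, 120L, 510L), "+", c(3L, 4L, 7L),
                    c(1L, 2L, 3L), destranded = TRUE)
  agg <- aggregate_amplicon_counts(pool, targets2())
  expect_equal(agg$meth, c(7L, 7L))
  expect_equal(agg$unmeth, c(3L, 3L))
})
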