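# Differential methylation core: destranding, uniting, exact test, DMV,
# q-values, DML calling.

test_that("destranding adds minus-strand counts onto the dyad position", {
  pool <- make_pool("chr1", c(100L, 101L, 300L), c("+", "-", "+"),
                    c(3L, 2L, 5L), c(1L, 2L, 0L))
  out <- suppressMessages(destrand_merge(pool))
  expect_equal(out$pos, c(100L, 300L))
  expect_equal(out$meth, c(5L, 5L))
  expect_equal(out$unmeth, c(3L, 0L))
  expect_true(all(out$strand == "+"))
  expect_true(attr(out, "destranded"))
  # determinism and idempotence
  expect_identical(as.data.frame(suppressMessages(destrand_merge(pool))),
                   as.data.frame(out))
  expect_identical(destrand_merge(out), out)
})

test_that("orphan minus-strand loci are kept at their dyad position and reported", {
  pool <- make_pool("chr1", c(51L, 100L), c("-", "+"), c(4L, 1L), c(0L, 1L))
  expect_message(out <- destrand_merge(pool), "1 minus-strand")
  expect_equal(out$pos, c(50L, 100L))
  expect_equal(out$meth, c(4L, 1L))
  expect_equal(attr(out, "n_orphan_minus"), 1L)
})

test_that("uniting keeps only loci at the coverage floor in both groups", {
  a <- make_pool("chr1", c(10L, 20L, 30L), "+", c(3L, 3L, 9L), c(2L, 2L, 1L),
                 label = "A", destranded = TRUE)
  b <- make_pool("chr1", c(10L, 20L), "+", c(2L, 2L), c(3L, 2L),
                 label = "B", destranded = TRUE)
  u <- suppressMessages(unite_pools(a, b, min_coverage = 5))
  # 10: 5/5 kept; 20: 5/4 dropped; 30: only in A, dropped
  expect_equal(u$pos, 10L)
  expect_equal(u$meth_a, 3L)
  expect_equal(u$meth_b, 2L)
  zero <- make_pool("chr1", 10L, "+", 0L, 0L, destranded = TRUE)
  expect_warning(u0 <- suppressMessages(unite_pools(zero, zero)), "empty")
  expect_equal(nrow(u0), 0L)
})

test_that("the exact test reproduces enumerated two-sided p-values", {
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(3, 3, 3, 3), 1)
  expect_equal(fisher_exact_2x2(10, 0, 10, 0), 1)
  expect_equal(fisher_exact_2x2(9, 1, 1, 9), 202 / 184756, tolerance = 1e-12)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "positive")
})

test_that("the exact test agrees with the enumeration oracle and fisher.test", {
  # exhaustive over small tables (the full <= 40 sweep runs in acceptance)
  for (tot in 2:12) {
    for (ra in 1:(tot - 1)) {
      rb <- tot - ra
      for (ma in 0:ra) for (mb in 0:rb) {
        p <- fisher_exact_2x2(ma, ra - ma, mb, rb - mb)
        expect_equal(p, fisher_oracle(ma, ra - ma, mb, rb - mb),
                     tolerance = 1e-12)
      }
    }
  }
  set.seed(8)
  ma <- rbinom(25, 40, 0.5); ua <- rbinom(25, 40, 0.5) + 1L
  mb <- rbinom(25, 25, 0.2); ub <- rbinom(25, 25, 0.8) + 1L
  p <- fisher_exact_2x2(ma, ua, mb, ub)
  pref <- vapply(seq_along(ma), function(i) {
    stats::fisher.test(matrix(c(ma[i], ua[i], mb[i], ub[i]), 2L,
                              byrow = TRUE))$p.value
  }, numeric(1))
  expect_equal(p, pref, tolerance = 1e-9)
})

test_that("swapping groups preserves p-values and negates DMVs", {
  set.seed(3)
  ma <- rbinom(50, 30, 0.7); ua <- 30 - ma + 1L
  mb <- rbinom(50, 30, 0.4); ub <- 30 - mb + 1L
  expect_equal(fisher_exact_2x2(ma, ua, mb, ub),
               fisher_exact_2x2(mb, ub, ma, ua), tolerance = 1e-12)
  expect_equal(compute_dmv(ma, ua, mb, ub), -compute_dmv(mb, ub, ma, ua))
})

test_that("DMV is the difference of group percent methylation", {
  expect_equal(compute_dmv(8, 2, 3, 7), 50)
  expect_equal(compute_dmv(4, 6, 2, 3), 0)
  expect_equal(compute_dmv(10, 0, 0, 10), 100)
  expect_error(compute_dmv(0, 0, 1, 1), "positive coverage")
})

test_that("BH q-values follow the step-up formula and dominate p elementwise", {
  expect_equal(bh_qvalues(0.04), 0.04)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  expect_identical(bh_qvalues(numeric(0)), numeric(0))
  set.seed(2)
  p <- runif(200)
  q <- bh_qvalues(p)
  expect_true(all(q >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_error(bh_qvalues(c(0.5, 0)), "0, 1")
})

test_that("call_dml applies the P, DMV and chromosome filters jointly", {
  a <- make_pool(c("chr1", "chr1", "chrX"), c(10L, 20L, 30L), "+",
                 c(9L, 6L, 10L), c(1L, 4L, 0L), label = "case",
                 destranded = TRUE)
  b <- make_pool(c("chr1", "chr1", "chrX"), c(10L, 20L, 30L), "+",
                 c(1L, 5L, 0L), c(9L, 5L, 10L), label = "ctrl",
                 destranded = TRUE)
  rec <- quiet_dml(a, b)
  # chr1:10 (90% vs 10%, p = 202/184756, dmv 80) called hyper;
  # chr1:20 has dmv 10 < 20 regardless of p; chrX excluded up front.
  expect_equal(rec$pos, 10L)
  expect_equal(rec$dmv, 80)
  expect_equal(rec$p_value, 202 / 184756, tolerance = 1e-12)
  expect_equal(rec$direction, "hyper")
  expect_equal(attr(rec, "n_united"), 2L)
  # direction flips with the group order
  rec2 <- quiet_dml(b, a)
  expect_equal(rec2$dmv, -80)
  expect_equal(rec2$direction, "hypo")
  expect_equal(rec2$p_value, rec$p_value)
})

test_that("the DMV threshold is inclusive at the boundary and sharp one ULP above", {
  # 40% vs 20% at coverage 60: dmv exactly 20, p ~ 0.028
  a <- make_pool("chr1", 10L, "+", 24L, 36L, label = "A", destranded = TRUE)
  b <- make_pool("chr1", 10L, "+", 12L, 48L, label = "B", destranded = TRUE)
  at <- quiet_dml(a, b, diffmeth_params(dmv_threshold = 20))
  expect_equal(nrow(at), 1L)
  expect_equal(at$dmv, 20)
  above <- quiet_dml(a, b, diffmeth_params(
    dmv_threshold = 20 * (1 + .Machine$double.eps)))
  expect_equal(nrow(above), 0L)
})

test_that("the optional q-value bound is honoured", {
  set.seed(40)
  n <- 60
  a <- make_pool("chr1", seq_len(n) * 10L, "+", rbinom(n, 20, 0.55),
                 rbinom(n, 20, 0.45) + 1L, label = "A", destranded = TRUE)
  b <- make_pool("chr1", seq_len(n) * 10L, "+", rbinom(n, 20, 0.45),
                 rbinom(n, 20, 0.55) + 1L, label = "B", destranded = TRUE)
  loose <- quiet_dml(a, b, diffmeth_params(q_threshold = NA))
  strict <- quiet_dml(a, b, diffmeth_params(q_threshold = 0.01))
  expect_lte(nrow(strict), nrow(loose))
  if (nrow(strict)) expect_true(all(strict$q_value <= 0.01))
})

test_that("destranding inside call_dml matches destranding outside", {
  study <- tiny_study(seed = 31L)
  inside <- quiet_dml(study$pools$MBC, study$pools$H)
  pre_a <- suppressMessages(destrand_merge(study$pools$MBC))
  pre_b <- suppressMessages(destrand_merge(study$pools$H))
  outside <- quiet_dml(pre_a, pre_b)
  expect_equal(as.data.frame(inside), as.data.frame(outside))
})
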