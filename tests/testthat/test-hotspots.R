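# Island hotspot calling and recovery scoring.

island_track <- function(n = 3L, width = 200L, gap = 800L) {
  start <- 1L + (seq_len(n) - 1L) * (width + gap)
  annotation_track("CPGI", data.frame(chrom = "chr1", start = start,
                                      end = start + width - 1L,
                                      name = sprintf("CGI%02d", seq_len(n))))
}

hotspot_records <- function(pos, dmv) {
  structure(data.frame(chrom = "chr1", pos = as.integer(pos), strand = "+",
                       dmv = dmv,
                       direction = ifelse(dmv > 0, "hyper", "hypo"),
                       stringsAsFactors = FALSE),
            class = c("dml_records", "data.frame"))
}

test_that("an island needs at least min_dml hyper loci at min_dmv, inclusive", {
  isl <- island_track()
  # island 1: exactly 8 hyper loci at dmv exactly 50 -> called
  # island 2: 7 qualifying -> not called
  # island 3: 7 hyper + 1 hypo of large |dmv| -> not called
  rec <- rbind(hotspot_records(seq(10, 80, by = 10), rep(50, 8)),
               hotspot_records(seq(1010, 1070, by = 10), rep(80, 7)),
               hotspot_records(seq(2010, 2080, by = 10),
                               c(rep(60, 7), -60)))
  calls <- call_hotspots(rec, isl, hotspot_params())
  expect_equal(calls$name, "CGI01")
  expect_equal(calls$n_qualifying, 8L)
  expect_equal(calls$mean_dmv, 50)
  expect_equal(calls$span_start, 10L)
  expect_equal(calls$span_end, 80L)
  # one ULP below the DMV floor disqualifies
  below <- call_hotspots(hotspot_records(seq(10, 80, by = 10),
                                         rep(50 * (1 - .Machine$double.eps),
                                             8)),
                         isl, hotspot_params())
  expect_equal(nrow(below), 0L)
  # supporting loci are the input records, unchanged
  sup <- attr(calls, "supporting")[["CGI01"]]
  expect_equal(sup$pos, seq(10L, 80L, by = 10L))
  expect_true(all(sup$dmv >= 50))
})

test_that("require_hyper = FALSE admits strong hypomethylated loci", {
  isl <- island_track(1L)
  rec <- hotspot_records(seq(10, 80, by = 10), rep(-70, 8))
  expect_equal(nrow(call_hotspots(rec, isl, hotspot_params())), 0L)
  calls <- call_hotspots(rec, isl,
                         hotspot_params(require_hyper = FALSE, min_dmv = 50))
  expect_equal(nrow(calls), 0L)  # dmv is signed; -70 < 50
  calls2 <- call_hotspots(hotspot_records(seq(10, 80, by = 10), rep(70, 8)),
                          isl, hotspot_params(require_hyper = FALSE))
  expect_equal(nrow(calls2), 1L)
})

test_that("an empty island track is an error", {
  rec <- hotspot_records(10, 60)
  empty <- annotation_track("CPGI", data.frame(chrom = character(0),
                                               start = integer(0),
                                               end = integer(0)))
  expect_error(call_hotspots(rec, empty), "empty island track")
})

test_that("calls are monotone in min_dml and min_dmv and match a quadratic scan", {
  set.seed(77)
  for (rep in 1:5) {
    isl <- island_track(n = 12L, width = 300L, gap = 500L)
    n <- 400
    rec <- hotspot_records(sample.int(12L * 800L, n),
                           round(runif(n, -100, 100), 1))
    for (prm in list(hotspot_params(), hotspot_params(min_dml = 3,
                                                      min_dmv = 30))) {
      calls <- call_hotspots(rec, isl, prm)
      expect_identical(sort(calls$name), hotspot_oracle(rec, isl, prm))
      # raising min_dml never adds islands
      stricter <- call_hotspots(rec, isl,
                                hotspot_params(min_dml = prm$min_dml + 2,
                                               min_dmv = prm$min_dmv))
      expect_true(all(stricter$name %in% calls$name))
      # raising min_dmv never increases n_qualifying per island
      higher <- call_hotspots(rec, isl,
                              hotspot_params(min_dml = 1,
                                             min_dmv = prm$min_dmv + 10))
      base <- call_hotspots(rec, isl, hotspot_params(min_dml = 1,
                                                     min_dmv = prm$min_dmv))
      shared <- intersect(higher$name, base$name)
      expect_true(all(higher$n_qualifying[match(shared, higher$name)] <=
                        base$n_qualifying[match(shared, base$name)]))
    }
  }
})

test_that("recovery scoring matches calls against planted island identities", {
  truth <- simulation_truth(data.frame(chrom = "chr1",
                                       start = c(1L, 1001L),
                                       end = c(200L, 1200L),
                                       name = c("CGI01", "CGI02")),
                            0.9, "MBC", seed = 1L)
  isl <- island_track(3L)
  rec <- rbind(hotspot_records(seq(10, 80, by = 10), rep(60, 8)),
               hotspot_records(seq(2010, 2080, by = 10), rep(60, 8)))
  calls <- call_hotspots(rec, isl, hotspot_params())
  sc <- score_recovery(calls, truth)
  expect_equal(sc$n_planted, 2L)
  expect_equal(sc$n_recovered, 1L)
  expect_equal(sc$sensitivity, 0.5)
  expect_equal(sc$n_false_positive, 1L)
  expect_equal(sc$false_positive, "CGI03")
  empty_calls <- call_hotspots(hotspot_records(10, 60), isl,
                               hotspot_params())
  expect_equal(score_recovery(empty_calls, truth)$sensitivity, 0)
})
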