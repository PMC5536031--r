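test_that("confusion counts follow the four definitions and always sum to n", {
  expect_equal(unclass(confusion(rep(c(1, 0), each = 5), rep(c(1, 0), each = 5))),
               list(tp = 5L, fp = 0L, tn = 5L, fn = 0L),
               ignore_attr = TRUE)
  truth <- c(rep(1L, 54), rep(0L, 2895))
  cc <- confusion(truth, rep(1L, 2949))
  expect_equal(with(cc, c(tp, fp, tn, fn)), c(54, 2895, 0, 0))
  empty <- confusion(integer(0), integer(0))
  expect_equal(with(empty, tp + fp + tn + fn), 0)
  expect_error(confusion(c(0, 1), c(1)), class = "hotspotRP_dim_error")
  # random counts always partition n
  set.seed(2)
  for (r in 1:20) {
    t <- rbinom(100, 1, 0.3); p <- rbinom(100, 1, 0.5)
    cc <- confusion(t, p)
    expect_equal(with(cc, tp + fp + tn + fn), 100)
  }
})

test_that("metrics implement the four formulas with explicit undefined handling", {
  perfect <- metrics(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(c(perfect$sen, perfect$prec, perfect$f1, perfect$mcc),
               rep(1, 4))

  m <- metrics(list(tp = 29, fp = 103, tn = 2794, fn = 23))
  expect_equal(m$sen, 29 / 52)
  expect_equal(m$prec, 29 / 132)
  expect_equal(m$mcc, oracle_mcc(29, 103, 2794, 23), tolerance = 1e-12)

  # undefined markers: no predicted positives -> precision NA, F1 NA
  none <- metrics(confusion(c(1, 0, 0), c(0, 0, 0)))
  expect_true(is.na(none$prec))
  expect_true(is.na(none$f1))
  expect_equal(none$sen, 0)
  # MCC with zero denominator is 0 by convention
  expect_equal(metrics(list(tp = 0, fp = 0, tn = 5, fn = 0))$mcc, 0)
})

test_that("F1 equals the harmonic mean of precision and sensitivity", {
  # identity over random counts
  set.seed(3)
  for (r in 1:50) {
    cc <- list(tp = rpois(1, 20) + 1, fp = rpois(1, 30), tn = rpois(1, 50),
               fn = rpois(1, 10))
    m <- metrics(cc)
    expect_equal(m$f1, 2 * m$prec * m$sen / (m$prec + m$sen),
                 tolerance = 1e-12)
  }
  expect_true(is.na(f1_score(0, 0)))
  expect_true(is.na(f1_score(NA, 0.5)))
})

test_that("benchmark-table F1 values are consistent with their sensitivity/precision pairs", {
  # headline transfer result: Sen 0.846, Prec 0.440 -> F1 0.579
  expect_equal(round(f1_score(0.846, 0.440), 3), 0.579)
  # same row from integer counts (44/52 hits, 100 predicted positives)
  m <- metrics(list(tp = 44, fp = 56, tn = 2839, fn = 8))
  expect_equal(round(m$sen, 3), 0.846)
  expect_equal(round(m$prec, 3), 0.440)
  expect_equal(round(m$f1, 3), 0.579)
  # top-3 ensemble on the reverse transfer: 0.793/0.245 -> 0.374
  expect_equal(round(f1_score(0.793, 0.245), 3), 0.374)
  # top-5 ensemble: 1.000/0.226 -> 0.369
  expect_equal(round(f1_score(1.000, 0.226), 3), 0.369)
  # random predictor row: 0.983/0.018 -> 0.035
  expect_equal(round(f1_score(0.983, 0.018), 3), 0.035)
})

test_that("MCC is invariant under simultaneous class swap", {
  set.seed(11)
  for (r in 1:10) {
    t <- rbinom(200, 1, 0.2); p <- rbinom(200, 1, 0.4)
    m1 <- metrics(confusion(t, p))
    m2 <- metrics(confusion(1 - t, 1 - p))
    expect_equal(m1$mcc, m2$mcc, tolerance = 1e-12)
  }
})

test_that("a truth-independent random predictor has precision ~ prevalence and MCC ~ 0", {
  truth <- c(rep(1L, 54), rep(0L, 2895))
  avg <- random_predictor(truth, positive_rate = 0.983, n_runs = 1000,
                          seed = 7L)
  expect_equal(avg$prec, 54 / 2949, tolerance = 0.002 / (54 / 2949))
  expect_lt(abs(avg$mcc), 0.01)
  expect_equal(nrow(attr(avg, "per_run")), 1000L)

  # positive rate 1: sensitivity exactly 1 and precision exactly prevalence
  # in every run
  all_pos <- random_predictor(truth, 1, n_runs = 5, seed = 1L)
  runs <- attr(all_pos, "per_run")
  expect_true(all(runs$sen == 1))
  expect_true(all(runs$prec == 54 / 2949))
  expect_error(random_predictor(truth, 0), class = "hotspotRP_config_error")
})

test_that("sweeps emit one row per grid cell with seed-stable metrics", {
  fix <- worked_fixture()
  co <- generate_corpus(n_sequences = 6, length_range = c(40, 60),
                        prevalence = 0.08, effect_size = 3,
                        n_properties = 10, seed = 2)
  tab <- sweep_performance(co, co, co$properties, target_dims = c(1L, 2L, 5L),
                           window_lengths = 5L, n_repeats = 2L,
                           n_projections = 4L, top_n = 1L, master_seed = 3L)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("f1", "f1_sd") %in% names(tab)))
  expect_true(all(is.finite(tab$f1_sd)))
  tab2 <- sweep_performance(co, co, co$properties, target_dims = c(1L, 2L, 5L),
                            window_lengths = 5L, n_repeats = 2L,
                            n_projections = 4L, top_n = 1L, master_seed = 3L)
  expect_equal(tab, tab2)
  expect_error(sweep_performance(co, co, co$properties,
                                 target_dims = integer(0)),
               class = "hotspotRP_config_error")
})

test_that("ROC points move monotonically from strictest to loosest threshold", {
  set.seed(4)
  truth <- rbinom(100, 1, 0.3)
  score <- runif(100) + 0.5 * truth
  roc <- roc_points(truth, score)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$sen) >= 0))
  expect_equal(roc$sen[nrow(roc)], 1)
  expect_equal(roc$fpr[nrow(roc)], 1)
})
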