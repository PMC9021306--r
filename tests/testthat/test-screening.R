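# Two-stage screening: confidence score, round-dependent gate, trimmed
# spread score, and ROC threshold selection.

test_that("validation confidence weights zones A and B only", {
  expect_equal(validation_confidence(c(A = 12, B = 0, C = 0, D = 0, E = 0)),
               100)
  expect_equal(validation_confidence(c(A = 10, B = 10, C = 0, D = 0, E = 0)),
               75)
  expect_equal(validation_confidence(c(A = 0, B = 0, C = 3, D = 2, E = 1)),
               0)
  expect_true(is.na(validation_confidence(c(A = 0, B = 0, C = 0, D = 0,
                                            E = 0))))
})

test_that("confidence score improves when predictions move up-zone", {
  base <- c(A = 5, B = 5, C = 5, D = 0, E = 0)
  up_b <- c(A = 5, B = 6, C = 4, D = 0, E = 0)
  up_a <- c(A = 6, B = 4, C = 5, D = 0, E = 0)
  expect_gt(validation_confidence(up_b), validation_confidence(base))
  expect_gt(validation_confidence(up_a), validation_confidence(base))
  expect_true(validation_confidence(base) >= 0 &&
                validation_confidence(base) <= 100)
})

test_that("the stage-1 gate switches thresholds exactly at round 7", {
  expect_true(stage1_gate(55, 5))
  expect_false(stage1_gate(55, 8))
  expect_true(stage1_gate(55, 6))
  expect_false(stage1_gate(55, 7))    # round 7 already uses the 60 cutoff
  expect_true(stage1_gate(60, 7))
  expect_true(stage1_gate(50, 6))     # threshold is inclusive
  expect_false(stage1_gate(49.9, 6))
  for (r in c(4, 6, 7, 9, 15)) expect_true(stage1_gate(100, r))
  expect_false(stage1_gate(NA_real_, 5))   # fail safe on missing score
})

test_that("the spread score reproduces the worked example", {
  preds <- c(100, 110, 120, 130, 140)
  # trim 100 and 140; retained (110,120,130): mean 120, SS 200,
  # /(N-1)=50, sqrt ~ 7.0711, median 120
  expect_equal(test_spread(preds), sqrt(50) / 120, tolerance = 1e-12)
  expect_equal(test_spread(preds, divisor = "conventional"),
               10 / 120, tolerance = 1e-12)
})

test_that("spread score is zero iff constant and scale invariant", {
  expect_equal(test_spread(rep(123, 5)), 0)
  p <- c(95, 104, 100, 111, 120)
  expect_gt(test_spread(p), 0)
  expect_equal(test_spread(2 * p), test_spread(p), tolerance = 1e-12)
  expect_equal(test_spread(p * 0.37), test_spread(p), tolerance = 1e-12)
  expect_error(test_spread(c(100, 110, 120)), "at least 4")
  expect_error(test_spread(c(100, 110, -5, 120, 130)), "positive")
})

test_that("stage-2 filter accepts below threshold with the trimmed median", {
  preds <- c(100, 110, 120, 130, 140)
  ok <- stage2_filter(preds, y = 0.07)
  expect_true(ok$accepted)
  expect_equal(ok$prediction, 120)
  bad <- stage2_filter(preds, y = 0.05)
  expect_false(bad$accepted)
  expect_true(is.na(bad$prediction))
  const <- stage2_filter(rep(150, 5), y = 0.01)
  expect_true(const$accepted)
  expect_equal(const$prediction, 150)
})

test_that("ROC finds the corner for separable scores", {
  s_t <- c(0.01, 0.02, 0.03, 0.5, 0.6, 0.7)
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- roc_threshold(s_t, truth)
  best <- r$roc[r$roc$threshold == r$optimal_y, ]
  expect_equal(best$tpr, 1)
  expect_equal(best$fpr, 0)
  expect_equal(r$auc, 1)
  expect_gt(r$optimal_y, 0.03)
  expect_lte(r$optimal_y, 0.5)
  expect_error(roc_threshold(s_t, rep(TRUE, 6)), "both true and false")
})

test_that("ROC hugs the diagonal when labels are independent of scores", {
  set.seed(31)
  n <- 4000
  s_t <- runif(n, 0, 0.2)
  truth <- runif(n) < 0.5
  r <- roc_threshold(s_t, truth)
  expect_lt(abs(r$auc - 0.5), 0.05)
})

test_that("ROC detects a monotone score-label relationship", {
  set.seed(32)
  n <- 1000
  s_t <- runif(n, 0, 0.2)
  truth <- (s_t < 0.08) != (runif(n) < 0.03)   # low spread => true, 3% flips
  r <- roc_threshold(s_t, truth)
  expect_gt(r$auc, 0.9)
  expect_lt(abs(r$optimal_y - 0.08), 0.03)
  # independent oracle for the AUC computation
  if (requireNamespace("pROC", quietly = TRUE)) {
    auc_ref <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = -s_t, quiet = TRUE,
      direction = "<")))
    expect_equal(r$auc, auc_ref, tolerance = 1e-8)
  }
})

test_that("screening configuration enforces its invariants", {
  expect_error(screening_config(n_repeats = 3), "n_repeats")
  expect_error(screening_config(st_threshold = 0))
  cfg <- screening_config()
  expect_equal(cfg$st_threshold, 0.07)
  expect_equal(cfg$n_repeats, 5L)
  expect_equal(unname(cfg$zone_weights[c("A", "B")]), c(1, 0.5))
})
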