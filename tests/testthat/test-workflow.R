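# Orchestration: cross-validation folds, repeated final training, test
# pairing with the last training round, and the end-to-end pipeline.

wf_subject <- function() {
  fixture("wf_subject", generate_subject(sim_config(
    n_rounds = 6, duration = 30, heart_rate = 72,
    coupling_coefficient = 0.3, noise_sd = 0, drift_sd = 0, seed = 21),
    subject_id = "WF"))
}

wf_vectors <- function() fixture("wf_vectors", subject_vectors(wf_subject()))

wf_model <- function(channels) {
  model_config(channels = channels, scale = 128, epochs = 4,
               batch_size = 128, learning_rate = 5e-3, seed = 3)
}

test_that("experiment plans validate the data split", {
  ds <- wf_subject()
  expect_error(experiment_plan(ds, "DL", training_rounds = 4,
                               test_rounds = 3), "after the last")
  expect_error(experiment_plan(ds, "DL", training_rounds = c(2, 3),
                               test_rounds = 5), "contiguous")
  expect_error(experiment_plan(ds, "DL", training_rounds = 4,
                               test_rounds = 9), "exceeds")
  plan <- experiment_plan(ds, "IL", training_rounds = 4, test_rounds = 5,
                          model = wf_model(1))
  expect_equal(plan$training_rounds, 1:4)
  expect_error(experiment_plan(ds, "DL", training_rounds = 4,
                               test_rounds = 5, model = wf_model(1)),
               "2-channel")
})

test_that("cross-validation folds cover the right target rounds", {
  ds <- wf_subject()
  v <- wf_vectors()
  dl_plan <- experiment_plan(ds, "DL+S", training_rounds = 4,
                             test_rounds = 5, model = wf_model(2),
                             seed = 21)
  cv <- loo_cross_validate(dl_plan, v)
  # paired folds: rounds 2..4 (round 1 has no predecessor), 2 replicates
  expect_equal(sort(unique(cv$predictions$round)), 2:4)
  expect_equal(nrow(cv$predictions), 6)
  expect_equal(sum(cv$zone_counts), nrow(cv$predictions))
  expect_true(is.na(cv$s_v) || (cv$s_v >= 0 && cv$s_v <= 100))

  il_plan <- experiment_plan(ds, "IL", training_rounds = 4,
                             test_rounds = 5, model = wf_model(1),
                             seed = 21)
  cv_il <- loo_cross_validate(il_plan, v)
  expect_equal(sort(unique(cv_il$predictions$round)), 1:4)
  expect_equal(nrow(cv_il$predictions), 8)
})

test_that("final training repeats exactly for the screened method", {
  ds <- wf_subject()
  v <- wf_vectors()
  scr <- screening_config(n_repeats = 4)
  plan <- experiment_plan(ds, "DL+S", training_rounds = 4, test_rounds = 5,
                          model = wf_model(2), screening = scr, seed = 5)
  models <- train_final(plan, v)
  expect_length(models, 4)
  seeds <- vapply(models, function(m) m$config$seed, integer(1))
  expect_length(unique(seeds), 4)
  il_models <- train_final(
    experiment_plan(ds, "IL", training_rounds = 4, test_rounds = 5,
                    model = wf_model(1), seed = 5), v)
  expect_length(il_models, 1)
  # same plan trains to identical weights
  models2 <- train_final(plan, v)
  expect_identical(
    lapply(models, function(m) m$history$train_loss),
    lapply(models2, function(m) m$history$train_loss))
})

test_that("test prediction pairs with the last training round", {
  ds <- wf_subject()
  v <- wf_vectors()
  plan <- experiment_plan(ds, "DL", training_rounds = 4, test_rounds = 5:6,
                          model = wf_model(2), seed = 9)
  models <- train_final(plan, v)
  preds <- predict_test(plan, models, v)
  expect_equal(nrow(preds), 4)            # 2 rounds x 2 replicates
  expect_true(all(preds$accepted))
  expect_true(all(is.finite(preds$predicted_bgl)))
  expect_true(all(is.na(preds$s_t)))
  # invariant to the order test rounds are processed
  plan_rev <- plan
  plan_rev$test_rounds <- rev(plan$test_rounds)
  preds_rev <- predict_test(plan_rev, models, v)
  key <- function(d) d[order(d$round, d$replicate),
                       c("round", "replicate", "predicted_bgl")]
  expect_equal(key(preds_rev), key(preds), ignore_attr = TRUE)
})

test_that("stage-1 rejection short-circuits the pipeline", {
  ds <- wf_subject()
  plan <- experiment_plan(
    ds, "DL+S", training_rounds = 4, test_rounds = 5,
    model = wf_model(2),
    screening = screening_config(sv_threshold_early = 1000,
                                 sv_threshold_late = 1000), seed = 2)
  res <- run_experiment(plan)
  expect_false(res$stage1_pass)
  expect_null(res$predictions)
  expect_null(res$metrics)
})

test_that("a strongly coupled noise-free subject passes end to end", {
  ds <- wf_subject()
  mc <- model_config(channels = 2, scale = 64, epochs = 15,
                     batch_size = 256, learning_rate = 5e-3, seed = 21)
  plan <- experiment_plan(ds, "DL+S", training_rounds = 4,
                          test_rounds = 5:6, model = mc, seed = 21)
  res <- run_experiment(plan)
  expect_true(res$stage1_pass)
  expect_s3_class(res$predictions, "data.frame")
  acc <- res$predictions[res$predictions$accepted, ]
  expect_equal(res$metrics$n, nrow(acc))
  expect_gt(nrow(acc), 0)
  # accepted predictions of a clean, strongly coupled subject are clinical
  expect_true(all(acc$zone %in% c("A", "B")))
  # determinism of the full pipeline
  res2 <- run_experiment(plan)
  expect_equal(res$predictions$predicted_bgl,
               res2$predictions$predicted_bgl, tolerance = 1e-12)
})
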