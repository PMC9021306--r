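# End-to-end orchestration: accumulated training over rounds 1..N,
# leave-one-out cross-validation (stage-1 screening input), repeated final
# training (stage-2 input), test-round prediction with last-round pairing,
# and evaluation.

#' Define an experiment plan
#'
#' Fixes the method, the data split and the configurations for one
#' subject-level experiment: train on rounds 1..N, test on later rounds.
#' Methods: `"IL"` (single-channel, each round's windows predict their own
#' glucose), `"DL"` (two-channel, adjacent-round pairs with the preceding
#' round's glucose as baseline; test rounds pair with round N), `"DL+S"`
#' (DL plus the two-stage screening).
#'
#' @param dataset A `subject_dataset` ([generate_subject()] or
#'   [read_subject()]).
#' @param method `"IL"`, `"DL"` or `"DL+S"`.
#' @param training_rounds Either the last training round N (trains on
#'   1..N) or the vector `1:N` itself.
#' @param test_rounds Rounds to predict; all must exceed N.
#' @param model Optional [model_config()]; defaults to a desk-scale
#'   configuration (scale 32, 40 epochs, batch 128, learning rate 3e-3)
#'   with the channel count implied by the method.
#' @param screening A [screening_config()] (used by `"DL+S"`).
#' @param seed Global integer seed for pairing and repeat training.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(dataset, method = c("DL+S", "DL", "IL"),
                            training_rounds, test_rounds,
                            model = NULL, screening = screening_config(),
                            seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "subject_dataset"))
  if (length(training_rounds) == 1)
    training_rounds <- seq_len(training_rounds)
  if (!identical(as.integer(training_rounds),
                 seq_len(max(training_rounds))))
    stop("training_rounds must be the contiguous block 1..N")
  n <- max(training_rounds)
  if (method != "IL" && n < 2)
    stop("paired training needs at least 2 training rounds")
  if (any(test_rounds <= n))
    stop("all test rounds must come after the last training round")
  n_avail <- length(dataset$recordings)
  if (max(test_rounds) > n_avail)
    stop("test round exceeds the rounds present in the dataset")
  if (is.null(model))
    model <- model_config(channels = if (method == "IL") 1 else 2,
                          scale = 32, epochs = 40, batch_size = 128,
                          learning_rate = 3e-3, seed = seed)
  if (method == "IL" && model$channels != 1)
    stop("IL requires a 1-channel model configuration")
  if (method != "IL" && model$channels != 2)
    stop("paired methods require a 2-channel model configuration")
  structure(list(
    dataset = dataset, method = method,
    training_rounds = as.integer(training_rounds),
    test_rounds = as.integer(test_rounds), model = model,
    screening = screening, seed = as.integer(seed)
  ), class = "experiment_plan")
}

.round_bgl <- function(dataset, r) {
  dataset$recordings[[r]][[1]]$reference_bgl
}

# Pool the replicates of one round into a single window_vectors-like list.
.pool_round <- function(round_vectors) {
  list(vectors = do.call(rbind, lapply(round_vectors, `[[`, "vectors")),
       meta = do.call(rbind, lapply(round_vectors, `[[`, "meta")))
}

.il_round_samples <- function(vectors, r) {
  build_il_samples(.pool_round(vectors[[r]]))
}

.dl_pair_samples <- function(plan, vectors, prev, now) {
  build_dl_samples(.pool_round(vectors[[now]]),
                   .pool_round(vectors[[prev]]),
                   .round_bgl(plan$dataset, prev),
                   seed = plan$seed,
                   subject_id = plan$dataset$subject_id)
}

.training_samples <- function(plan, vectors, exclude_target = NULL) {
  tr <- plan$training_rounds
  if (plan$method == "IL") {
    keep <- setdiff(tr, exclude_target)
    concat_samples(lapply(keep, function(r) .il_round_samples(vectors, r)))
  } else {
    sched <- schedule_dc_trainings(max(tr))
    if (!is.null(exclude_target))
      sched <- sched[sched$now_round != exclude_target, , drop = FALSE]
    concat_samples(lapply(seq_len(nrow(sched)), function(i)
      .dl_pair_samples(plan, vectors, sched$prev_round[i],
                       sched$now_round[i])))
  }
}

#' Leave-one-out cross-validation over the training rounds
#'
#' Holds out one training round at a time as the prediction target, trains
#' a fresh model on the remainder, and predicts the held-out round per
#' replicate. For the paired methods a fold holds out round j as the
#' *target*: the (j-1, j) pair leaves the training set, round j is
#' predicted paired with round j-1, and round 1 is never a fold target
#' (it has no predecessor). For IL every training round is a fold. The
#' pooled predictions and their Clarke zone counts feed the stage-1
#' confidence score.
#'
#' @param plan An [experiment_plan()] with at least 3 training rounds.
#' @param vectors Optional precomputed [subject_vectors()] result.
#' @return List with `predictions` (data frame `round`, `replicate`,
#'   `reference_bgl`, `predicted_bgl`), `zone_counts`, and `s_v` (the
#'   validation confidence score).
#' @export
loo_cross_validate <- function(plan, vectors = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  tr <- plan$training_rounds
  if (length(tr) < 3)
    stop("leave-one-out validation needs at least 3 training rounds")
  if (is.null(vectors)) vectors <- subject_vectors(plan$dataset)
  folds <- if (plan$method == "IL") tr else tr[-1]
  rows <- list()
  for (j in folds) {
    train_set <- .training_samples(plan, vectors, exclude_target = j)
    cfg <- plan$model
    cfg$seed <- plan$model$seed + 1000L + j
    net <- build_network(cfg)
    net <- train_model(net, train_set)
    for (k in seq_along(vectors[[j]])) {
      samp <- if (plan$method == "IL")
        build_il_samples(vectors[[j]][[k]])
      else
        build_dl_samples(vectors[[j]][[k]], .pool_round(vectors[[j - 1]]),
                         .round_bgl(plan$dataset, j - 1),
                         seed = plan$seed,
                         subject_id = plan$dataset$subject_id)
      rows[[length(rows) + 1]] <- data.frame(
        round = j, replicate = k,
        reference_bgl = .round_bgl(plan$dataset, j),
        predicted_bgl = predict_replicate(net, samp))
    }
  }
  predictions <- do.call(rbind, rows)
  zones <- ceg_zone(predictions$reference_bgl, predictions$predicted_bgl)
  zone_counts <- vapply(c("A", "B", "C", "D", "E"),
                        function(z) sum(zones == z), integer(1))
  list(predictions = predictions, zone_counts = zone_counts,
       s_v = validation_confidence(zone_counts,
                                   plan$screening$zone_weights))
}

#' Train the final model(s) on all training rounds
#'
#' Trains on the pooled samples of all training rounds (all adjacent-round
#' pairs for the paired methods). For `"DL+S"` the training is repeated
#' `n_repeats` times on identical data with distinct seeds, providing the
#' spread-score input; otherwise a single model is trained.
#'
#' @param plan An [experiment_plan()].
#' @param vectors Optional precomputed [subject_vectors()] result.
#' @return List of trained `dc_network` objects.
#' @export
train_final <- function(plan, vectors = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (is.null(vectors)) vectors <- subject_vectors(plan$dataset)
  train_set <- .training_samples(plan, vectors)
  n_models <- if (plan$method == "DL+S") plan$screening$n_repeats else 1L
  lapply(seq_len(n_models), function(i) {
    cfg <- plan$model
    cfg$seed <- plan$model$seed + i
    train_model(build_network(cfg), train_set)
  })
}

#' Predict the test rounds
#'
#' For the paired methods every test round's windows are paired with the
#' windows of the last training round N (same replicate), with round N's
#' measured glucose as the baseline; IL predicts from the test round's
#' windows alone. Per (round, replicate) each model yields one
#' (median-aggregated) prediction; under `"DL+S"` the repeat predictions
#' pass through the stage-2 spread filter.
#'
#' @param plan An [experiment_plan()].
#' @param models List of trained networks from [train_final()].
#' @param vectors Optional precomputed [subject_vectors()] result.
#' @return Data frame with one row per (test round, replicate): `round`,
#'   `replicate`, `reference_bgl`, `predicted_bgl` (`NA` when rejected),
#'   `accepted`, `s_t` (`NA` unless screening ran) and `zone`.
#' @export
predict_test <- function(plan, models, vectors = NULL) {
  stopifnot(inherits(plan, "experiment_plan"), length(models) >= 1)
  if (is.null(vectors)) vectors <- subject_vectors(plan$dataset)
  n_last <- max(plan$training_rounds)
  rows <- list()
  for (t in plan$test_rounds) {
    for (k in seq_along(vectors[[t]])) {
      samp <- if (plan$method == "IL")
        build_il_samples(vectors[[t]][[k]])
      else
        build_dl_samples(vectors[[t]][[k]], .pool_round(vectors[[n_last]]),
                         .round_bgl(plan$dataset, n_last),
                         seed = plan$seed,
                         subject_id = plan$dataset$subject_id)
      preds <- vapply(models, function(m) predict_replicate(m, samp),
                      numeric(1))
      if (plan$method == "DL+S") {
        sc <- stage2_filter(preds, plan$screening$st_threshold,
                            plan$screening$st_divisor)
        pred <- sc$prediction
        accepted <- sc$accepted
        s_t <- sc$s_t
      } else {
        pred <- preds[1]
        accepted <- TRUE
        s_t <- NA_real_
      }
      ref <- .round_bgl(plan$dataset, t)
      rows[[length(rows) + 1]] <- data.frame(
        round = t, replicate = k, reference_bgl = ref,
        predicted_bgl = pred, accepted = accepted, s_t = s_t,
        zone = if (accepted && is.finite(pred) && pred > 0)
          ceg_zone(ref, pred) else NA_character_)
    }
  }
  do.call(rbind, rows)
}

#' Run a full experiment
#'
#' Executes the whole pipeline on a subject: window vectors, the stage-1
#' cross-validation gate (for `"DL+S"`), final (repeated) training, test
#' prediction with stage-2 screening, and metric evaluation over the
#' accepted predictions. A stage-1 rejection short-circuits: no test
#' predictions are made.
#'
#' @param plan An [experiment_plan()].
#' @param out_dir Optional directory; when given, the prediction table,
#'   the cross-validation table and a metrics summary are written as CSV.
#' @param verbose Print stage progress.
#' @return An object of class `glucopair_experiment`: list with `plan`
#'   (method and split), `s_v`, `stage1_pass`, `cv` (cross-validation
#'   output or `NULL`), `predictions` (or `NULL` on stage-1 rejection) and
#'   `metrics` (a `metrics_report` over accepted predictions, or `NULL`).
#' @export
run_experiment <- function(plan, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  say <- function(...) if (verbose) message(...)
  say("computing window vectors")
  vectors <- subject_vectors(plan$dataset)
  cv <- NULL
  s_v <- NA_real_
  stage1 <- TRUE
  if (plan$method == "DL+S") {
    say("stage 1: leave-one-out cross-validation")
    cv <- loo_cross_validate(plan, vectors)
    s_v <- cv$s_v
    stage1 <- stage1_gate(s_v, min(plan$test_rounds), plan$screening)
  }
  predictions <- NULL
  metrics <- NULL
  if (stage1) {
    say("final training")
    models <- train_final(plan, vectors)
    say("test prediction")
    predictions <- predict_test(plan, models, vectors)
    acc <- predictions[predictions$accepted &
                         is.finite(predictions$predicted_bgl), ,
                       drop = FALSE]
    if (nrow(acc) > 0)
      metrics <- error_metrics(acc$reference_bgl, acc$predicted_bgl)
  } else {
    say("stage 1 rejected the model (S_V = ", round(s_v, 1),
        "); collect more rounds")
  }
  res <- structure(list(
    plan = list(method = plan$method,
                training_rounds = plan$training_rounds,
                test_rounds = plan$test_rounds, seed = plan$seed),
    s_v = s_v, stage1_pass = stage1, cv = cv,
    predictions = predictions, metrics = metrics
  ), class = "glucopair_experiment")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (!is.null(predictions))
      utils::write.csv(predictions,
                       file.path(out_dir, "predictions.csv"),
                       row.names = FALSE)
    if (!is.null(cv))
      utils::write.csv(cv$predictions,
                       file.path(out_dir, "cross_validation.csv"),
                       row.names = FALSE)
    if (!is.null(metrics))
      utils::write.csv(data.frame(
        r_a_mean = metrics$r_a_mean, r_a_sd = metrics$r_a_sd,
        mae = metrics$mae, rmse = metrics$rmse, r_p = metrics$r_p,
        zone_a_ratio = metrics$zone_a_ratio, n = metrics$n,
        s_v = s_v), file.path(out_dir, "summary.csv"),
        row.names = FALSE)
  }
  res
}

#' @export
print.glucopair_experiment <- function(x, ...) {
  cat("<glucopair_experiment>", x$plan$method, "\n")
  cat("  training rounds 1-", max(x$plan$training_rounds),
      ", test rounds ", paste(x$plan$test_rounds, collapse = ","),
      "\n", sep = "")
  if (x$plan$method == "DL+S")
    cat(sprintf("  stage 1: S_V = %.1f -> %s\n", x$s_v,
                if (x$stage1_pass) "pass" else "reject"))
  if (!is.null(x$predictions)) {
    cat(sprintf("  predictions: %d accepted / %d\n",
                sum(x$predictions$accepted), nrow(x$predictions)))
  }
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
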