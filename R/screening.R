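# Two-stage prediction-confidence screening:
#   stage 1 gates the model itself on a zone-weighted cross-validation
#   confidence score (S_V);
#   stage 2 filters individual test predictions on the trimmed,
#   median-normalized spread (S_T) of predictions from repeatedly trained
#   models, with the spread threshold selected from an ROC curve.

#' Screening configuration
#'
#' @param sv_threshold_early Stage-1 confidence threshold when the test
#'   round is earlier than `late_round` (default 50).
#' @param sv_threshold_late Stage-1 threshold from `late_round` on
#'   (default 60).
#' @param late_round Round index at which the stricter threshold starts to
#'   apply (default 7).
#' @param st_threshold Stage-2 spread threshold `y` (default 0.07).
#' @param n_repeats Number of repeated final trainings feeding the spread
#'   score (default 5; must be >= 4 so that two values can be trimmed).
#' @param st_divisor `"as_printed"` divides the trimmed sum of squares by
#'   `N - 1` (the published definition); `"conventional"` uses `N - 3`,
#'   the sample variance of the `N - 2` retained values.
#' @param zone_weights Zone weights of the confidence score (defaults:
#'   A = 1, B = 0.5, C = D = E = 0).
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(sv_threshold_early = 50, sv_threshold_late = 60,
                             late_round = 7, st_threshold = 0.07,
                             n_repeats = 5,
                             st_divisor = c("as_printed", "conventional"),
                             zone_weights = c(A = 1, B = 0.5, C = 0,
                                              D = 0, E = 0)) {
  st_divisor <- match.arg(st_divisor)
  stopifnot(n_repeats >= 4, sv_threshold_early > 0, sv_threshold_late > 0,
            st_threshold > 0, all(zone_weights >= 0 & zone_weights <= 1),
            all(c("A", "B", "C", "D", "E") %in% names(zone_weights)))
  structure(list(
    sv_threshold_early = sv_threshold_early,
    sv_threshold_late = sv_threshold_late, late_round = late_round,
    st_threshold = st_threshold, n_repeats = as.integer(n_repeats),
    st_divisor = st_divisor, zone_weights = zone_weights
  ), class = "screening_config")
}

#' Validation confidence score from zone counts
#'
#' The zone-weighted fraction of cross-validation predictions, reported on
#' a 0--100 scale: `100 * sum(w_i C_i) / sum(C_i)` with weights 1 for
#' zone A, 0.5 for zone B and 0 elsewhere (by default). All predictions in
#' zone A give 100; predictions only in zero-weight zones give 0.
#'
#' @param zone_counts Named counts per zone (A--E); a table or named
#'   vector. Missing zones count as zero.
#' @param weights Zone weights (default from [screening_config()]).
#' @return The confidence score in \[0, 100\], or `NA` when the total
#'   count is zero (callers must treat `NA` as a rejection).
#' @export
validation_confidence <- function(zone_counts,
                                  weights = c(A = 1, B = 0.5, C = 0,
                                              D = 0, E = 0)) {
  if (is.null(names(zone_counts))) {
    if (length(zone_counts) != length(weights))
      stop("unnamed zone_counts must list one count per zone, in order ",
           paste(names(weights), collapse = ""))
    names(zone_counts) <- names(weights)
  }
  if (!all(names(zone_counts) %in% names(weights)))
    stop("zone_counts has zones without a weight")
  counts <- stats::setNames(numeric(length(weights)), names(weights))
  counts[names(zone_counts)] <- as.numeric(zone_counts)
  total <- sum(counts)
  if (total < 1) return(NA_real_)
  100 * sum(weights[names(counts)] * counts) / total
}

#' Stage-1 gate on the validation confidence score
#'
#' Passes when the score reaches the round-dependent threshold: the early
#' threshold for test rounds before `late_round`, the stricter late
#' threshold afterwards. An `NA` score (no validation predictions) fails
#' safe and rejects.
#'
#' @param s_v Confidence score from [validation_confidence()].
#' @param test_round Index of the round being predicted.
#' @param config A [screening_config()].
#' @return `TRUE` (model accepted) or `FALSE` (reject; more training
#'   rounds are needed).
#' @export
stage1_gate <- function(s_v, test_round, config = screening_config()) {
  thr <- if (test_round < config$late_round) config$sv_threshold_early
  else config$sv_threshold_late
  isTRUE(s_v >= thr)
}

#' Test spread score of repeated predictions
#'
#' Given `N >= 4` predictions of the same quantity from repeatedly trained
#' models, removes exactly one maximum and one minimum, computes the sum
#' of squared deviations of the `N - 2` retained values about their mean,
#' divides by `N - 1` (as published; set `divisor = "conventional"` for
#' `N - 3`), takes the square root, and normalizes by the median of the
#' retained values. The score is 0 iff the retained predictions are all
#' equal and is invariant under positive rescaling of all predictions.
#'
#' @param predictions Numeric vector of `N >= 4` positive predictions.
#' @param divisor `"as_printed"` (N - 1) or `"conventional"` (N - 3).
#' @return The dimensionless spread score.
#' @export
test_spread <- function(predictions,
                        divisor = c("as_printed", "conventional")) {
  divisor <- match.arg(divisor)
  n <- length(predictions)
  if (n < 4) stop("spread score needs at least 4 repeated predictions")
  if (any(!is.finite(predictions) | predictions <= 0))
    stop("predictions must be positive and finite")
  retained <- predictions[-c(which.max(predictions),
                             which.min(predictions))]
  med <- stats::median(retained)
  if (med == 0) stop("median of retained predictions is zero")
  den <- if (divisor == "as_printed") n - 1 else n - 3
  sqrt(sum((retained - mean(retained))^2) / den) / med
}

#' Stage-2 filter on the spread of repeated predictions
#'
#' Accepts the test prediction when the spread score stays below the
#' threshold `y`, returning the median of the retained (trimmed)
#' predictions as the final value; otherwise rejects (the measurement
#' should be redone).
#'
#' @param predictions `N >= 4` repeated predictions (mg/dl).
#' @param y Spread threshold (default 0.07).
#' @param divisor Passed to [test_spread()].
#' @return List with `accepted` (flag), `s_t` (the spread score) and
#'   `prediction` (mg/dl; `NA` when rejected).
#' @export
stage2_filter <- function(predictions, y = 0.07,
                          divisor = c("as_printed", "conventional")) {
  s_t <- test_spread(predictions, divisor)
  retained <- predictions[-c(which.max(predictions),
                             which.min(predictions))]
  if (s_t < y)
    list(accepted = TRUE, s_t = s_t,
         prediction = stats::median(retained))
  else
    list(accepted = FALSE, s_t = s_t, prediction = NA_real_)
}

#' ROC curve over spread-score thresholds
#'
#' For each candidate threshold `y`, a prediction is called positive
#' (accepted) when its spread score is below `y`; the true/false positive
#' rates are computed against supplied truth flags (in the intended use, a
#' round is "true" when both replicate predictions land in Clarke zone A,
#' or one in A and the other in B). The optimal threshold minimizes the
#' Euclidean distance to the ideal corner (FPR 0, TPR 1). The area under
#' the curve is computed by trapezoidal integration after closing the
#' curve at (0,0) and (1,1).
#'
#' @param s_t Numeric spread scores.
#' @param truth Logical truth flags, same length; both classes must be
#'   present.
#' @param thresholds Candidate thresholds; defaults to the sorted unique
#'   scores plus an all-accepting upper bound.
#' @return List with `roc` (data frame `threshold`, `tpr`, `fpr`,
#'   `reject_ratio`), `optimal_y`, and `auc`.
#' @export
roc_threshold <- function(s_t, truth, thresholds = NULL) {
  stopifnot(length(s_t) == length(truth))
  truth <- as.logical(truth)
  if (!any(truth) || all(truth))
    stop("truth flags must contain both true and false outcomes")
  if (is.null(thresholds))
    thresholds <- c(sort(unique(s_t)), max(s_t) * 1.01 + 1e-12)
  pts <- vapply(thresholds, function(y) {
    pos <- s_t < y
    c(tpr = sum(pos & truth) / sum(truth),
      fpr = sum(pos & !truth) / sum(!truth),
      reject_ratio = mean(!pos))
  }, numeric(3))
  roc <- data.frame(threshold = thresholds, tpr = pts["tpr", ],
                    fpr = pts["fpr", ], reject_ratio = pts["reject_ratio", ])
  dist <- sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
  optimal_y <- roc$threshold[which.min(dist)]
  curve <- rbind(data.frame(fpr = 0, tpr = 0), roc[c("fpr", "tpr")],
                 data.frame(fpr = 1, tpr = 1))
  curve <- curve[order(curve$fpr, curve$tpr), ]
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(roc = roc, optimal_y = optimal_y, auc = auc)
}
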