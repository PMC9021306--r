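# Clinical evaluation: Clarke Error Grid zone classification, the
# accuracy score, and the standard error metrics (MAE, RMSE, Pearson
# correlation) over reference/predicted glucose pairs.

#' Clarke Error Grid zone of (reference, prediction) pairs
#'
#' Classifies each pair into one of the canonical Clarke zones, evaluated
#' in the fixed order A, E, C, D, with B as the remainder, using
#' boundary-inclusive comparisons:
#' \describe{
#'   \item{A}{ref <= 70 and pred <= 70, or pred within 20\% of ref.}
#'   \item{E}{ref >= 180 and pred <= 70, or ref <= 70 and pred >= 180.}
#'   \item{C}{70 <= ref <= 290 and pred >= ref + 110, or
#'     130 <= ref <= 180 and pred <= (7/5) ref - 182.}
#'   \item{D}{ref >= 240 and 70 <= pred <= 180, or ref <= 70 <= pred <= 180,
#'     or 175/3 <= ref <= 70 and pred >= (6/5) ref.}
#'   \item{B}{everything else.}
#' }
#' The rule order makes the classification total and exclusive: every
#' positive pair maps to exactly one zone, and perfect predictions always
#' map to A.
#'
#' @param reference Reference glucose, mg/dl (> 0); vectorized.
#' @param prediction Predicted glucose, mg/dl (> 0); recycled against
#'   `reference`.
#' @return Character vector of zones ("A".."E").
#' @export
ceg_zone <- function(reference, prediction) {
  n <- max(length(reference), length(prediction))
  ref <- rep_len(as.numeric(reference), n)
  pred <- rep_len(as.numeric(prediction), n)
  if (any(!is.finite(ref)) || any(!is.finite(pred)) ||
      any(ref <= 0) || any(pred <= 0))
    stop("reference and prediction must be positive finite glucose values")
  zone <- rep("B", n)
  a <- (ref <= 70 & pred <= 70) | (pred >= 0.8 * ref & pred <= 1.2 * ref)
  e <- (ref >= 180 & pred <= 70) | (ref <= 70 & pred >= 180)
  cc <- (ref >= 70 & ref <= 290 & pred >= ref + 110) |
    (ref >= 130 & ref <= 180 & pred <= (7 / 5) * ref - 182)
  d <- (ref >= 240 & pred >= 70 & pred <= 180) |
    (ref <= 70 & pred >= 70 & pred <= 180) |
    (ref >= 175 / 3 & ref <= 70 & pred >= (6 / 5) * ref)
  # precedence A > E > C > D > B
  zone[a] <- "A"
  zone[!a & e] <- "E"
  zone[!a & !e & cc] <- "C"
  zone[!a & !e & !cc & d] <- "D"
  zone[!a & !e & !cc & !d] <- "B"
  zone
}

#' Per-prediction accuracy score
#'
#' The symmetric form (default) is `100 * (1 - |pred - ref| / ref)`, which
#' equals 100 for a perfect prediction and decreases with the relative
#' error in either direction. The `as_printed` form,
#' `|(pred - ref)/ref - 1| * 100`, is the literal published expression; it
#' also gives 100 at equality but exceeds 100 for underpredictions, and is
#' provided for comparison.
#'
#' @param reference Reference glucose, mg/dl (> 0).
#' @param prediction Predicted glucose, mg/dl.
#' @param mode `"symmetric"` (default) or `"as_printed"`.
#' @return Numeric score vector (100 = perfect).
#' @export
accuracy_score <- function(reference, prediction,
                           mode = c("symmetric", "as_printed")) {
  mode <- match.arg(mode)
  if (any(reference <= 0)) stop("reference glucose must be positive")
  if (mode == "symmetric")
    100 * (1 - abs(prediction - reference) / reference)
  else
    abs((prediction - reference) / reference - 1) * 100
}

#' Error metrics and zone summary for a prediction set
#'
#' Computes mean absolute error, root mean squared error, the sample
#' Pearson correlation coefficient, the per-prediction accuracy-score mean
#' and standard deviation, and the Clarke zone counts with the zone-A
#' ratio.
#'
#' @param reference Reference glucose values, mg/dl.
#' @param prediction Predicted glucose values, same length.
#' @param accuracy_mode Passed to [accuracy_score()].
#' @return An object of class `metrics_report`: list with `n`, `mae`,
#'   `rmse`, `r_p` (NA when either side has zero variance or n < 2),
#'   `r_a_mean`, `r_a_sd`, `zone_counts` (named A--E), `zone_a_ratio`.
#' @export
error_metrics <- function(reference, prediction,
                          accuracy_mode = "symmetric") {
  if (length(reference) != length(prediction))
    stop("reference and prediction must have the same length")
  n <- length(reference)
  if (n == 0) stop("no predictions to evaluate")
  err <- prediction - reference
  r_p <- if (n >= 2 && stats::sd(reference) > 0 && stats::sd(prediction) > 0)
    stats::cor(reference, prediction) else NA_real_
  zones <- ceg_zone(reference, prediction)
  zone_counts <- vapply(c("A", "B", "C", "D", "E"),
                        function(z) sum(zones == z), integer(1))
  ra <- accuracy_score(reference, prediction, accuracy_mode)
  structure(list(
    n = n, mae = mean(abs(err)), rmse = sqrt(mean(err^2)), r_p = r_p,
    r_a_mean = mean(ra), r_a_sd = if (n >= 2) stats::sd(ra) else NA_real_,
    zone_counts = zone_counts,
    zone_a_ratio = zone_counts[["A"]] / n
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  n            %d\n", x$n))
  cat(sprintf("  R_A          %.2f +/- %.2f\n", x$r_a_mean,
              ifelse(is.na(x$r_a_sd), 0, x$r_a_sd)))
  cat(sprintf("  MAE          %.2f mg/dl\n", x$mae))
  cat(sprintf("  RMSE         %.2f mg/dl\n", x$rmse))
  cat(sprintf("  R_P          %s\n",
              ifelse(is.na(x$r_p), "NA", sprintf("%.3f", x$r_p))))
  cat(sprintf("  zone A ratio %.1f%%  (A:%d B:%d C:%d D:%d E:%d)\n",
              100 * x$zone_a_ratio, x$zone_counts[["A"]],
              x$zone_counts[["B"]], x$zone_counts[["C"]],
              x$zone_counts[["D"]], x$zone_counts[["E"]]))
  invisible(x)
}

#' Clarke Error Grid scatter plot
#'
#' Draws the predictions over the classical Clarke zone boundaries using
#' base graphics, coloring points by zone.
#'
#' @param reference,prediction Glucose pairs, mg/dl.
#' @param max_bgl Axis limit (default 400).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the zone of each point.
#' @export
plot_ceg <- function(reference, prediction, max_bgl = 400, ...) {
  zones <- ceg_zone(reference, prediction)
  cols <- c(A = "forestgreen", B = "steelblue", C = "orange",
            D = "darkorange3", E = "firebrick")
  graphics::plot(reference, prediction, xlim = c(0, max_bgl),
                 ylim = c(0, max_bgl), col = cols[zones], pch = 19,
                 xlab = "Reference BGL (mg/dl)",
                 ylab = "Predicted BGL (mg/dl)", ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  graphics::abline(0, 1.2, col = "grey70")
  graphics::abline(0, 0.8, col = "grey70")
  graphics::segments(c(70, 0), c(0, 70), c(70, 70), c(56, 70),
                     col = "grey70")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                   bty = "n", title = "CEG zone")
  invisible(zones)
}
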