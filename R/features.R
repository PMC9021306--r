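# Morphological features of a PPG pulse and assembly of the 406-element
# model input vector (6 features followed by the 400 window samples).

#' Locate the last complete pulse inside a window
#'
#' A window ends at an accepted valley; the last complete pulse it contains
#' spans from the last accepted valley before the terminal one (if present
#' inside the window) to the terminal valley.
#'
#' @param window A `signal_window` from [extract_windows()].
#' @return Integer vector `c(start, end)` of window-local sample positions
#'   (1-based, `end` is the window length), or `NULL` when the window holds
#'   no preceding accepted valley and must be excluded downstream.
#' @export
pulse_bounds <- function(window) {
  stopifnot(inherits(window, "signal_window"))
  if (is.na(window$preceding_valley_index)) return(NULL)
  wl <- window$window_len
  start <- window$preceding_valley_index - window$terminal_valley_index + wl
  if (start < 1 || start >= wl) return(NULL)
  c(start = as.integer(start), end = wl)
}

# Total duration (seconds) where the linear interpolant of y stays >= thr.
.width_at <- function(y, thr, dt) {
  n <- length(y)
  if (n < 2) return(0)
  a1 <- y[-n]
  a2 <- y[-1]
  b1 <- a1 >= thr
  b2 <- a2 >= thr
  fall <- b1 & !b2
  rise <- !b1 & b2
  dt * (sum(b1 & b2) +
          sum((a1[fall] - thr) / (a1[fall] - a2[fall])) +
          sum((a2[rise] - thr) / (a2[rise] - a1[rise])))
}

#' Morphological features of a window's last complete pulse
#'
#' Computes the six features used as model input: heart rate, area under
#' the pulse, and the pulse widths at 0% (full width), 25%, 50% and 75% of
#' the peak amplitude. The pulse baseline is the smaller of the two
#' bounding valley amplitudes; the peak amplitude `A` is the pulse maximum
#' above that baseline. A width at fraction `q` is the total duration where
#' the baseline-corrected signal stays at or above `q * A`, with linear
#' interpolation at threshold crossings; the full width (`q = 0`) is the
#' valley-to-valley pulse duration and the heart rate is `60 /` that
#' duration.
#'
#' @param window A `signal_window` from [extract_windows()].
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `morph_features`: list with `heart_rate`
#'   (bpm), `auc` (amplitude x seconds), `fw`, `fw_25`, `fw_50`, `fw_75`
#'   (seconds); or `NULL` for a window without a complete pulse.
#' @export
morph_features <- function(window, sampling_rate) {
  stopifnot(sampling_rate > 0)
  bounds <- pulse_bounds(window)
  if (is.null(bounds)) return(NULL)
  x <- window$samples[bounds[["start"]]:bounds[["end"]]]
  dt <- 1 / sampling_rate
  duration <- (bounds[["end"]] - bounds[["start"]]) * dt
  baseline <- min(x[1], x[length(x)])
  y <- x - baseline
  a <- max(y)
  if (a <= 0) return(NULL)
  widths <- vapply(c(0, 0.25, 0.5, 0.75),
                   function(q) .width_at(y, q * a, dt), numeric(1))
  auc <- sum((y[-1] + y[-length(y)]) / 2) * dt
  structure(list(
    heart_rate = 60 / duration, auc = auc,
    fw = widths[1], fw_25 = widths[2], fw_50 = widths[3], fw_75 = widths[4]
  ), class = "morph_features")
}

#' Assemble the 406-element model input vector
#'
#' Concatenates the six morphological features (in the order heart rate,
#' AUC, full width, FW_25, FW_50, FW_75) with the 400 window samples.
#'
#' @param features A [morph_features()] result.
#' @param window The `signal_window` the features were computed from.
#' @param meta Optional list with `round_index`, `replicate_index`,
#'   `reference_bgl`, attached as attributes.
#' @return Numeric vector of length 406 with the metadata as attributes.
#' @export
assemble_vector <- function(features, window, meta = list()) {
  stopifnot(inherits(features, "morph_features"),
            inherits(window, "signal_window"))
  v <- c(features$heart_rate, features$auc, features$fw, features$fw_25,
         features$fw_50, features$fw_75, window$samples)
  if (length(v) != window$window_len + 6)
    stop("internal error: assembled vector has wrong length")
  attr(v, "round_index") <- meta$round_index
  attr(v, "replicate_index") <- meta$replicate_index
  attr(v, "reference_bgl") <- meta$reference_bgl
  v
}

#' Compute all window vectors of one recording
#'
#' Runs [preprocess_recording()], computes features for every window, and
#' stacks the resulting 406-element vectors into a matrix. Windows without
#' a complete pulse are dropped.
#'
#' @param recording A [ppg_recording()].
#' @param cutoff,window_len Passed to [preprocess_recording()].
#' @return List with `vectors` (matrix, one row per valid window, 406
#'   columns), `meta` (data frame with `round`, `replicate`,
#'   `reference_bgl`, one row per window), `n_dropped` (windows without a
#'   complete pulse) and the `windows` list itself.
#' @export
window_vectors <- function(recording, cutoff = 0.75, window_len = 400) {
  pp <- preprocess_recording(recording, cutoff = cutoff,
                             window_len = window_len)
  fs <- recording$sampling_rate
  meta <- list(round_index = recording$round_index,
               replicate_index = recording$replicate_index,
               reference_bgl = recording$reference_bgl)
  rows <- list()
  dropped <- 0L
  for (w in pp$windows) {
    f <- morph_features(w, fs)
    if (is.null(f)) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1]] <- assemble_vector(f, w, meta)
  }
  vectors <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, window_len + 6)
  colnames(vectors) <- c("heart_rate", "auc", "fw", "fw_25", "fw_50",
                         "fw_75", paste0("s", seq_len(window_len)))
  list(
    vectors = vectors,
    meta = data.frame(
      round = rep(recording$round_index, nrow(vectors)),
      replicate = rep(recording$replicate_index, nrow(vectors)),
      reference_bgl = rep(recording$reference_bgl, nrow(vectors))
    ),
    n_dropped = dropped,
    windows = pp$windows
  )
}

#' Window vectors for every recording of a subject
#'
#' @param dataset A `subject_dataset` from [generate_subject()].
#' @param ... Passed to [window_vectors()].
#' @return Nested list `[[round]][[replicate]]` of [window_vectors()]
#'   results.
#' @export
subject_vectors <- function(dataset, ...) {
  stopifnot(inherits(dataset, "subject_dataset"))
  lapply(dataset$recordings, function(round)
    lapply(round, function(rec) window_vectors(rec, ...)))
}
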