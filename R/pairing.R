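# Assembly of model samples: conventional single-channel samples and
# two-channel paired samples linking adjacent measurement rounds, plus
# the schedule of differential-cell (DC) training tasks.

#' Build single-channel samples for one round
#'
#' One sample per window vector; the target is that window's reference
#' glucose. This is the conventional single-input formulation: the current
#' round's signal alone predicts the current round's glucose.
#'
#' @param round_vectors A [window_vectors()] result (or a pooled list with
#'   `vectors` and `meta`).
#' @return An object of class `sample_set` with `x_now` (matrix), `target`
#'   (mg/dl), `round`, `replicate`; `x_prev` and `baseline` are `NULL`.
#' @export
build_il_samples <- function(round_vectors) {
  v <- round_vectors$vectors
  m <- round_vectors$meta
  structure(list(
    x_now = v, x_prev = NULL, baseline = NULL,
    target = m$reference_bgl, round = m$round, replicate = m$replicate,
    pairing = NULL
  ), class = "sample_set")
}

# Deterministic per-(subject, round, replicate) RNG substream, so adding
# subjects or rounds does not perturb other pairings.
.pair_seed <- function(seed, subject_id, round, replicate) {
  h <- sum(utf8ToInt(as.character(subject_id))) %% 10007
  as.integer((as.numeric(seed) * 100003 + h * 7919 +
                round * 1009 + replicate * 101) %% 2147483629)
}

#' Build two-channel paired samples for one round
#'
#' Each window of the current round is paired with a window drawn uniformly
#' at random (with replacement) from the *same replicate* of the preceding
#' round, and carries the preceding round's measured glucose as the
#' baseline; the target is the current round's reference glucose. Pairing
#' is deterministic given `seed`: every (subject, round, replicate) block
#' uses its own derived RNG substream.
#'
#' @param now [window_vectors()]-style list for the current round and
#'   replicate(s).
#' @param prev Same for the preceding round.
#' @param prev_bgl_by_replicate Numeric vector of the preceding round's
#'   reference glucose indexed by replicate (a scalar is recycled to all
#'   replicates).
#' @param seed Global integer seed.
#' @param subject_id Subject identifier entering the pairing substream.
#' @return A `sample_set` with `x_now`, `x_prev` (matrices, same row
#'   count), `baseline`, `target`, `round`, `replicate` and a `pairing`
#'   audit data frame (`now_row`, `prev_row`, `replicate`).
#' @export
build_dl_samples <- function(now, prev, prev_bgl_by_replicate, seed = 1L,
                             subject_id = "S1") {
  vn <- now$vectors
  mn <- now$meta
  vp <- prev$vectors
  mp <- prev$meta
  n <- nrow(vn)
  if (n == 0)
    return(structure(list(x_now = vn, x_prev = vn, baseline = numeric(0),
                          target = numeric(0), round = integer(0),
                          replicate = integer(0),
                          pairing = data.frame()), class = "sample_set"))
  reps <- sort(unique(mn$replicate))
  if (length(prev_bgl_by_replicate) == 1)
    prev_bgl_by_replicate <- stats::setNames(
      rep(prev_bgl_by_replicate, length(reps)), reps)
  prev_row <- integer(n)
  baseline <- numeric(n)
  for (k in reps) {
    now_idx <- which(mn$replicate == k)
    prev_idx <- which(mp$replicate == k)
    if (length(prev_idx) == 0)
      stop("no previous-round windows for replicate ", k)
    rnd <- unique(mn$round[now_idx])[1]
    set.seed(.pair_seed(seed, subject_id, rnd, k))
    prev_row[now_idx] <- prev_idx[
      sample.int(length(prev_idx), length(now_idx), replace = TRUE)]
    b <- if (!is.null(names(prev_bgl_by_replicate)))
      prev_bgl_by_replicate[[as.character(k)]]
    else prev_bgl_by_replicate[[min(k, length(prev_bgl_by_replicate))]]
    baseline[now_idx] <- b
  }
  structure(list(
    x_now = vn, x_prev = vp[prev_row, , drop = FALSE],
    baseline = baseline, target = mn$reference_bgl,
    round = mn$round, replicate = mn$replicate,
    pairing = data.frame(now_row = seq_len(n), prev_row = prev_row,
                         replicate = mn$replicate)
  ), class = "sample_set")
}

#' Schedule of differential-cell training tasks
#'
#' Accumulated training through `n_rounds` rounds uses one task per
#' adjacent round pair: (1,2), (2,3), ..., (`n_rounds`-1, `n_rounds`).
#'
#' @param n_rounds Number of training rounds (>= 2).
#' @return Data frame with columns `prev_round`, `now_round`
#'   (`n_rounds - 1` rows, consecutive and ordered).
#' @export
schedule_dc_trainings <- function(n_rounds) {
  if (n_rounds < 2)
    stop("at least 2 rounds are required to schedule pair trainings")
  data.frame(prev_round = seq_len(n_rounds - 1),
             now_round = seq_len(n_rounds - 1) + 1L)
}

#' Concatenate sample sets
#'
#' Pools several [build_il_samples()] / [build_dl_samples()] results into
#' one training set. All sets must agree on whether they carry a paired
#' channel.
#'
#' @param sets List of `sample_set` objects.
#' @return A single `sample_set`.
#' @export
concat_samples <- function(sets) {
  sets <- Filter(function(s) length(s$target) > 0, sets)
  stopifnot(length(sets) > 0)
  paired <- !is.null(sets[[1]]$x_prev)
  structure(list(
    x_now = do.call(rbind, lapply(sets, `[[`, "x_now")),
    x_prev = if (paired) do.call(rbind, lapply(sets, `[[`, "x_prev")),
    baseline = if (paired) unlist(lapply(sets, `[[`, "baseline")),
    target = unlist(lapply(sets, `[[`, "target")),
    round = unlist(lapply(sets, `[[`, "round")),
    replicate = unlist(lapply(sets, `[[`, "replicate")),
    pairing = NULL
  ), class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples, %s, rounds %s\n",
              length(x$target),
              if (is.null(x$x_prev)) "1-channel" else "2-channel (paired)",
              paste(sort(unique(x$round)), collapse = ",")))
  invisible(x)
}
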