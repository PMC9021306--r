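# Shared fixtures, memoized so expensive synthetic subjects are built once
# per test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) assign(name, force(expr), envir = .fx)
  .fx[[name]]
}

# Noise-free one-minute recording at exactly 60 bpm: 1.6 s lead-in then 60
# identical pulses at 1 Hz, 250 Hz sampling.
clean_minute_subject <- function() {
  fixture("clean_minute", generate_subject(sim_config(
    n_rounds = 2, heart_rate = 60, noise_sd = 0, wander_amplitude = 0,
    coupling_coefficient = 0, drift_sd = 0, seed = 101)))
}

# Small subject with all noise sources on, used for property checks.
# 40 s recordings: with a random 60-90 bpm heart rate, shorter recordings
# can fall to exactly 30 beats, the cliff of the 30th-largest-fall rule.
noisy_subject <- function() {
  fixture("noisy", generate_subject(sim_config(
    n_rounds = 5, duration = 40, seed = 202)))
}

# Quick model configuration for wiring tests (not meant to learn much).
tiny_model_cfg <- function(channels = 1, ...) {
  model_config(channels = channels, scale = 128, epochs = 3,
               batch_size = 64, learning_rate = 1e-2, seed = 7, ...)
}

# Row indices of window vectors whose terminal valley sits at least
# `margin_s` seconds away from both recording edges (zero-phase filter
# transients distort the outermost beats).
interior_rows <- function(wv, n_samples, sampling_rate, margin_s = 5) {
  valid <- !vapply(wv$windows, function(w) is.null(pulse_bounds(w)),
                   logical(1))
  term <- vapply(wv$windows[valid], `[[`, integer(1),
                 "terminal_valley_index")
  m <- margin_s * sampling_rate
  which(term > m & term < n_samples - m)
}

# Random sample_set of pure-noise vectors, for model wiring tests.
random_samples <- function(n, channels = 1, targets = NULL, seed = 1) {
  set.seed(seed)
  structure(list(
    x_now = matrix(stats::rnorm(n * 406), n, 406),
    x_prev = if (channels == 2) matrix(stats::rnorm(n * 406), n, 406),
    baseline = if (channels == 2) stats::runif(n, 100, 200),
    target = if (is.null(targets)) stats::runif(n, 80, 350) else targets,
    round = rep(1L, n), replicate = rep(1L, n)
  ), class = "sample_set")
}
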