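# Synthetic PPG / blood-glucose simulator.
#
# Emulates the measurement protocol the rest of the package expects:
# repeated rounds of fasting measurements, two 1-minute PPG replicates per
# round, one reference blood-glucose value (mg/dl) per round, pulse
# morphology riding on low-frequency baseline wander plus additive noise,
# and a tunable coupling between pulse width and glucose change.

#' Simulation configuration for a synthetic PPG subject
#'
#' Parameters describing one simulated subject: the recording geometry
#' (sampling rate, duration, lead-in), the per-round physiology (heart rate,
#' glucose trajectory), and the generative couplings (glucose-to-pulse-width
#' coupling, slow morphological drift, baseline wander, noise).
#'
#' The pulse width-at-half-maximum of round \eqn{r} is modulated as
#' \deqn{w_r = w_0 \cdot d_r \cdot (1 + c \, (BGL_r - BGL_1)/100)}
#' where \eqn{w_0} is `base_width`, \eqn{c} is `coupling_coefficient`
#' (fractional width change per 100 mg/dl of glucose change relative to
#' round 1) and \eqn{d_r} is a slow multiplicative random-walk drift
#' (`drift_sd` per round) emulating long-term morphological change that is
#' unrelated to glucose.
#'
#' @param sampling_rate Sampling rate in Hz. Default 250 (so that a
#'   400-sample analysis window spans 1.6 s).
#' @param duration Duration of the pulse train in seconds (default 60).
#' @param lead_in Seconds of flat pre-signal before the first pulse
#'   (default 1.6, guaranteeing the first pulse valley has 400 preceding
#'   samples).
#' @param lead_out Seconds of flat signal appended after the last pulse so
#'   its terminal valley is detectable as a local minimum (default 0.8).
#' @param heart_rate Heart rate in beats/min: a scalar (all rounds equal), a
#'   vector of length `n_rounds`, or `NULL` to draw one value per round
#'   uniformly from 60--90 bpm.
#' @param n_rounds Number of measurement rounds (>= 2; default 15).
#' @param n_replicates Recordings per round (default 2).
#' @param bgl_trajectory Reference blood glucose per round in mg/dl, or
#'   `NULL` to draw a bounded random walk in 80--350 mg/dl.
#' @param base_width Pulse width at half maximum of round 1, as a fraction
#'   of the beat period (default 0.4).
#' @param coupling_coefficient Fractional change of pulse width per
#'   100 mg/dl of glucose change from round 1 (default 0.1).
#' @param drift_sd Standard deviation of the per-round multiplicative
#'   random-walk drift of the base pulse width (default 0.02). Set to 0 for
#'   a drift-free subject.
#' @param pulse_amplitude Peak amplitude of each pulse in arbitrary units
#'   (default 1).
#' @param wander_amplitude Amplitude of the sinusoidal baseline wander
#'   (default 0.5).
#' @param wander_freq Frequency of the baseline wander in Hz; must lie
#'   strictly below the 0.75 Hz band-split cutoff (default 0.2).
#' @param noise_sd Standard deviation of the additive measurement noise
#'   (default 0.02).
#' @param noise_bandwidth Bandwidth of the measurement noise in Hz
#'   (default 8): Gaussian noise low-passed to emulate the anti-aliasing
#'   filter of a PPG analog front end, then rescaled to `noise_sd`. Pulse
#'   content lives well below this bandwidth, so the noise is broadband
#'   relative to the signal while still sampled smoothly.
#' @param seed Integer seed making the whole subject reproducible.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_subject()], [synth_pulse()]
#' @export
sim_config <- function(sampling_rate = 250, duration = 60, lead_in = 1.6,
                       lead_out = 0.8, heart_rate = NULL, n_rounds = 15,
                       n_replicates = 2, bgl_trajectory = NULL,
                       base_width = 0.4, coupling_coefficient = 0.1,
                       drift_sd = 0.02, pulse_amplitude = 1,
                       wander_amplitude = 0.5, wander_freq = 0.2,
                       noise_sd = 0.02, noise_bandwidth = 8, seed = 1L) {
  cfg <- structure(list(
    sampling_rate = sampling_rate, duration = duration, lead_in = lead_in,
    lead_out = lead_out, heart_rate = heart_rate, n_rounds = n_rounds,
    n_replicates = n_replicates, bgl_trajectory = bgl_trajectory,
    base_width = base_width, coupling_coefficient = coupling_coefficient,
    drift_sd = drift_sd, pulse_amplitude = pulse_amplitude,
    wander_amplitude = wander_amplitude, wander_freq = wander_freq,
    noise_sd = noise_sd, noise_bandwidth = noise_bandwidth,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$sampling_rate > 0, cfg$duration > 0, cfg$lead_in >= 0,
            cfg$lead_out >= 0, cfg$n_replicates >= 1, cfg$noise_sd >= 0,
            cfg$wander_amplitude >= 0, cfg$drift_sd >= 0,
            cfg$pulse_amplitude > 0)
  if (cfg$n_rounds < 2)
    stop("n_rounds must be >= 2 (round pairing needs a preceding round)")
  if (!(cfg$wander_freq > 0 && cfg$wander_freq < 0.75))
    stop("wander_freq must lie in (0, 0.75) Hz, below the band-split cutoff")
  if (cfg$base_width < 0.1 || cfg$base_width > 0.9)
    stop("base_width must lie in [0.1, 0.9]")
  if (!(cfg$noise_bandwidth > 0 &&
        cfg$noise_bandwidth < cfg$sampling_rate / 2))
    stop("noise_bandwidth must lie in (0, sampling_rate/2) Hz")
  if (!is.null(cfg$bgl_trajectory)) {
    if (length(cfg$bgl_trajectory) != cfg$n_rounds)
      stop("bgl_trajectory must have one value per round")
    if (any(cfg$bgl_trajectory <= 20 | cfg$bgl_trajectory >= 600))
      stop("bgl_trajectory values must lie in (20, 600) mg/dl")
  }
  if (!is.null(cfg$heart_rate)) {
    if (!length(cfg$heart_rate) %in% c(1L, cfg$n_rounds))
      stop("heart_rate must be a scalar or one value per round")
    if (any(cfg$heart_rate <= 0)) stop("heart_rate must be positive")
  }
  invisible(cfg)
}

#' Generate a single asymmetric PPG pulse
#'
#' Builds one pulse as a power-of-cosine lobe with a fast rise (first third
#' of the support) and a slower fall (remaining two thirds), mimicking the
#' systolic upstroke / diastolic decay of a finger PPG beat. The fall from
#' the peak to the following valley is the largest amplitude difference in
#' the pulse, which is the property the bigger-fall-side-slope annotation
#' relies on. The exponent is chosen so that the width of the pulse at half
#' of its peak amplitude equals `width_fraction` times the pulse duration
#' (exact in continuous time; discretisation error is below one sample
#' spacing). The first and last samples are exactly zero.
#'
#' @param width_fraction Width at half maximum as a fraction of the pulse
#'   duration, in \[0.1, 0.9\].
#' @param length Number of samples; 0 gives an empty series.
#' @return Numeric vector of `length` amplitudes, peak amplitude 1.
#' @examples
#' p <- synth_pulse(0.5, 250)
#' @export
synth_pulse <- function(width_fraction, length) {
  if (!is.numeric(width_fraction) || length(width_fraction) != 1 ||
      is.na(width_fraction) || width_fraction < 0.1 || width_fraction > 0.9)
    stop("width_fraction must be a single value in [0.1, 0.9]")
  length <- as.integer(length)
  if (length <= 0) return(numeric(0))
  if (length == 1) return(0)
  s <- seq(0, 1, length.out = length)
  r <- 1 / 3                       # rise fraction; fall takes the rest
  # cosine lobe blended with a tent so the pulse keeps a nonzero slope
  # into its endpoints: diastolic valleys of real PPG are V-shaped, and a
  # flat-bottomed valley would make the detected minimum ill-conditioned
  beta <- 0.25
  h <- ifelse(s <= r,
              (1 - cos(pi * s / r)) / 2,
              (1 + cos(pi * (s - r) / (1 - r))) / 2)
  tent <- ifelse(s <= r, s / r, (1 - s) / (1 - r))
  g <- (1 - beta) * h + beta * tent
  if (length < 8) return(g)
  # raising to a power narrows (p > 1) or broadens (p < 1) the lobe
  # without moving its zeros; solve p so the width at half maximum equals
  # width_fraction of the support
  dt <- 1 / (length - 1)
  fwhm <- function(p) {
    y <- g^p
    .width_at(y, max(y) / 2, dt)
  }
  p <- stats::uniroot(function(p) fwhm(p) - width_fraction,
                      lower = 0.02, upper = 80, tol = 1e-9)$root
  g^p
}

#' Generate a full multi-round synthetic subject
#'
#' Produces `n_rounds` rounds of `n_replicates` PPG recordings each, with a
#' shared per-round reference glucose value. Each recording is a flat
#' lead-in, a train of identical pulses at the round's heart rate, a short
#' flat lead-out, sinusoidal baseline wander (round-specific random phase,
#' identical across replicates) and additive white noise (the only
#' component that differs between replicates of a round). The per-round
#' pulse width follows the glucose trajectory through
#' `coupling_coefficient` (see [sim_config()]).
#'
#' @param config A [sim_config()] object.
#' @param subject_id Identifier stored in each recording (default "S1").
#' @return An object of class `subject_dataset`: a list with
#'   `recordings[[round]][[replicate]]` ([ppg_recording()] objects),
#'   `ground_truth` (per-round data frame of latent heart rate, width
#'   fraction, drift, glucose and wander phase, for recovery tests) and the
#'   `config` used.
#' @export
generate_subject <- function(config, subject_id = "S1") {
  validate_sim_config(config)
  fs <- config$sampling_rate
  set.seed(config$seed)

  n_rounds <- config$n_rounds
  hr <- config$heart_rate
  if (is.null(hr)) hr <- stats::runif(n_rounds, 60, 90)
  if (length(hr) == 1) hr <- rep(hr, n_rounds)

  bgl <- config$bgl_trajectory
  if (is.null(bgl)) {
    bgl <- numeric(n_rounds)
    bgl[1] <- stats::runif(1, 120, 220)
    for (r in seq_len(n_rounds - 1)) {
      step <- stats::rnorm(1, 0, 40)
      nxt <- bgl[r] + step
      # reflect into the plausible fasting range
      if (nxt < 80) nxt <- 80 + (80 - nxt)
      if (nxt > 350) nxt <- 350 - (nxt - 350)
      bgl[r + 1] <- min(max(nxt, 80), 350)
    }
  }

  drift <- cumprod(c(1, 1 + stats::rnorm(n_rounds - 1, 0, config$drift_sd)))
  phase <- stats::runif(n_rounds, 0, 2 * pi)

  wf <- config$base_width * drift *
    (1 + config$coupling_coefficient * (bgl - bgl[1]) / 100)
  wf <- pmin(pmax(wf, 0.1), 0.9)

  n_lead <- round(config$lead_in * fs)
  n_tail <- round(config$lead_out * fs)

  recordings <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    period <- round(fs * 60 / hr[r])
    n_beats <- floor(config$duration * fs / period)
    n_total <- n_lead + n_beats * period + 1 + n_tail
    base <- numeric(n_total)
    pulse <- config$pulse_amplitude * synth_pulse(wf[r], period + 1)
    for (b in seq_len(n_beats)) {
      idx <- n_lead + (b - 1) * period + seq_len(period + 1)
      base[idx] <- base[idx] + pulse
    }
    t <- (seq_len(n_total) - 1) / fs
    wander <- config$wander_amplitude *
      sin(2 * pi * config$wander_freq * t + phase[r])
    nf <- if (config$noise_sd > 0)
      signal::butter(2, config$noise_bandwidth / (fs / 2), type = "low")
    recordings[[r]] <- vector("list", config$n_replicates)
    for (k in seq_len(config$n_replicates)) {
      noise <- numeric(n_total)
      if (config$noise_sd > 0) {
        raw <- signal::filtfilt(nf, stats::rnorm(n_total))
        noise <- raw * (config$noise_sd / stats::sd(raw))
      }
      recordings[[r]][[k]] <- ppg_recording(
        samples = base + wander + noise,
        sampling_rate = fs, subject_id = subject_id,
        round_index = r, replicate_index = k, reference_bgl = bgl[r]
      )
    }
  }

  structure(list(
    recordings = recordings,
    ground_truth = data.frame(
      round = seq_len(n_rounds), heart_rate = hr, width_fraction = wf,
      drift = drift, reference_bgl = bgl, wander_phase = phase
    ),
    config = config,
    subject_id = subject_id
  ), class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat("<subject_dataset>", x$subject_id, "\n")
  cat("  rounds:", x$config$n_rounds,
      " replicates/round:", x$config$n_replicates, "\n")
  cat("  reference BGL range:",
      sprintf("%.0f-%.0f mg/dl", min(x$ground_truth$reference_bgl),
              max(x$ground_truth$reference_bgl)), "\n")
  invisible(x)
}

#' Write / read a subject dataset as plain-text files
#'
#' `write_subject()` stores one CSV per recording (a single `amplitude`
#' column) plus a JSON manifest holding per-recording metadata (round,
#' replicate, reference glucose, sampling rate) and the latent ground
#' truth. `read_subject()` restores the dataset from such a directory.
#'
#' @param dataset A `subject_dataset` from [generate_subject()].
#' @param dir Output (input) directory; created if missing.
#' @return `write_subject()` returns `dir` invisibly; `read_subject()`
#'   returns a `subject_dataset`.
#' @export
write_subject <- function(dataset, dir) {
  stopifnot(inherits(dataset, "subject_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  for (r in seq_along(dataset$recordings)) {
    for (k in seq_along(dataset$recordings[[r]])) {
      rec <- dataset$recordings[[r]][[k]]
      file <- sprintf("r%02d_k%d.csv", r, k)
      utils::write.csv(data.frame(amplitude = rec$samples),
                       file.path(dir, file), row.names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        round = r, replicate = k, file = file,
        reference_bgl = rec$reference_bgl,
        sampling_rate = rec$sampling_rate
      )
    }
  }
  manifest <- list(
    subject_id = dataset$subject_id,
    n_rounds = dataset$config$n_rounds,
    n_replicates = dataset$config$n_replicates,
    recordings = do.call(rbind, rows),
    ground_truth = dataset$ground_truth
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_subject
#' @export
read_subject <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  n_rounds <- manifest$n_rounds
  n_rep <- manifest$n_replicates
  recs <- manifest$recordings
  recordings <- rep(list(vector("list", n_rep)), n_rounds)
  for (i in seq_len(nrow(recs))) {
    amp <- utils::read.csv(file.path(dir, recs$file[i]))$amplitude
    recordings[[recs$round[i]]][[recs$replicate[i]]] <- ppg_recording(
      samples = amp, sampling_rate = recs$sampling_rate[i],
      subject_id = manifest$subject_id, round_index = recs$round[i],
      replicate_index = recs$replicate[i],
      reference_bgl = recs$reference_bgl[i]
    )
  }
  structure(list(
    recordings = recordings,
    ground_truth = as.data.frame(manifest$ground_truth),
    config = NULL,
    subject_id = manifest$subject_id
  ), class = "subject_dataset")
}
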