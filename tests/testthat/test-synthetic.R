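# Synthetic PPG generator: pulse geometry, determinism, couplings, and the
# spectral placement of its components.

test_that("pulse width at half maximum tracks the requested fraction", {
  for (len in c(200, 250, 333)) {
    for (wf in c(0.2, 0.35, 0.5, 0.7, 0.9)) {
      p <- synth_pulse(wf, len)
      above <- which(p >= max(p) / 2)
      measured <- (max(above) - min(above)) / (len - 1)
      expect_lt(abs(measured / wf - 1), 0.05)
    }
  }
})

test_that("pulse shape is asymmetric with the big drop on the fall side", {
  p <- synth_pulse(0.5, 250)
  expect_equal(p[1], 0)
  expect_equal(p[250], 0)
  expect_lt(which.max(p), 125)            # fast rise, slower fall
  # the peak-to-following-valley drop spans the full amplitude
  expect_equal(max(p) - min(p[which.max(p):250]), max(p))
})

test_that("pulse generation handles degenerate input and is deterministic", {
  expect_identical(synth_pulse(0.5, 0), numeric(0))
  expect_identical(synth_pulse(0.42, 250), synth_pulse(0.42, 250))
  expect_error(synth_pulse(0.05, 100), "width_fraction")
  expect_error(synth_pulse(0.95, 100), "width_fraction")
})

test_that("identical seeds reproduce a subject bit-identically", {
  cfg <- sim_config(n_rounds = 3, duration = 30, seed = 9)
  a <- generate_subject(cfg)
  b <- generate_subject(cfg)
  expect_identical(a, b)
})

test_that("zero coupling, drift and noise make all rounds identical", {
  cfg <- sim_config(n_rounds = 3, duration = 30, heart_rate = 70,
                    coupling_coefficient = 0, drift_sd = 0, noise_sd = 0,
                    wander_amplitude = 0, seed = 5)
  ds <- generate_subject(cfg)
  expect_identical(ds$recordings[[1]][[1]]$samples,
                   ds$recordings[[2]][[1]]$samples)
  expect_identical(ds$recordings[[2]][[1]]$samples,
                   ds$recordings[[3]][[1]]$samples)
})

test_that("replicates of a round differ only by the noise realization", {
  cfg <- sim_config(n_rounds = 2, duration = 30, noise_sd = 0, seed = 3)
  ds <- generate_subject(cfg)
  expect_identical(ds$recordings[[1]][[1]]$samples,
                   ds$recordings[[1]][[2]]$samples)
  cfg2 <- sim_config(n_rounds = 2, duration = 30, noise_sd = 0.02, seed = 3)
  ds2 <- generate_subject(cfg2)
  expect_false(identical(ds2$recordings[[1]][[1]]$samples,
                         ds2$recordings[[1]][[2]]$samples))
})

test_that("wander energy sits below the band cutoff, beats above it", {
  fs <- 250
  cfg <- sim_config(n_rounds = 2, noise_sd = 0, heart_rate = 72, seed = 8)
  ds <- generate_subject(cfg)
  x <- ds$recordings[[1]][[1]]$samples
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  # wander component alone
  gt <- ds$ground_truth
  t <- (seq_len(n) - 1) / fs
  wander <- cfg$wander_amplitude *
    sin(2 * pi * cfg$wander_freq * t + gt$wander_phase[1])
  pw <- Mod(stats::fft(wander))^2
  low_mask <- freqs < 0.75 | freqs > fs - 0.75
  expect_gt(sum(pw[low_mask]) / sum(pw), 0.95)
  # beat fundamental of the pulse train exceeds the cutoff
  expect_gt(gt$heart_rate[1] / 60, 0.75)
})

test_that("glucose-width coupling moves FW_50 by the configured fraction", {
  cfg <- sim_config(n_rounds = 2, heart_rate = 70, noise_sd = 0,
                    drift_sd = 0, coupling_coefficient = 0.1,
                    bgl_trajectory = c(150, 250), seed = 7)
  ds <- generate_subject(cfg)
  f1 <- stats::median(window_vectors(ds$recordings[[1]][[1]])$vectors[, "fw_50"])
  f2 <- stats::median(window_vectors(ds$recordings[[2]][[1]])$vectors[, "fw_50"])
  expect_lt(abs(f2 / f1 - 1.1), 0.02)
})

test_that("generator rejects invalid configurations", {
  expect_error(sim_config(n_rounds = 1), "n_rounds")
  expect_error(sim_config(wander_freq = 0.8), "wander_freq")
  expect_error(sim_config(bgl_trajectory = c(10, 100), n_rounds = 2),
               "mg/dl")
  expect_error(sim_config(base_width = 0.95), "base_width")
})

test_that("subject datasets survive a CSV + manifest round trip", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_rounds = 2, duration = 30, seed = 12)
  ds <- generate_subject(cfg, subject_id = "RT")
  write_subject(ds, dir)
  back <- read_subject(dir)
  expect_equal(back$subject_id, "RT")
  expect_equal(length(back$recordings), 2)
  expect_equal(back$recordings[[2]][[1]]$reference_bgl,
               ds$recordings[[2]][[1]]$reference_bgl)
  expect_equal(back$recordings[[1]][[2]]$samples,
               ds$recordings[[1]][[2]]$samples, tolerance = 1e-12)
  expect_equal(back$ground_truth$width_fraction,
               ds$ground_truth$width_fraction, tolerance = 1e-12)
})
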