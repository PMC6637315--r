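test_that("synth_config rejects invalid worlds", {
  expect_error(synth_config(fs = 400), "Nyquist")
  expect_error(synth_config(duration_s = 0), "duration")
  expect_error(synth_config(activation_profile = numeric()), "non-empty")
  expect_error(synth_config(activation_profile = c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(synth_config(channel_gains = c(1, -1, 1, 1, 1)), ">= 0")
})

test_that("identical seed and config give bit-identical output", {
  a <- simulate_recording(tiny_cfg())
  b <- simulate_recording(tiny_cfg())
  expect_identical(a$recording$channels, b$recording$channels)
  expect_identical(a$ground_truth$breaths, b$ground_truth$breaths)
  expect_identical(a$ground_truth$r_peaks, b$ground_truth$r_peaks)
})

test_that("substreams are independent: noise level does not move the flow", {
  a <- simulate_recording(tiny_cfg(duration_s = 60))
  b <- simulate_recording(tiny_cfg(duration_s = 60, noise_sd = 0.01))
  expect_identical(a$recording$channels$flow, b$recording$channels$flow)
  expect_identical(a$recording$channels$ecg, b$recording$channels$ecg)
})

test_that("simulate_ecg beat count follows the rate integral", {
  ## constant 60 bpm for 60 s -> exactly 60 beats
  e <- simulate_ecg(60, fs = 500, duration_s = 60)
  expect_length(e$r_peaks, 60)

  ## ramp: count equals the integral of the rate within one beat
  e2 <- simulate_ecg(c(80, 124), fs = 500, duration_s = 120)
  expect_lte(abs(length(e2$r_peaks) - mean(c(80, 124)) / 60 * 120), 1.01)

  ## amplitude 0 -> flat zero; invalid rates rejected
  expect_true(all(simulate_ecg(60, 500, 10, amp = 0)$signal == 0))
  expect_error(simulate_ecg(0, 500, 10), "positive")
  expect_error(simulate_ecg(500 * 60, 500, 10), "resolvable")
})

test_that("no contamination and no noise reproduces clean_emg exactly", {
  cfg <- tiny_cfg(duration_s = 30, noise_sd = 0,
                  ecg_coupling = rep(list(0), 5))
  sim <- simulate_recording(cfg)
  for (c_ in 1:5) {
    expect_identical(sim$recording$channels[[paste0("emg_", c_)]],
                     sim$ground_truth$clean_emg[[c_]])
  }
})

test_that("heartbeats per inspiratory cycle tracks hr / breath-rate", {
  cfg <- synth_config(duration_s = 120, hr_bpm = 120, breath_rate_bpm = 30,
                      breath_jitter_sd = 0, rr_jitter_sd = 0,
                      activation_profile = c(0.3, 0.3), seed = 5)
  sim <- simulate_recording(cfg)
  expect_equal(heartbeats_per_breath(sim$ground_truth), 4, tolerance = 0.1)
})

test_that("channel amplitude profile: outer channels largest, middle smallest", {
  gt <- tiny_sim()$ground_truth
  r <- vapply(gt$clean_emg, sd, 0)
  expect_gt(r[[1L]], r[[2L]])
  expect_gt(r[[2L]], r[[3L]])
  expect_gt(r[[5L]], r[[4L]])
  expect_gt(r[[4L]], r[[3L]])
})

test_that("contamination adds power and stays band-separated", {
  sim <- tiny_sim()
  gt <- sim$ground_truth
  for (c_ in 1:5) {
    expect_gte(var(sim$recording$channels[[paste0("emg_", c_)]]),
               var(gt$clean_emg[[c_]]))
  }
  ## spectral content: clean EMG concentrated in 20-250 Hz,
  ## ECG concentrated below 100 Hz
  fs <- sim$recording$fs
  band_frac <- function(x, lo, hi) {
    p <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    f <- pmin(f, fs - f)
    sum(p[f >= lo & f <= hi]) / sum(p[f > 0])
  }
  expect_gt(band_frac(gt$clean_emg[[1L]], 20, 250), 0.95)
  expect_gt(band_frac(sim$recording$channels$ecg, 0.1, 100), 0.95)
})

test_that("ground-truth breath intervals are ordered, disjoint and half-open", {
  br <- tiny_sim()$ground_truth$breaths
  expect_true(all(br$insp_start_s < br$insp_end_s))
  expect_true(all(br$insp_end_s <= br$exp_end_s))
  expect_true(all(diff(br$insp_start_s) > 0))
  expect_true(all(head(br$exp_end_s, -1) <= br$insp_start_s[-1L] + 1e-9))
  ## every minute has at least one activation value
  gt <- tiny_sim()$ground_truth
  expect_true(all(seq_len(floor(max(br$exp_end_s) / 60)) %in%
                  gt$true_activation_per_minute$minute_index))
})

test_that("tidal mean inspiratory amplitude encodes the activation ratio", {
  ## noise- and artifact-free world: the per-breath mean of the true
  ## amplitude envelope divided by the IC mean must equal the configured
  ## activation (this is the calibration the analysis pipeline estimates)
  cfg <- tiny_cfg(duration_s = 90, noise_sd = 0,
                  ecg_coupling = rep(list(0), 5),
                  activation_profile = c(0.25, 0.6))
  sim <- simulate_recording(cfg)
  gt <- sim$ground_truth
  fs <- cfg$fs
  ## the calibrated quantity is the mean inspiratory AMPLITUDE (the mean
  ## of the running RMS envelope), not the inspiration-level RMS; estimate
  ## it from mean |x| of the unit-variance-carrier signal: E|Z| = sqrt(2/pi)
  env_mean <- function(br) {
    i <- seq.int(round(br$insp_start_s * fs) + 1, round(br$insp_end_s * fs))
    mean(abs(gt$clean_emg[[1L]][i])) / sqrt(2 / pi)
  }
  br <- gt$breaths
  ics <- br[br$is_ic, ]
  m_ic <- mean(vapply(seq_len(nrow(ics)), function(i) env_mean(ics[i, ]), 0))
  tid <- br[!br$is_ic & br$minute_index == 2, ]
  m_t <- mean(vapply(seq_len(nrow(tid)), function(i) env_mean(tid[i, ]), 0))
  expect_equal(m_t / m_ic, 0.6, tolerance = 0.05)
  expect_equal(gt$true_emgdimax[[1L]],
               cfg$emgdimax_v * gt$mean_ic_shape, tolerance = 1e-12)
})
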