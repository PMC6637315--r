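test_that("zero reference leaves the input untouched, bit exact", {
  set.seed(1)
  emg <- rnorm(5000)
  res <- lms_clean(emg, numeric(5000))
  expect_identical(res$cleaned, emg)
  expect_true(all(res$weights == 0))
})

test_that("cleaned + residual_estimate reconstructs the input exactly", {
  set.seed(2)
  emg <- rnorm(4000)
  ref <- rnorm(4000)
  res <- lms_clean(emg, ref, lms_config(standardize_ref = TRUE))
  expect_equal(res$cleaned + res$residual_estimate, emg, tolerance = 1e-14)
})

test_that("pure delayed-scaled reference converges to the Wiener impulse", {
  ## d(n) = 0.8 x(n - 10): the Wiener solution is exactly a 0.8 spike at
  ## lag 10; steady-state residual power must drop below 1 % of input
  set.seed(3)
  n <- 30000
  ref <- as.numeric(stats::filter(rnorm(n), rep(1, 3) / 3, sides = 1))
  ref[is.na(ref)] <- 0
  d <- 0.8 * c(rep(0, 10), head(ref, -10))
  res <- lms_clean(d, ref, lms_config(filter_length = 70, step_size = 0.01,
                                      standardize_ref = TRUE))
  tail_idx <- seq.int(n - 5000, n)
  expect_lt(mean(res$cleaned[tail_idx]^2), 0.01 * mean(d[tail_idx]^2))
  w <- res$weights
  expect_equal(which.max(abs(w)), 11L)       # lag 10, 1-based
  ## weights are in standardized-reference units: scale back
  expect_equal(w[[11L]] * 1 / sd(ref), 0.8, tolerance = 0.1)
  expect_lt(max(abs(w[-11L])) / abs(w[[11L]]), 0.35)
})

test_that("clean_recording touches only EMG channels and is deterministic", {
  sim <- tiny_sim_1k()
  rec <- sim$recording
  a <- clean_recording(rec)
  b <- clean_recording(rec)
  expect_identical(a$channels$flow, rec$channels$flow)
  expect_identical(a$channels$ecg, rec$channels$ecg)
  expect_identical(a$channels$emg_1, b$channels$emg_1)   # no randomness
  expect_false(identical(a$channels$emg_1, rec$channels$emg_1))
  expect_length(attr(a, "lms_results"), 5L)
  expect_match(attr(a, "provenance"), "L=70 mu=0.01")

  expect_error(clean_recording(recording(list(emg_1 = 1:10), fs = 10)),
               "ecg")
  expect_error(
    clean_recording(recording(list(ecg = rnorm(10), flow = rnorm(10)),
                              fs = 10)),
    "no emg")
})

test_that("all-zero EMG input stays at zero", {
  set.seed(4)
  res <- lms_clean(numeric(8000), rnorm(8000))
  expect_lt(mean(tail(res$cleaned, 2000)^2), 1e-10)
})

test_that("divergence guard names the step size", {
  set.seed(5)
  ref <- 100 * rnorm(5000)
  expect_error(lms_clean(rnorm(5000), ref,
                         lms_config(step_size = 1)),
               "step_size")
})

test_that("stability: the white-input bound fails for an impulsive reference", {
  ## The mean-power stability bound mu < 2 / (L * var) = 0.029 suggests
  ## mu = 0.01 is safe on a unit-variance reference -- but an ECG is
  ## impulsive: the instantaneous 70-tap energy of the standardized
  ## reference exceeds 2/mu during QRS bursts, and plain LMS genuinely
  ## diverges.  The divergence guard must catch it; the raw-volt default
  ## and the power-normalised update must both stay stable.
  sim <- tiny_sim_1k()
  rec <- sim$recording
  x <- rec$channels$emg_1; ref <- rec$channels$ecg

  s <- (ref - mean(ref)) / sd(ref)
  e70 <- as.numeric(stats::filter(s^2, rep(1, 70), sides = 1))
  expect_gt(max(e70, na.rm = TRUE), 2 / 0.01)   # bound violated in bursts
  expect_error(lms_clean(x, ref, lms_config(standardize_ref = TRUE)),
               "diverged")

  raw <- lms_clean(x, ref)
  expect_true(all(is.finite(raw$cleaned)))
  nlms <- lms_clean(x, ref, lms_config(standardize_ref = TRUE,
                                       normalized = TRUE))
  expect_true(all(is.finite(nlms$cleaned)))
})

expiratory_attenuation_db <- function(rec, cleaned, breaths, skip_s = 30) {
  fs <- rec$fs
  n <- n_samples(rec)
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(breaths))) {
    i0 <- round(breaths$insp_end_s[[i]] * fs) + 1L
    i1 <- min(round(breaths$exp_end_s[[i]] * fs), n)
    if (i1 > i0) mask[i0:i1] <- TRUE
  }
  mask[seq_len(min(n, round(skip_s * fs)))] <- FALSE
  10 * log10(mean(rec$channels$emg_1[mask]^2) /
             mean(cleaned$channels$emg_1[mask]^2))
}

test_that("artifact removal keeps tracking through a heart-rate ramp", {
  ## ramped vs constant heart rate: final-minute expiratory attenuation
  ## within 6 dB of each other (the coupling path, not the rhythm, is
  ## what the filter estimates)
  att_final <- function(hr) {
    sim <- simulate_recording(tiny_cfg(duration_s = 150, hr_bpm = hr))
    rec <- resample_recording(sim$recording, 1000)
    cln <- clean_recording(rec)
    br <- sim$ground_truth$breaths
    expiratory_attenuation_db(rec, cln, br, skip_s = 90)
  }
  a_ramp <- att_final(c(80, 124))
  a_const <- att_final(100)
  expect_gt(a_ramp, 20)
  expect_lt(abs(a_ramp - a_const), 6)
})
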