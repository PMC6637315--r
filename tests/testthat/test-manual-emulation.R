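test_that("detect_qrs finds a clean 60 bpm train and nothing in silence", {
  fs <- 1000
  e <- simulate_ecg(60, fs, 60)
  q <- detect_qrs(e$signal, fs)
  expect_length(q$r_peaks, 60)
  expect_lt(max(abs((q$r_peaks - 1) / fs - e$beat_times_s)), 0.010)

  q0 <- detect_qrs(numeric(10000), fs)
  expect_length(q0$r_peaks, 0L)
})

test_that("detect_qrs matches ground truth through a heart-rate ramp", {
  sim <- tiny_sim_1k()
  gt <- sim$ground_truth
  q <- detect_qrs(sim$recording$channels$ecg, 1000)
  expect_equal(length(q$r_peaks), length(gt$r_peaks))
  match_err <- vapply(gt$r_peak_times_s, function(tt) {
    min(abs((q$r_peaks - 1) / 1000 - tt))
  }, 0)
  expect_lt(max(match_err), 0.010)
})

test_that("clean-interval enumeration partitions the inspiration", {
  fs <- 1000
  br <- fake_breaths(1001, 2001, 3001, fs)[1, ]  # 1 s inspiration
  env <- rep(0.1, 3500)
  no_qrs <- structure(list(r_peaks = integer(),
                           blanked = matrix(integer(), 0, 2)),
                      class = "qrs_annotation")
  iv <- enumerate_clean_intervals(br, no_qrs, env, fs)
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$start, iv$end), c(1001L, 2001L))

  ## 4 disjoint blanking windows strictly inside -> 5 intervals
  ## (about four heartbeats in one inspiration)
  bl <- cbind(c(1150, 1350, 1550, 1750), c(1250, 1450, 1650, 1850))
  qrs <- structure(list(r_peaks = rowMeans(bl), blanked = bl),
                   class = "qrs_annotation")
  iv4 <- enumerate_clean_intervals(br, qrs, env, fs)
  expect_equal(nrow(iv4), 5L)
  expect_true(all(iv4$mean_rms == 0.1))

  ## blanking covering the whole inspiration -> empty
  all_bl <- structure(list(r_peaks = 1500,
                           blanked = cbind(500L, 2500L)),
                      class = "qrs_annotation")
  expect_equal(nrow(enumerate_clean_intervals(br, all_bl, env, fs)), 0L)
})

test_that("interval selection strategies and tie-breaks", {
  iv <- data.frame(start = c(100L, 300L, 600L), end = c(200L, 500L, 700L),
                   width_s = c(0.1, 0.2, 0.1), mean_rms = c(0.1, 0.1, 0.3))
  expect_equal(select_interval(iv, "highest")$start, 600L)
  expect_equal(select_interval(iv, "widest")$start, 300L)

  ## equal means -> highest picks the later; equal widths -> widest the
  ## earlier
  tie <- data.frame(start = c(100L, 600L), end = c(200L, 700L),
                    width_s = c(0.1, 0.1), mean_rms = c(0.2, 0.2))
  expect_equal(select_interval(tie, "highest")$start, 600L)
  expect_equal(select_interval(tie, "widest")$start, 100L)

  expect_error(select_interval(iv[0, ], "highest"), "no selectable")
})

test_that("optimality invariants hold on simulated breaths", {
  sim <- tiny_sim_1k()
  rec <- sim$recording
  env <- rms_envelope(highpass(rec$channels$emg_1, rec$fs), rec$fs, 0.05)
  qrs <- detect_qrs(rec$channels$ecg, rec$fs)
  br <- segment_breaths(rec)
  n_checked <- 0L
  for (i in seq_len(nrow(br))) {
    iv <- enumerate_clean_intervals(br[i, ], qrs, env, rec$fs)
    if (nrow(iv) < 2L) next
    hi <- select_interval(iv, "highest")
    wi <- select_interval(iv, "widest")
    expect_gte(wi$width_s, hi$width_s)
    expect_gte(hi$mean_rms, wi$mean_rms)
    ## selected intervals never overlap a blanked region
    overlaps <- qrs$blanked[, 1L] < hi$end & qrs$blanked[, 2L] > hi$start
    expect_false(any(overlaps))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 20L)
})

test_that("short inspirations leave fewer intervals; one interval => no choice", {
  fs <- 1000
  env <- rep(0.1, 20000)
  qrs <- structure(list(r_peaks = seq(500, 19500, by = 500),
                        blanked = cbind(seq(440L, 19440, by = 500),
                                        seq(600L, 19600, by = 500))),
                   class = "qrs_annotation")
  long_br <- fake_breaths(1001, 2501, 4001, fs)[1, ]     # 1.5 s Ti
  short_br <- fake_breaths(1001, 1401, 2001, fs)[1, ]    # 0.4 s Ti
  iv_long <- enumerate_clean_intervals(long_br, qrs, env, fs)
  iv_short <- enumerate_clean_intervals(short_br, qrs, env, fs)
  expect_gt(nrow(iv_long), nrow(iv_short))
  if (nrow(iv_short) == 1L) {
    expect_identical(select_interval(iv_short, "highest"),
                     select_interval(iv_short, "widest"))
  }
})

test_that("flat-envelope minutes: the estimate equals the true level ratio", {
  fs <- 1000
  n <- 70000
  env <- numeric(n)
  starts <- seq(1001, 58001, by = 3000)
  br <- fake_breaths(starts, starts + 999, starts + 2999, fs)
  ## IC breath with level 0.2, tidal breaths at 0.1 -> 50 % exactly
  br$is_ic[[1L]] <- TRUE
  for (i in seq_len(nrow(br))) {
    env[br$insp_start[[i]]:(br$insp_end[[i]] - 1L)] <-
      if (br$is_ic[[i]]) 0.2 else 0.1
  }
  qrs <- structure(list(r_peaks = seq(500, n - 500, by = 700),
                        blanked = cbind(seq(440L, n - 560, by = 700),
                                        seq(600L, n - 400, by = 700))),
                   class = "qrs_annotation")
  for (strat in c("highest", "widest")) {
    res <- manual_minute_estimate(br, env, qrs, fs, strategy = strat)
    expect_equal(res$minutes$emgdi_pct, 50, tolerance = 1e-10)
  }
})

test_that("late-peak envelopes produce the highest > widest rater bias", {
  sim <- cached_sim("late240", function() {
    s <- simulate_recording(synth_config(duration_s = 240,
                                         activation_profile = c(.3, .4, .5, .5),
                                         ic_schedule = c(25, 145),
                                         seed = 42L))
    list(recording = resample_recording(s$recording, 1000),
         ground_truth = s$ground_truth)
  })
  rec <- sim$recording
  hi <- analyze_manual(rec, strategy = "highest", channel = "emg_1")
  wi <- analyze_manual(rec, strategy = "widest", channel = "emg_1")
  expect_gt(mean(hi$minutes$emgdi_pct), mean(wi$minutes$emgdi_pct))
  ## audited cursor positions never touch blanked samples
  expect_true(all(hi$audit$end_s > hi$audit$start_s))
})
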