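#' Configuration for the synthetic recording generator
#'
#' Describes a constant-work-rate-style test: a resting phase, then loaded
#' breathing with ramping heart rate, breathing frequency and diaphragm
#' activation, plus scheduled inspiratory-capacity (IC) maneuvers.  The
#' defaults are anchored to typical COPD endurance-cycling values: heart
#' rate 80 -> 124 bpm, breathing frequency 22 -> 32 breaths/min (about four
#' heartbeats per breath throughout), maximal-activation EMG amplitude
#' 0.15 V, EMG band 20-250 Hz, outer EMG channels largest and the middle
#' channel smallest.
#'
#' The per-minute `activation_profile` is defined as the true ratio of mean
#' inspiratory activation of tidal breaths to mean inspiratory activation
#' of an IC maneuver (the quantity the EMGdi/EMGdiMax% pipeline estimates);
#' IC maneuvers have activation 1 by construction.
#'
#' @param duration_s total duration (s)
#' @param fs generation sampling rate (Hz); must exceed `2 * emg_band[2]`
#' @param breath_rate_bpm breaths/min; scalar or `c(start, end)` ramp
#' @param hr_bpm heart rate in bpm; scalar or `c(start, end)` ramp.  If
#'   `NULL`, derived as `hb_per_insp_target * breath_rate_bpm`.
#' @param hb_per_insp_target heartbeats per breath cycle used only when
#'   `hr_bpm` is `NULL` (default 4, the typical exercise ratio)
#' @param ti_frac inspiratory fraction of the breath period
#' @param envelope_shape `"flat"`, `"late_peak"` or `"early_peak"`;
#'   intra-breath activation envelope of tidal breaths.  `late_peak`
#'   reproduces the untrained pattern (activation grows toward
#'   end-inspiration); `flat` the post-training pattern.
#' @param envelope_peak peak position in (0, 1) for the peaked shapes
#'   (default 0.8 for `late_peak`, 0.25 for `early_peak`)
#' @param channel_gains five relative EMG channel amplitudes
#' @param emgdimax_v peak IC activation amplitude (volts) of a gain-1
#'   channel; sets the absolute EMG scale
#' @param ecg_amp R-peak amplitude (volts) of the ECG reference channel
#' @param ecg_coupling list of five FIR kernels mixing the reference ECG
#'   into each EMG channel; `NULL` uses channel-specific scaled, delayed,
#'   smoothed impulses giving artifact peaks near 0.06-0.09 V
#' @param emg_band EMG carrier band (Hz)
#' @param noise_sd white instrumentation noise (volts)
#' @param activation_profile per-minute true activation ratios in (0, 1]
#' @param tidal_flow_peak peak inspiratory flow (L/s); scalar or ramp
#' @param ic_schedule times (s) at which IC maneuvers are inserted
#' @param ic_flow_factor IC inspiratory flow amplitude relative to tidal
#' @param ic_ti_factor IC inspiratory time relative to tidal Ti (< 1:
#'   fast maximal inspirations are shorter than tidal breaths)
#' @param breath_jitter_sd relative SD of breath-period variability
#' @param rr_jitter_sd SD (s) of beat-time variability
#' @param seed master seed; expanded into fixed per-component substreams
#' @return list of class `synth_config`
#' @export
synth_config <- function(duration_s = 480, fs = 2000,
                         breath_rate_bpm = c(22, 32), hr_bpm = c(80, 124),
                         hb_per_insp_target = 4, ti_frac = 0.40,
                         envelope_shape = c("late_peak", "flat", "early_peak"),
                         envelope_peak = NULL,
                         channel_gains = c(1, 0.7, 0.3, 0.7, 1),
                         emgdimax_v = 0.15, ecg_amp = 0.5,
                         ecg_coupling = NULL, emg_band = c(20, 250),
                         noise_sd = 0.001,
                         activation_profile = c(0.15, 0.15, 0.15, 0.35,
                                                0.50, 0.55, 0.60, 0.60),
                         tidal_flow_peak = c(0.5, 1.1),
                         ic_schedule = c(55, 115, 175, 295, 415),
                         ic_flow_factor = 2.8, ic_ti_factor = 0.9,
                         breath_jitter_sd = 0.03, rr_jitter_sd = 0.01,
                         seed = 1L) {
  envelope_shape <- match.arg(envelope_shape)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs <= 2 * emg_band[[2L]]) {
    stop("fs must exceed 2 * emg_band upper edge (Nyquist)")
  }
  if (any(channel_gains < 0)) stop("channel gains must be >= 0")
  if (!length(activation_profile)) stop("activation_profile must be non-empty")
  if (any(activation_profile <= 0 | activation_profile > 1)) {
    stop("activation_profile values must lie in (0, 1]")
  }
  if (is.null(hr_bpm)) hr_bpm <- hb_per_insp_target * breath_rate_bpm
  if (is.null(envelope_peak)) {
    envelope_peak <- switch(envelope_shape, late_peak = 0.8,
                            early_peak = 0.25, flat = NA_real_)
  }
  if (is.null(ecg_coupling)) {
    base <- 0.26 * c(1, 0.85, 0.7, 0.85, 1)
    delay_ms <- c(2, 3, 4, 5, 6)
    ecg_coupling <- lapply(1:5, function(c_) {
      c(rep(0, round(delay_ms[[c_]] * fs / 1000)),
        base[[c_]] * c(0.2, 0.6, 0.2))
    })
  }
  ic_schedule <- ic_schedule[ic_schedule < duration_s]
  structure(list(duration_s = duration_s, fs = fs,
                 breath_rate_bpm = breath_rate_bpm, hr_bpm = hr_bpm,
                 hb_per_insp_target = hb_per_insp_target, ti_frac = ti_frac,
                 envelope_shape = envelope_shape,
                 envelope_peak = envelope_peak,
                 channel_gains = channel_gains, emgdimax_v = emgdimax_v,
                 ecg_amp = ecg_amp, ecg_coupling = ecg_coupling,
                 emg_band = emg_band, noise_sd = noise_sd,
                 activation_profile = activation_profile,
                 tidal_flow_peak = tidal_flow_peak,
                 ic_schedule = ic_schedule,
                 ic_flow_factor = ic_flow_factor,
                 ic_ti_factor = ic_ti_factor,
                 breath_jitter_sd = breath_jitter_sd,
                 rr_jitter_sd = rr_jitter_sd, seed = as.integer(seed)),
            class = "synth_config")
}

## fixed substream slots so adding a component never perturbs the others
synth_seeds <- function(seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 16L)
}

ramp_at <- function(value, t, duration) {
  if (length(value) == 1L) return(rep(value, length(t)))
  value[[1L]] + (value[[2L]] - value[[1L]]) * pmin(pmax(t / duration, 0), 1)
}

## intra-breath envelope shapes on u in [0,1), peak normalised to 1
envelope_shape_fun <- function(shape, peak) {
  switch(shape,
    flat = function(u) {
      r <- 0.15
      ifelse(u < r, 0.5 * (1 - cos(pi * u / r)),
             ifelse(u > 1 - r, 0.5 * (1 - cos(pi * (1 - u) / r)), 1))
    },
    late_peak = ,
    early_peak = function(u) {
      ifelse(u <= peak, 0.5 * (1 - cos(pi * u / peak)),
             0.5 * (1 + cos(pi * (u - peak) / (1 - peak))))
    })
}

ic_shape_fun <- envelope_shape_fun("flat", NA)

#' Synthetic ECG signal
#'
#' A train of fixed-morphology beats (Gaussian Q/R/S lobes plus smaller P
#' and T waves, dominant energy well below 100 Hz) at an instantaneous rate
#' given by `hr_bpm`.  Beat times are found by integrating the rate profile
#' and locating integer crossings of the accumulated phase.
#'
#' @param hr_bpm heart rate: scalar, `c(start, end)` linear ramp, or a
#'   per-sample vector of length `duration_s * fs`
#' @param fs sampling rate (Hz)
#' @param duration_s duration (s)
#' @param amp R-peak amplitude (volts); 0 gives a flat zero signal
#' @param rr_jitter_sd SD (s) of Gaussian beat-time jitter
#' @param seed RNG seed for the jitter
#' @return list with `signal` (numeric vector), `r_peaks` (sample indices
#'   of R waves) and `beat_times_s`
#' @export
simulate_ecg <- function(hr_bpm, fs, duration_s, amp = 1,
                         rr_jitter_sd = 0, seed = 1L) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  hr <- if (length(hr_bpm) == n) hr_bpm else ramp_at(hr_bpm, t, duration_s)
  if (any(hr <= 0)) stop("heart rate must be positive everywhere")
  if (max(hr) / 60 > fs / 2) stop("heart rate not resolvable at this fs")
  phase <- cumsum(hr / 60) / fs          # beats elapsed
  phase <- phase - phase[[1L]]           # first beat exactly at t = 0
  k <- seq.int(0L, floor(phase[[n]]))
  beat_times <- approx(phase, t, xout = k, ties = "ordered")$y
  if (rr_jitter_sd > 0) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    set.seed(seed)
    beat_times <- beat_times + rnorm(length(beat_times), 0, rr_jitter_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    beat_times <- sort(beat_times)
  }
  beat_times <- beat_times[beat_times >= 0 & beat_times < duration_s]
  sig <- numeric(n)
  if (amp > 0 && length(beat_times)) {
    tpl_t <- seq(-0.30, 0.40, by = 1 / fs)
    g <- function(mu, s) exp(-(tpl_t - mu)^2 / (2 * s^2))
    ## sharp QRS lobes (R sigma 8 ms: substantial 20-60 Hz energy, so the
    ## artifact genuinely survives a 20 Hz high-pass, as in real
    ## recordings), smoother P and T deflections
    tpl <- amp * (g(0, 0.008) - 0.30 * g(0.028, 0.010) -
                  0.20 * g(-0.028, 0.010) + 0.15 * g(-0.18, 0.020) +
                  0.25 * g(0.22, 0.035))
    off <- round(-0.30 * fs)
    for (bt in beat_times) {
      i0 <- round(bt * fs) + off + 1L
      idx <- seq.int(i0, i0 + length(tpl) - 1L)
      ok <- idx >= 1L & idx <= n
      sig[idx[ok]] <- sig[idx[ok]] + tpl[ok]
    }
  }
  list(signal = sig, r_peaks = round(beat_times * fs) + 1L,
       beat_times_s = beat_times)
}

## unit-variance band-limited Gaussian noise via FFT masking
band_noise <- function(n, fs, band, seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  x <- rnorm(n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  mask <- as.numeric(f >= band[[1L]] & f <= band[[2L]])
  y <- Re(fft(fft(x) * mask, inverse = TRUE)) / n
  y / sd(y)
}

build_breath_plan <- function(cfg) {
  seeds <- synth_seeds(cfg$seed)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seeds[[12L]])
  ic_pending <- cfg$ic_schedule
  rows <- list()
  t <- 0.5  # settle time before the first breath
  while (TRUE) {
    rate <- ramp_at(cfg$breath_rate_bpm, t, cfg$duration_s)
    period <- 60 / rate
    if (cfg$breath_jitter_sd > 0) {
      period <- period * exp(rnorm(1, 0, cfg$breath_jitter_sd))
    }
    is_ic <- length(ic_pending) && ic_pending[[1L]] < t + period
    if (is_ic) ic_pending <- ic_pending[-1L]
    amp <- ramp_at(cfg$tidal_flow_peak, t, cfg$duration_s)
    ti <- cfg$ti_frac * period
    if (is_ic) {
      ti <- cfg$ic_ti_factor * ti
      amp <- cfg$ic_flow_factor * amp
    }
    if (t + period > cfg$duration_s - 0.25) break
    minute <- floor(t / 60) + 1
    act <- if (is_ic) 1 else
      cfg$activation_profile[[min(minute, length(cfg$activation_profile))]]
    rows[[length(rows) + 1L]] <- data.frame(
      insp_start_s = t, insp_end_s = t + ti, exp_end_s = t + period,
      flow_amp = amp, is_ic = is_ic, minute_index = minute,
      activation = act)
    t <- t + period
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  do.call(rbind, rows)
}

#' Simulate a ground-truth multi-channel recording
#'
#' Builds a seven-channel recording (five EMG channels, one ECG reference,
#' one flow channel) plus the ground truth needed to validate every
#' downstream step.  Construction, per channel `c`:
#' `emg_c = gain_c * A(t) * carrier_c(t) + (coupling_c * ecg)(t) + noise`,
#' where `A(t)` is the inspiratory activation envelope (zero during
#' expiration), `carrier_c` is unit-variance band-limited Gaussian noise,
#' and `coupling_c` is a channel-specific FIR kernel applied to the
#' reference ECG.  Flow is a smooth biphasic waveform with negative
#' (inspiratory) half-sine lobes; expiratory lobes return the inspired
#' volume.  Tidal envelopes are scaled so that the ratio of their mean
#' inspiratory amplitude to the IC mean inspiratory amplitude equals the
#' configured per-minute activation exactly.
#'
#' @param cfg a [synth_config()]
#' @return list with elements `recording` (an `emgdi_recording`) and
#'   `ground_truth`, a list holding `breaths` (data frame of true breath
#'   intervals, IC flags and activations), `r_peaks` / `r_peak_times_s`,
#'   `clean_emg` and `artifact` (per-channel component signals),
#'   `true_activation_per_minute` (data frame `minute_index`,
#'   `activation_pct`) and `true_emgdimax` (per channel, volts; the mean
#'   inspiratory IC amplitude, with the peak amplitude in
#'   `true_emgdimax_peak`)
#' @export
simulate_recording <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  seeds <- synth_seeds(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  breaths <- build_breath_plan(cfg)

  ## ---- flow and activation envelope -------------------------------------
  flow <- numeric(n)
  A <- numeric(n)          # scalar activation envelope (gain-1 channel)
  shape_f <- envelope_shape_fun(cfg$envelope_shape, cfg$envelope_peak)
  ## mean of the IC envelope shape: the normalisation anchor
  u_ref <- (seq_len(1000) - 0.5) / 1000
  m_ic <- mean(ic_shape_fun(u_ref))
  m_tidal <- mean(shape_f(u_ref))
  for (b in seq_len(nrow(breaths))) {
    br <- breaths[b, ]
    i0 <- round(br$insp_start_s * cfg$fs) + 1L
    i1 <- round(br$insp_end_s * cfg$fs)
    i2 <- min(round(br$exp_end_s * cfg$fs), n)
    insp <- seq.int(i0, i1)
    u <- (insp - i0 + 0.5) / length(insp)
    flow[insp] <- -br$flow_amp * sin(pi * u)
    vol <- br$flow_amp * (2 / pi) * (length(insp) / cfg$fs)
    if (i2 > i1 + 1L) {
      ex <- seq.int(i1 + 1L, i2)
      v <- (ex - i1 - 0.5) / length(ex)
      amp_e <- vol * pi / (2 * (length(ex) / cfg$fs))
      flow[ex] <- amp_e * sin(pi * v)
    }
    if (br$is_ic) {
      A[insp] <- cfg$emgdimax_v * ic_shape_fun(u)
    } else {
      k <- cfg$emgdimax_v * br$activation * m_ic / m_tidal
      A[insp] <- k * shape_f(u)
    }
  }

  ## ---- ECG reference and coupling ---------------------------------------
  ecg <- simulate_ecg(cfg$hr_bpm, cfg$fs, cfg$duration_s, amp = cfg$ecg_amp,
                      rr_jitter_sd = cfg$rr_jitter_sd, seed = seeds[[1L]])
  artifact <- lapply(1:5, function(c_) {
    kern <- cfg$ecg_coupling[[c_]]
    if (!length(kern) || all(kern == 0)) return(numeric(n))
    iir_filter_cpp(kern, c(1, rep(0, length(kern) - 1L)), ecg$signal,
                   numeric(max(length(kern) - 1L, 1L)))
  })

  ## ---- EMG channels ------------------------------------------------------
  clean <- vector("list", 5L)
  channels <- list()
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  for (c_ in 1:5) {
    carrier <- band_noise(n, cfg$fs, cfg$emg_band, seeds[[1L + c_]])
    clean[[c_]] <- cfg$channel_gains[[c_]] * A * carrier
    set.seed(seeds[[6L + c_]])
    wn <- if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else numeric(n)
    channels[[paste0("emg_", c_)]] <- clean[[c_]] + artifact[[c_]] + wn
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  channels$ecg <- ecg$signal
  channels$flow <- flow

  ## ---- markers ------------------------------------------------------------
  ic_rows <- breaths[breaths$is_ic, ]
  markers <- data.frame(
    time_s = c(0, pmin((ic_rows$insp_start_s + ic_rows$insp_end_s) / 2,
                       cfg$duration_s), cfg$duration_s),
    label = c("rest_start", rep("ic_maneuver", nrow(ic_rows)), "test_end"))
  markers <- markers[order(markers$time_s), ]
  rec <- recording(channels, fs = cfg$fs, markers = markers)

  ## ---- ground truth --------------------------------------------------------
  tidal <- breaths[!breaths$is_ic, ]
  per_min <- stats::aggregate(activation ~ minute_index, data = tidal, mean)
  gt <- list(
    breaths = breaths,
    r_peaks = ecg$r_peaks,
    r_peak_times_s = ecg$beat_times_s,
    clean_emg = clean,
    artifact = artifact,
    true_activation_per_minute = data.frame(
      minute_index = per_min$minute_index,
      activation_pct = 100 * per_min$activation),
    true_emgdimax = cfg$emgdimax_v * cfg$channel_gains * m_ic,
    true_emgdimax_peak = cfg$emgdimax_v * cfg$channel_gains,
    mean_ic_shape = m_ic,
    config = cfg)
  list(recording = rec, ground_truth = gt)
}

#' Mean number of heartbeats per breath cycle in a simulated ground truth
#' @param gt the `ground_truth` element returned by [simulate_recording()]
#' @return average count of R peaks falling inside each full breath cycle
#' @export
heartbeats_per_breath <- function(gt) {
  br <- gt$breaths
  counts <- vapply(seq_len(nrow(br)), function(i) {
    sum(gt$r_peak_times_s >= br$insp_start_s[[i]] &
        gt$r_peak_times_s < br$exp_end_s[[i]])
  }, 0)
  mean(counts)
}
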