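#' Per-breath mean and peak RMS amplitude
#'
#' The semi-automated per-breath statistic: the mean (and peak) of the RMS
#' envelope over the inspiratory samples `[insp_start, insp_end)`.
#'
#' @param envelope RMS envelope ([rms_envelope()]) of one channel
#' @param breath a single-row slice of an `emgdi_breaths` data frame
#' @param method tag recorded with the value
#' @return data.frame with `breath_id`, `mean_rms`, `peak_rms`, `method`
#' @export
breath_mean_rms <- function(envelope, breath,
                            method = c("semi_auto", "manual_highest",
                                       "manual_widest")) {
  method <- match.arg(method)
  if (breath$insp_end <= breath$insp_start) {
    stop("empty inspiratory interval for breath ", breath$breath_id)
  }
  idx <- seq.int(breath$insp_start, breath$insp_end - 1L)
  e <- envelope[idx]
  data.frame(breath_id = breath$breath_id, mean_rms = mean(e),
             peak_rms = max(e), method = method)
}

#' Per-breath RMS table for every breath in a segmentation
#'
#' Vectorised form of [breath_mean_rms()].
#'
#' @param envelope RMS envelope of one channel
#' @param breaths an `emgdi_breaths` data frame
#' @param method tag recorded with the values
#' @return data.frame with one row per breath
#' @export
breath_table_rms <- function(envelope, breaths, method = "semi_auto") {
  do.call(rbind, lapply(seq_len(nrow(breaths)), function(i) {
    breath_mean_rms(envelope, breaths[i, ], method = method)
  }))
}

#' Maximal diaphragm activation (EMGdiMax)
#'
#' The normalisation denominator, taken from the recorded IC maneuvers.
#' Two statistics are offered.  `"mean"` (the default) takes, per IC
#' inspiration and channel, the mean RMS over the inspiration and returns
#' the largest such value: it matches the per-breath statistic that it
#' normalises and is robust to stochastic excursions of the smoothed RMS
#' trace.  `"peak"` returns the largest single RMS envelope value reached
#' during any IC inspiration (the literal largest-amplitude reading); it
#' is noisier because the maximum of a windowed RMS estimate has a
#' positive bias that grows with the number of windows searched.
#'
#' @param ic_breaths rows of an `emgdi_breaths` data frame with
#'   `is_ic == TRUE`
#' @param envelopes_by_channel named list of RMS envelopes, one per channel
#' @param stat `"mean"` or `"peak"`
#' @return list with `emgdimax` (volts), `channel`, `breath_id`
#' @export
compute_emgdimax <- function(ic_breaths, envelopes_by_channel,
                             stat = c("mean", "peak")) {
  stat <- match.arg(stat)
  if (!nrow(ic_breaths)) {
    stop("no IC maneuvers found: supply ic_maneuver markers or enable ",
         "volume-threshold IC detection")
  }
  best <- list(value = -Inf)
  for (ch in names(envelopes_by_channel)) {
    env <- envelopes_by_channel[[ch]]
    for (i in seq_len(nrow(ic_breaths))) {
      idx <- seq.int(ic_breaths$insp_start[[i]], ic_breaths$insp_end[[i]] - 1L)
      v <- if (stat == "mean") mean(env[idx]) else max(env[idx])
      if (v > best$value) {
        best <- list(value = v, channel = ch,
                     breath_id = ic_breaths$breath_id[[i]])
      }
    }
  }
  list(emgdimax = best$value, channel = best$channel,
       breath_id = best$breath_id)
}

#' Select the reporting channel
#'
#' The channel that on average contains the largest EMG signal during IC
#' maneuvers (for a correctly positioned catheter, an outer channel).  The
#' per-IC statistic follows [compute_emgdimax()]'s `stat`; ties go to the
#' lowest channel index.
#'
#' @inheritParams compute_emgdimax
#' @return the selected channel name
#' @export
select_reporting_channel <- function(ic_breaths, envelopes_by_channel,
                                     stat = c("mean", "peak")) {
  stat <- match.arg(stat)
  if (!nrow(ic_breaths)) stop("no IC maneuvers found")
  score <- vapply(envelopes_by_channel, function(env) {
    mean(vapply(seq_len(nrow(ic_breaths)), function(i) {
      idx <- seq.int(ic_breaths$insp_start[[i]],
                     ic_breaths$insp_end[[i]] - 1L)
      if (stat == "mean") mean(env[idx]) else max(env[idx])
    }, 0))
  }, 0)
  names(envelopes_by_channel)[[which.max(score)]]  # which.max: first = lowest
}

#' Per-minute activation summary
#'
#' Averages the per-breath mean RMS of every usable (quality `"ok"`,
#' non-IC) breath in each minute and normalises by EMGdiMax, yielding
#' per-minute EMGdi/EMGdiMax%.  Minutes with no usable tidal breath are
#' reported as missing (dropped), never as zero.
#'
#' @param breaths an `emgdi_breaths` data frame with minutes assigned
#' @param activations per-breath table from [breath_mean_rms()] /
#'   [breath_table_rms()] for the reporting channel
#' @param emgdimax normalisation denominator (volts)
#' @return data.frame `minute_index`, `emgdi_pct`, `n_breaths_used`
#' @export
minute_summary <- function(breaths, activations, emgdimax) {
  if (emgdimax <= 0) stop("emgdimax must be positive")
  merged <- merge(breaths, activations, by = "breath_id")
  usable <- merged[!merged$is_ic & merged$quality == "ok" &
                   merged$minute_index > 0, ]
  if (!nrow(usable)) {
    return(data.frame(minute_index = integer(), emgdi_pct = numeric(),
                      n_breaths_used = integer()))
  }
  agg <- stats::aggregate(mean_rms ~ minute_index, data = usable, mean)
  cnt <- stats::aggregate(mean_rms ~ minute_index, data = usable, length)
  data.frame(minute_index = agg$minute_index,
             emgdi_pct = 100 * agg$mean_rms / emgdimax,
             n_breaths_used = cnt$mean_rms)
}

#' Semi-automated analysis of a recording
#'
#' The full semi-automated path: LMS ECG cancellation on the raw EMG
#' channels against the ECG reference, 20 Hz high-pass, RMS envelope,
#' breath segmentation from zero-flow points, IC identification, reporting
#' channel and EMGdiMax from the IC maneuvers, per-breath mean inspiratory
#' RMS of every tidal breath, and per-minute EMGdi/EMGdiMax%.
#'
#' @param rec an `emgdi_recording` (emg_1..5, ecg, flow)
#' @param lms an [lms_config()]; `NULL` skips cancellation (for comparing
#'   the uncleaned path against ground truth)
#' @param highpass_hz high-pass cutoff (Hz)
#' @param rms_window_s RMS window (s)
#' @param emgdimax_stat statistic for [compute_emgdimax()]
#' @param channel fixed reporting channel name, or `NULL` to select from
#'   the IC maneuvers
#' @param ... passed to [detect_breaths()]
#' @return list of class `emgdi_analysis`: `minutes` (per-minute summary),
#'   `breaths`, `breath_activations`, `emgdimax`, `reporting_channel`,
#'   `envelopes`
#' @export
analyze_semiauto <- function(rec, lms = lms_config(), highpass_hz = 20,
                             rms_window_s = 0.05,
                             emgdimax_stat = c("mean", "peak"),
                             channel = NULL, ...) {
  emgdimax_stat <- match.arg(emgdimax_stat)
  if (!is.null(lms)) rec <- clean_recording(rec, lms)
  emg_names <- emg_channel_names(rec)
  envelopes <- lapply(setNames(emg_names, emg_names), function(nm) {
    rms_envelope(highpass(rec$channels[[nm]], rec$fs, highpass_hz),
                 rec$fs, rms_window_s)
  })
  breaths <- segment_breaths(rec, ...)
  ics <- breaths[breaths$is_ic, ]
  if (is.null(channel)) {
    channel <- select_reporting_channel(ics, envelopes, stat = emgdimax_stat)
  }
  breaths <- exclude_outlier_breaths(breaths, envelopes[[channel]])
  mx <- compute_emgdimax(ics, envelopes, stat = emgdimax_stat)
  acts <- breath_table_rms(envelopes[[channel]], breaths)
  minutes <- minute_summary(breaths, acts, mx$emgdimax)
  structure(list(minutes = minutes, breaths = breaths,
                 breath_activations = acts, emgdimax = mx$emgdimax,
                 emgdimax_source = mx[c("channel", "breath_id")],
                 reporting_channel = channel, envelopes = envelopes),
            class = "emgdi_analysis")
}

#' @export
print.emgdi_analysis <- function(x, ...) {
  cat(sprintf(paste0("<emgdi_analysis> channel %s, EMGdiMax %.4f V, ",
                     "%d minutes, %d breaths\n"),
              x$reporting_channel, x$emgdimax, nrow(x$minutes),
              nrow(x$breaths)))
  invisible(x)
}
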