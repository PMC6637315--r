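#' Amplitude-threshold QRS detection
#'
#' R peaks are local maxima of `abs(ecg)` exceeding `threshold_frac` times
#' a rolling 95th percentile of `abs(ecg)` (computed over `block_s` blocks
#' and interpolated), separated by a refractory period.  Around every peak
#' a blanking interval `[r - blank_pre_s, r + blank_post_s)` marks the
#' samples a manual assessor would consider QRS contaminated.
#'
#' @param ecg ECG signal (volts)
#' @param fs sampling rate (Hz)
#' @param threshold_frac fraction of the rolling 95th percentile
#' @param refractory_s minimum R-R separation (s)
#' @param blank_pre_s,blank_post_s blanking widths (s) before/after each R
#' @param block_s block length (s) for the rolling percentile
#' @return list of class `qrs_annotation`: `r_peaks` (sample indices),
#'   `blanked` (two-column matrix of half-open sample intervals, merged
#'   when overlapping), widths used
#' @export
detect_qrs <- function(ecg, fs, threshold_frac = 0.5, refractory_s = 0.25,
                       blank_pre_s = 0.06, blank_post_s = 0.10,
                       block_s = 2) {
  n <- length(ecg)
  a <- abs(ecg)
  out <- list(r_peaks = integer(), blanked = matrix(integer(), 0, 2),
              blank_pre_s = blank_pre_s, blank_post_s = blank_post_s)
  class(out) <- "qrs_annotation"
  if (!any(a > 0)) return(out)
  ## rolling 95th percentile on blocks, linearly interpolated
  bl <- max(1L, as.integer(round(block_s * fs)))
  starts <- seq.int(1L, n, by = bl)
  q <- vapply(starts, function(s) {
    quantile(a[s:min(s + bl - 1L, n)], 0.95, names = FALSE)
  }, 0)
  centers <- pmin(starts + bl / 2, n)
  thr_line <- if (length(q) > 1L) {
    approx(centers, q, xout = seq_len(n), rule = 2)$y
  } else rep(q, n)
  thr <- threshold_frac * thr_line
  above <- a > thr & a > 0
  if (!any(above)) return(out)
  ## one candidate peak per contiguous supra-threshold run
  r <- rle(above)
  ends <- cumsum(r$lengths)
  runs <- cbind(ends - r$lengths + 1L, ends)[r$values, , drop = FALSE]
  cand <- vapply(seq_len(nrow(runs)), function(i) {
    seg <- runs[i, 1L]:runs[i, 2L]
    seg[[which.max(a[seg])]]
  }, 0L)
  ## refractory: greedy by descending amplitude
  ord <- cand[order(a[cand], decreasing = TRUE)]
  refr <- as.integer(round(refractory_s * fs))
  keep <- integer()
  for (p in ord) {
    if (!length(keep) || all(abs(keep - p) >= refr)) keep <- c(keep, p)
  }
  peaks <- sort(keep)
  pre <- as.integer(round(blank_pre_s * fs))
  post <- as.integer(round(blank_post_s * fs))
  iv <- cbind(pmax(peaks - pre, 1L), pmin(peaks + post, n + 1L))
  ## merge overlapping blanking intervals
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- nrow(merged)
    if (iv[i, 1L] <= merged[last, 2L]) {
      merged[last, 2L] <- max(merged[last, 2L], iv[i, 2L])
    } else {
      merged <- rbind(merged, iv[i, ])
    }
  }
  out$r_peaks <- peaks
  out$blanked <- merged
  out
}

#' Enumerate contamination-free intervals within one inspiration
#'
#' The maximal sub-intervals of `[insp_start, insp_end)` that are disjoint
#' from every blanked QRS interval and at least `min_interval_s` wide -
#' the "possible periods that could be chosen" by a manual assessor.  Note
#' that P/T-wave energy outside the blanked windows deliberately remains
#' selectable, as it is for a human assessor.
#'
#' @param breath single-row breath slice
#' @param qrs a `qrs_annotation`
#' @param envelope RMS envelope of the analysis channel
#' @param fs sampling rate (Hz)
#' @param min_interval_s minimum selectable width (s)
#' @return data.frame with `start`, `end` (half-open samples), `width_s`,
#'   `mean_rms`; zero rows when the whole inspiration is blanked
#' @export
enumerate_clean_intervals <- function(breath, qrs, envelope, fs,
                                      min_interval_s = 0.05) {
  lo <- breath$insp_start
  hi <- breath$insp_end
  segs <- list()
  cur <- lo
  bl <- qrs$blanked
  if (nrow(bl)) {
    bl <- bl[bl[, 2L] > lo & bl[, 1L] < hi, , drop = FALSE]
    if (nrow(bl)) {
      for (i in seq_len(nrow(bl))) {
        if (bl[i, 1L] > cur) segs[[length(segs) + 1L]] <- c(cur, bl[i, 1L])
        cur <- max(cur, bl[i, 2L])
      }
    }
  }
  if (cur < hi) segs[[length(segs) + 1L]] <- c(cur, hi)
  if (!length(segs)) {
    return(data.frame(start = integer(), end = integer(),
                      width_s = numeric(), mean_rms = numeric()))
  }
  m <- do.call(rbind, segs)
  df <- data.frame(start = m[, 1L], end = pmin(m[, 2L], hi))
  df$width_s <- (df$end - df$start) / fs
  df <- df[df$width_s >= min_interval_s, , drop = FALSE]
  if (!nrow(df)) {
    return(data.frame(start = integer(), end = integer(),
                      width_s = numeric(), mean_rms = numeric()))
  }
  df$mean_rms <- vapply(seq_len(nrow(df)), function(i) {
    mean(envelope[df$start[[i]]:(df$end[[i]] - 1L)])
  }, 0)
  rownames(df) <- NULL
  df
}

#' Select one between-QRS interval by rater strategy
#'
#' `"highest"` picks the interval with the largest mean RMS (ties: the
#' latest interval, matching the end-inspiratory tendency of a
#' highest-seeking assessor); `"widest"` picks the longest interval (ties:
#' the earliest, matching a centrally-anchored widest-seeking assessor).
#'
#' @param intervals data frame from [enumerate_clean_intervals()]
#' @param strategy `"highest"` or `"widest"`
#' @return the selected single-row interval
#' @export
select_interval <- function(intervals, strategy = c("highest", "widest")) {
  strategy <- match.arg(strategy)
  if (!nrow(intervals)) stop("no selectable interval in this breath")
  if (strategy == "highest") {
    best <- max(intervals$mean_rms)
    idx <- which(intervals$mean_rms == best)
    intervals[idx[[length(idx)]], ]
  } else {
    best <- max(intervals$width_s)
    idx <- which(intervals$width_s == best)
    intervals[idx[[1L]], ]
  }
}

#' Manual-method estimate for every minute
#'
#' Emulates one assessor: for each minute take the last `n_rep` usable
#' non-IC breaths (fewer when the minute has fewer), select one
#' between-QRS interval per breath according to `strategy`, and average
#' the selected interval means.  The same selection machinery applied to
#' the IC maneuvers gives the manual-path EMGdiMax (the largest per-IC
#' selected value); per-minute values are reported as percent of it.
#'
#' @param breaths an `emgdi_breaths` data frame with minutes assigned
#' @param envelope RMS envelope of the (contaminated) analysis channel
#' @param qrs a `qrs_annotation` from [detect_qrs()]
#' @param fs sampling rate (Hz)
#' @param strategy rater strategy, see [select_interval()]
#' @param n_rep number of representative breaths per minute (default 5)
#' @param min_interval_s minimum selectable interval width (s)
#' @return list of class `emgdi_manual`: `minutes` (`minute_index`,
#'   `emgdi_pct`, `n_breaths_used`), `emgdimax`, `audit` (per-breath
#'   selected cursor positions in seconds), `strategy`
#' @export
manual_minute_estimate <- function(breaths, envelope, qrs, fs,
                                   strategy = c("highest", "widest"),
                                   n_rep = 5L, min_interval_s = 0.05) {
  strategy <- match.arg(strategy)
  sel_value <- function(b) {
    iv <- enumerate_clean_intervals(b, qrs, envelope, fs, min_interval_s)
    if (!nrow(iv)) return(NULL)
    select_interval(iv, strategy)
  }
  ## manual EMGdiMax from the IC maneuvers
  ics <- breaths[breaths$is_ic, ]
  if (!nrow(ics)) stop("no IC maneuvers found for manual EMGdiMax")
  ic_vals <- numeric()
  for (i in seq_len(nrow(ics))) {
    s <- sel_value(ics[i, ])
    if (!is.null(s)) ic_vals <- c(ic_vals, s$mean_rms)
  }
  if (!length(ic_vals)) stop("every IC inspiration is fully QRS-blanked")
  emgdimax <- max(ic_vals)
  usable <- breaths[!breaths$is_ic & breaths$quality == "ok" &
                    breaths$minute_index > 0, ]
  audit <- list()
  rows <- list()
  for (m in sort(unique(usable$minute_index))) {
    bm <- usable[usable$minute_index == m, ]
    bm <- bm[order(bm$insp_start), ]
    bm <- tail(bm, n_rep)
    vals <- numeric()
    for (i in seq_len(nrow(bm))) {
      s <- sel_value(bm[i, ])
      if (is.null(s)) next  # breath unusable: inspiration fully blanked
      vals <- c(vals, s$mean_rms)
      audit[[length(audit) + 1L]] <- data.frame(
        minute_index = m, breath_id = bm$breath_id[[i]],
        start_s = (s$start - 1L) / fs, end_s = (s$end - 1L) / fs,
        mean_rms = s$mean_rms)
    }
    if (!length(vals)) next
    rows[[length(rows) + 1L]] <- data.frame(
      minute_index = m, emgdi_pct = 100 * mean(vals) / emgdimax,
      n_breaths_used = length(vals))
  }
  structure(list(minutes = do.call(rbind, rows), emgdimax = emgdimax,
                 audit = do.call(rbind, audit), strategy = strategy),
            class = "emgdi_manual")
}

#' Manual-method analysis of a recording
#'
#' The manual path works on the contaminated signal: 20 Hz high-pass and
#' RMS envelope (no adaptive cancellation), QRS detection on the ECG
#' reference, between-QRS interval selection per breath on the reporting
#' channel, five representative breaths per minute.
#'
#' @inheritParams analyze_semiauto
#' @param strategy rater strategy, see [select_interval()]
#' @param n_rep representative breaths per minute
#' @param channel reporting channel; `NULL` selects from IC maneuvers
#'   (same rule as the semi-automated path so that paths are comparable)
#' @param qrs_args list of overrides for [detect_qrs()]
#' @param ... passed to [detect_breaths()]
#' @return an `emgdi_manual` list (see [manual_minute_estimate()]) plus
#'   elements `breaths` and `reporting_channel`
#' @export
analyze_manual <- function(rec, strategy = c("highest", "widest"),
                           highpass_hz = 20, rms_window_s = 0.05,
                           n_rep = 5L, channel = NULL, qrs_args = list(),
                           ...) {
  strategy <- match.arg(strategy)
  emg_names <- emg_channel_names(rec)
  envelopes <- lapply(setNames(emg_names, emg_names), function(nm) {
    rms_envelope(highpass(rec$channels[[nm]], rec$fs, highpass_hz),
                 rec$fs, rms_window_s)
  })
  breaths <- segment_breaths(rec, ...)
  ics <- breaths[breaths$is_ic, ]
  if (is.null(channel)) {
    channel <- select_reporting_channel(ics, envelopes)
  }
  breaths <- exclude_outlier_breaths(breaths, envelopes[[channel]])
  qrs <- do.call(detect_qrs,
                 c(list(ecg = require_channel(rec, "ecg"), fs = rec$fs),
                   qrs_args))
  res <- manual_minute_estimate(breaths, envelopes[[channel]], qrs, rec$fs,
                                strategy = strategy, n_rep = n_rep)
  res$breaths <- breaths
  res$reporting_channel <- channel
  res
}
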