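#' Detect breaths from the respiratory flow signal
#'
#' Segments the record into breath cycles from zero-flow points: an
#' inspiration starts at a negative-going zero crossing (flow sign
#' convention: negative = inspiration), ends at the following
#' positive-going crossing, and the expiration runs to the next
#' negative-going crossing.  A crossing only counts when `abs(flow)`
#' subsequently spends at least `hysteresis_s` seconds beyond
#' `hysteresis_lps` before the opposite crossing (hysteresis against
#' noise-level chatter around zero flow).  Candidate breaths shorter than
#' `min_insp_s` or with peak inspiratory flow below `min_amplitude` are
#' dropped.
#'
#' @param flow flow signal (L/s), negative = inspiration
#' @param fs sampling rate (Hz)
#' @param min_insp_s minimum inspiratory duration (s); breaths below this
#'   are discarded as sub-physiological
#' @param min_amplitude minimum peak inspiratory flow (L/s)
#' @param hysteresis_lps,hysteresis_s hysteresis level (L/s) and minimum
#'   dwell time (s) validating a zero crossing
#' @return data.frame of class `emgdi_breaths` with half-open sample-index
#'   columns `insp_start`, `insp_end`, `exp_end` (`insp_end` is the first
#'   expiratory sample), times in seconds, and columns `breath_id`,
#'   `is_ic` (FALSE, see [detect_ic_maneuvers()]), `minute_index` (NA, see
#'   [assign_minutes()]) and `quality` ("ok")
#' @export
detect_breaths <- function(flow, fs, min_insp_s = 0.3, min_amplitude = 0.05,
                           hysteresis_lps = 0.05, hysteresis_s = 0.05) {
  n <- length(flow)
  empty <- data.frame(breath_id = integer(), insp_start = integer(),
                      insp_end = integer(), exp_end = integer(),
                      insp_start_s = numeric(), insp_end_s = numeric(),
                      exp_end_s = numeric(), peak_insp_flow = numeric(),
                      volume_l = numeric(), is_ic = logical(),
                      minute_index = integer(), quality = character())
  class(empty) <- c("emgdi_breaths", "data.frame")
  if (n < 2L) return(empty)
  s <- sign(flow)
  neg <- which(s[-1L] < 0 & s[-n] >= 0) + 1L   # first sample of negative run
  pos <- which(s[-1L] >= 0 & s[-n] < 0) + 1L   # first sample of non-negative run
  dwell <- max(1L, as.integer(round(hysteresis_s * fs)))
  ## validate: after a crossing, the signal must dwell beyond the hysteresis
  ## level for >= dwell samples before the next opposite crossing
  validate <- function(idx, opposite, sgn) {
    keep <- logical(length(idx))
    for (k in seq_along(idx)) {
      nxt <- opposite[opposite > idx[[k]]]
      end <- if (length(nxt)) nxt[[1L]] - 1L else n
      seg <- flow[idx[[k]]:end]
      keep[[k]] <- sum(sgn * seg > hysteresis_lps) >= dwell
    }
    idx[keep]
  }
  neg <- validate(neg, pos, -1)
  pos <- validate(pos, neg, +1)
  if (!length(neg)) return(empty)
  ## pair crossings: for each inspiratory onset, the next validated
  ## positive-going crossing ends the inspiration; the next validated
  ## negative-going crossing ends the expiration
  rows <- list()
  for (k in seq_along(neg)) {
    i0 <- neg[[k]]
    i1 <- pos[pos > i0]
    if (!length(i1)) break
    i1 <- i1[[1L]]
    i2 <- neg[neg > i1]
    i2 <- if (length(i2)) i2[[1L]] else n + 1L
    rows[[length(rows) + 1L]] <- c(i0, i1, i2)
  }
  if (!length(rows)) return(empty)
  m <- do.call(rbind, rows)
  df <- data.frame(insp_start = m[, 1L], insp_end = m[, 2L], exp_end = m[, 3L])
  df$peak_insp_flow <- vapply(seq_len(nrow(df)), function(i) {
    -min(flow[df$insp_start[[i]]:(df$insp_end[[i]] - 1L)])
  }, 0)
  df$volume_l <- vapply(seq_len(nrow(df)), function(i) {
    -sum(flow[df$insp_start[[i]]:(df$insp_end[[i]] - 1L)]) / fs
  }, 0)
  ti <- (df$insp_end - df$insp_start) / fs
  df <- df[ti >= min_insp_s & df$peak_insp_flow >= min_amplitude, ,
           drop = FALSE]
  if (!nrow(df)) return(empty)
  df$breath_id <- seq_len(nrow(df))
  df$insp_start_s <- (df$insp_start - 1L) / fs
  df$insp_end_s <- (df$insp_end - 1L) / fs
  df$exp_end_s <- (df$exp_end - 1L) / fs
  df$is_ic <- FALSE
  df$minute_index <- NA_integer_
  df$quality <- "ok"
  rownames(df) <- NULL
  df <- df[, names(empty)]
  attr(df, "fs") <- fs
  class(df) <- c("emgdi_breaths", "data.frame")
  df
}

#' Flag inspiratory-capacity maneuvers
#'
#' Marker mode flags breaths whose cycle contains an `ic_maneuver` event
#' marker.  Volume mode flags breaths whose inspired volume exceeds
#' `k` times the running median tidal volume (IC maneuvers are maximal
#' inspirations, typically 2-3x tidal volume).
#'
#' @param breaths an `emgdi_breaths` data frame
#' @param markers marker data frame (`time_s`, `label`) for marker mode
#' @param method `"marker"` or `"volume_threshold"`
#' @param k volume-mode threshold multiple (default 1.5); `Inf` flags none
#' @param window running-median window (breaths, odd) for volume mode
#' @return `breaths` with `is_ic` set
#' @export
detect_ic_maneuvers <- function(breaths, markers = NULL,
                                method = c("marker", "volume_threshold"),
                                k = 1.5, window = 15L) {
  method <- match.arg(method)
  if (!nrow(breaths)) return(breaths)
  if (method == "marker") {
    if (is.null(markers)) {
      stop("marker mode requires event markers; ",
           "use method = 'volume_threshold' instead")
    }
    ic_t <- markers$time_s[markers$label == "ic_maneuver"]
    breaths$is_ic <- vapply(seq_len(nrow(breaths)), function(i) {
      any(ic_t >= breaths$insp_start_s[[i]] & ic_t < breaths$exp_end_s[[i]])
    }, FALSE)
  } else {
    vol <- breaths$volume_l
    w <- min(as.integer(window), nrow(breaths))
    if (w %% 2L == 0L) w <- w - 1L
    ref <- if (w >= 3L) runmed(vol, w, endrule = "median") else rep(median(vol),
                                                                    length(vol))
    breaths$is_ic <- is.finite(k) & vol > k * ref
  }
  breaths
}

#' Assign breaths to test minutes
#'
#' Each breath belongs to the minute containing its inspiratory onset;
#' minutes are 1-based half-open intervals `[60(k-1), 60k)` seconds from
#' the anchor (the `rest_start` marker when present, otherwise `t0`).
#' Breaths starting before the anchor get `minute_index` -1 and quality
#' `excluded_short` downstream consumers skip them.
#'
#' @param breaths an `emgdi_breaths` data frame
#' @param markers optional marker data frame with a `rest_start` event
#' @param t0 fallback anchor time (s)
#' @return `breaths` with `minute_index` filled in
#' @export
assign_minutes <- function(breaths, markers = NULL, t0 = 0) {
  anchor <- t0
  if (!is.null(markers) && any(markers$label == "rest_start")) {
    anchor <- markers$time_s[markers$label == "rest_start"][[1L]]
  }
  rel <- breaths$insp_start_s - anchor
  breaths$minute_index <- ifelse(rel < 0, -1L, floor(rel / 60) + 1L)
  breaths
}

#' Flag outlier breaths
#'
#' Operationalises the visual exclusion of "short sighs or visible noise":
#' a non-IC breath is `excluded_short` when its inspiratory time is below
#' `min_insp_s`, and `excluded_noisy` when its mean inspiratory envelope is
#' more than `z_max` robust z-scores (median / MAD) away from its minute's
#' median.
#'
#' @param breaths an `emgdi_breaths` data frame with minutes assigned
#' @param envelope RMS envelope of the analysis channel ([rms_envelope()])
#' @param min_insp_s duration threshold (s)
#' @param z_max robust z-score threshold (default 4)
#' @return `breaths` with `quality` set
#' @export
exclude_outlier_breaths <- function(breaths, envelope, min_insp_s = 0.3,
                                    z_max = 4) {
  if (!nrow(breaths)) return(breaths)
  ti <- breaths$insp_end_s - breaths$insp_start_s
  mean_env <- vapply(seq_len(nrow(breaths)), function(i) {
    mean(envelope[breaths$insp_start[[i]]:(breaths$insp_end[[i]] - 1L)])
  }, 0)
  quality <- rep("ok", nrow(breaths))
  quality[!breaths$is_ic & ti < min_insp_s] <- "excluded_short"
  quality[breaths$minute_index < 0] <- "excluded_short"
  for (m in unique(breaths$minute_index)) {
    sel <- which(breaths$minute_index == m & !breaths$is_ic &
                 quality == "ok")
    if (length(sel) < 4L) next
    med <- median(mean_env[sel])
    s <- stats::mad(mean_env[sel])
    if (s <= 0) next
    quality[sel][abs(mean_env[sel] - med) / s > z_max] <- "excluded_noisy"
  }
  breaths$quality <- quality
  breaths
}

#' Full breath segmentation for a recording
#'
#' Convenience wrapper: [detect_breaths()] on the flow channel, IC
#' flagging (marker mode when markers are present, volume mode otherwise)
#' and minute assignment.
#'
#' @param rec an `emgdi_recording` with a `flow` channel
#' @param ... passed to [detect_breaths()]
#' @return an `emgdi_breaths` data frame
#' @export
segment_breaths <- function(rec, ...) {
  flow <- require_channel(rec, "flow")
  br <- detect_breaths(flow, rec$fs, ...)
  if (!is.null(rec$markers) && any(rec$markers$label == "ic_maneuver")) {
    br <- detect_ic_maneuvers(br, rec$markers, method = "marker")
  } else {
    br <- detect_ic_maneuvers(br, method = "volume_threshold")
  }
  assign_minutes(br, rec$markers, t0 = rec$t0)
}
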