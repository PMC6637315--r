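#' Multi-channel physiological recording
#'
#' Container for time-synchronised, equal-length signal channels sampled at a
#' single rate: five diaphragm EMG channels (`emg_1` .. `emg_5`, volts), one
#' ECG reference channel (`ecg`, volts) and one respiratory flow channel
#' (`flow`, L/s).  The flow sign convention is negative flow = inspiration.
#' Event markers (time in seconds + label) ride along as an attribute-style
#' field so that they survive resampling unchanged.
#'
#' @param channels named list or data.frame of equal-length numeric vectors.
#'   Channel names must be unique; `flow` and `ecg` are required for the
#'   downstream analysis functions but not for the container itself.
#' @param fs sampling rate in Hz (scalar > 0).
#' @param t0 start time of sample 1 in seconds (default 0).  Sample `i`
#'   covers the half-open interval `[t0 + (i-1)/fs, t0 + i/fs)`.
#' @param markers optional data.frame with columns `time_s` (non-decreasing)
#'   and `label` (character; vocabulary: `rest_start`, `unloaded_start`,
#'   `loaded_start`, `minute_k`, `ic_maneuver`, `test_end`).
#'
#' @return an object of class `emgdi_recording`: a list with elements
#'   `fs`, `t0`, `channels` (named list of numeric vectors), `markers`.
#' @export
recording <- function(channels, fs, t0 = 0, markers = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a positive scalar (Hz)")
  }
  channels <- as.list(channels)
  if (length(channels) == 0L) stop("at least one channel is required")
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("channel names must be present and unique")
  }
  len <- lengths(channels)
  if (length(unique(len)) != 1L) {
    stop("all channels must have identical length (got ",
         paste(unique(len), collapse = ", "), ")")
  }
  channels <- lapply(channels, function(x) as.numeric(x))
  markers <- validate_markers(markers)
  structure(list(fs = as.numeric(fs), t0 = as.numeric(t0),
                 channels = channels, markers = markers),
            class = "emgdi_recording")
}

marker_labels <- c("rest_start", "unloaded_start", "loaded_start",
                   "minute_k", "ic_maneuver", "test_end")

validate_markers <- function(markers) {
  if (is.null(markers)) return(NULL)
  markers <- as.data.frame(markers)
  if (!all(c("time_s", "label") %in% names(markers))) {
    stop("markers need columns 'time_s' and 'label'")
  }
  if (is.unsorted(markers$time_s)) stop("marker times must be non-decreasing")
  bad <- setdiff(unique(markers$label), marker_labels)
  if (length(bad)) {
    stop("unknown marker label(s): ", paste(bad, collapse = ", "))
  }
  markers[, c("time_s", "label")]
}

#' @export
print.emgdi_recording <- function(x, ...) {
  n <- length(x$channels[[1L]])
  cat(sprintf("<emgdi_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), n, x$fs, n / x$fs))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (!is.null(x$markers)) {
    cat(sprintf("  markers: %d events\n", nrow(x$markers)))
  }
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `emgdi_recording`
#' @return integer sample count
#' @export
n_samples <- function(rec) length(rec$channels[[1L]])

emg_channel_names <- function(rec) {
  grep("^emg_[0-9]+$", names(rec$channels), value = TRUE)
}

require_channel <- function(rec, role) {
  if (!role %in% names(rec$channels)) {
    stop(sprintf("%s channel required but not present in recording", role))
  }
  rec$channels[[role]]
}

#' Write a recording as delimited text
#'
#' Dialect: a first header line `# fs=<Hz> t0=<s>`, optional marker lines
#' `# marker <time_s> <label>`, a channel-name line, then tab-separated
#' numeric rows at full (17 significant digit) precision so that a
#' write/read round trip is bit-exact.
#'
#' @param rec an `emgdi_recording`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emgdi_recording"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g t0=%.17g", rec$fs, rec$t0), con)
  if (!is.null(rec$markers) && nrow(rec$markers)) {
    writeLines(sprintf("# marker %.17g %s", rec$markers$time_s,
                       rec$markers$label), con)
  }
  writeLines(paste(names(rec$channels), collapse = "\t"), con)
  mat <- do.call(cbind, rec$channels)
  lines <- do.call(paste, c(lapply(seq_len(ncol(mat)), function(j)
    sprintf("%.17g", mat[, j])), sep = "\t"))
  writeLines(lines, con)
  invisible(path)
}

#' Read a delimited-text recording
#'
#' Parses the dialect written by [write_recording()].  The `flow` and `ecg`
#' channels are required (the downstream pipeline cannot run without them);
#' unknown channel names are preserved.
#'
#' @param path input file path
#' @param require_roles channel roles that must be present
#'   (default `c("ecg", "flow")`; use `character()` to disable the check).
#' @return an `emgdi_recording`
#' @export
read_recording <- function(path, require_roles = c("ecg", "flow")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[[1L]], "# fs=")) {
    stop("not a recording file (missing '# fs=' header): ", path)
  }
  hdr <- strsplit(sub("^# ", "", lines[[1L]]), " ")[[1L]]
  kv <- strsplit(hdr, "=")
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  fs <- as.numeric(vals[["fs"]])
  t0 <- if ("t0" %in% names(vals)) as.numeric(vals[["t0"]]) else 0
  i <- 2L
  markers <- NULL
  while (i <= length(lines) && startsWith(lines[[i]], "# marker ")) {
    parts <- strsplit(sub("^# marker ", "", lines[[i]]), " ")[[1L]]
    markers <- rbind(markers, data.frame(time_s = as.numeric(parts[[1L]]),
                                         label = parts[[2L]]))
    i <- i + 1L
  }
  ch_names <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
  body <- lines[seq.int(i + 1L, length(lines))]
  split_rows <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(split_rows)
  if (any(nfield != length(ch_names))) {
    bad <- which(nfield != length(ch_names))[[1L]]
    stop(sprintf("ragged row in %s at line %d: %d fields, expected %d",
                 path, i + bad, nfield[[bad]], length(ch_names)))
  }
  mat <- matrix(as.numeric(unlist(split_rows, use.names = FALSE)),
                ncol = length(ch_names), byrow = TRUE)
  channels <- setNames(lapply(seq_along(ch_names), function(j) mat[, j]),
                       ch_names)
  missing_role <- setdiff(require_roles, ch_names)
  if (length(missing_role)) {
    stop(sprintf("%s channel required", missing_role[[1L]]))
  }
  recording(channels, fs = fs, t0 = t0, markers = markers)
}

#' Resample a recording to a lower rate
#'
#' Anti-alias filters every channel (zero-phase 8th-order Butterworth
#' low-pass at 0.45 x target rate) and then decimates.  Integer decimation
#' ratios are handled by picking every k-th sample; non-integer ratios by
#' interpolating the filtered signal at the new sample times.  Marker times
#' are stored in seconds and therefore unchanged.
#'
#' @param rec an `emgdi_recording`
#' @param target_fs new sampling rate in Hz; must not exceed `rec$fs`
#' @return resampled `emgdi_recording`
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "emgdi_recording"))
  if (target_fs > rec$fs) stop("upsampling is not supported")
  if (target_fs == rec$fs) return(rec)
  ratio <- rec$fs / target_fs
  cutoff <- 0.45 * target_fs
  ba <- butter_design(4L, cutoff, rec$fs, type = "low")
  n <- n_samples(rec)
  new_ch <- lapply(rec$channels, function(x) {
    xf <- filtfilt_ba(ba$b, ba$a, x)
    if (abs(ratio - round(ratio)) < 1e-9) {
      xf[seq.int(1L, n, by = as.integer(round(ratio)))]
    } else {
      t_old <- (seq_len(n) - 1) / rec$fs
      t_new <- seq(0, t_old[[n]], by = 1 / target_fs)
      approx(t_old, xf, xout = t_new)$y
    }
  })
  recording(new_ch, fs = target_fs, t0 = rec$t0, markers = rec$markers)
}
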