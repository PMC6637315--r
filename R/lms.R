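#' LMS adaptive-filter configuration
#'
#' Parameters of the reference-channel least-mean-squares FIR canceller.
#' The defaults (filter length 70 taps, step size 0.01, plain update on the
#' raw reference) reproduce the published operating point of the
#' semi-automated ECG exclusion.  The filter models the electrode-specific
#' linear path from the ECG reference channel into each EMG channel; its
#' output is subtracted continuously, so removal keeps working while the
#' heart rate drifts (the coupling path, not the rhythm, is what is
#' estimated).
#'
#' @param filter_length number of FIR taps (default 70)
#' @param step_size adaptation constant mu (default 0.01)
#' @param normalized if `TRUE`, use the power-normalised (NLMS) update
#'   `mu / (eps + ||x||^2)`; more robust to reference amplitude but not the
#'   reference behaviour of this package
#' @param standardize_ref if `TRUE`, the reference is centred and scaled to
#'   unit variance before filtering (the weights absorb the scale).  Default
#'   `FALSE`: with the plain update, gradient noise injected into the
#'   cleaned EMG grows with `mu * L * var(ref)`, and at unit reference
#'   power mu = 0.01 with 70 taps would distort the EMG amplitude.  On raw
#'   physiological reference amplitudes the published step size is both
#'   stable and low-noise.
#' @param eps NLMS regulariser (> 0)
#' @param guard divergence detector: abort when `max(abs(w))` exceeds this
#' @return list of class `lms_config`
#' @export
lms_config <- function(filter_length = 70L, step_size = 0.01,
                       normalized = FALSE, standardize_ref = FALSE,
                       eps = 1e-8, guard = 1e4) {
  if (filter_length < 1L) stop("filter_length must be >= 1")
  if (step_size <= 0) stop("step_size must be > 0")
  if (eps <= 0) stop("eps must be > 0")
  structure(list(filter_length = as.integer(filter_length),
                 step_size = step_size, normalized = isTRUE(normalized),
                 standardize_ref = isTRUE(standardize_ref),
                 eps = eps, guard = guard),
            class = "lms_config")
}

#' Remove ECG artifact from one EMG channel by LMS adaptive filtering
#'
#' At every sample the FIR filter predicts the artifact from the last
#' `filter_length` reference samples, subtracts the prediction, and nudges
#' the tap weights along the instantaneous gradient
#' `w <- w + mu * e(n) * x(n)` (plain LMS; see [lms_config()] for the
#' normalised variant).  Weights start at zero and the reference history is
#' zero padded, so output length and alignment equal the input.
#'
#' @param emg_channel contaminated EMG signal (volts)
#' @param ecg_reference time-synchronised ECG reference, same length
#' @param config an [lms_config()]
#' @return list of class `lms_result` with elements `cleaned`,
#'   `residual_estimate` (the artifact estimate; `cleaned +
#'   residual_estimate` reproduces the input to machine precision) and
#'   `weights` (final taps)
#' @export
lms_clean <- function(emg_channel, ecg_reference, config = lms_config()) {
  if (length(emg_channel) != length(ecg_reference)) {
    stop("emg_channel and ecg_reference must have the same length")
  }
  if (!inherits(config, "lms_config")) config <- do.call(lms_config, config)
  ref <- ecg_reference
  if (config$standardize_ref) {
    s <- sd(ref)
    if (s > 0) ref <- (ref - mean(ref)) / s
  }
  res <- lms_cpp(emg_channel, ref, config$filter_length, config$step_size,
                 config$normalized, config$eps, config$guard)
  structure(list(cleaned = res$cleaned, residual_estimate = res$artifact,
                 weights = res$weights), class = "lms_result")
}

#' Clean every EMG channel of a recording
#'
#' Applies [lms_clean()] to each `emg_*` channel against the recording's
#' `ecg` channel.  Flow, ECG and markers are passed through untouched.
#'
#' @param rec an `emgdi_recording` with an `ecg` and at least one `emg_*`
#'   channel
#' @param config an [lms_config()]
#' @return the recording with cleaned EMG channels; per-channel
#'   `lms_result`s are attached as attribute `lms_results`, and attribute
#'   `provenance` notes the configuration used
#' @export
clean_recording <- function(rec, config = lms_config()) {
  stopifnot(inherits(rec, "emgdi_recording"))
  ecg <- require_channel(rec, "ecg")
  emg_names <- emg_channel_names(rec)
  if (!length(emg_names)) stop("recording has no emg_* channels")
  results <- list()
  for (nm in emg_names) {
    res <- tryCatch(lms_clean(rec$channels[[nm]], ecg, config),
                    error = function(e) {
                      stop(sprintf("channel %s: %s", nm, conditionMessage(e)),
                           call. = FALSE)
                    })
    rec$channels[[nm]] <- res$cleaned
    results[[nm]] <- res
  }
  attr(rec, "lms_results") <- results
  attr(rec, "provenance") <- sprintf(
    "lms: L=%d mu=%g normalized=%s standardize_ref=%s",
    config$filter_length, config$step_size, config$normalized,
    config$standardize_ref)
  rec
}
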