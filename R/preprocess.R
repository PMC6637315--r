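## Butterworth IIR design (analog prototype -> bilinear transform) and
## zero-phase filtering.  Kept in-package deliberately: the 20 Hz high-pass
## and the anti-alias low-pass are the only filters needed and the closed
## form lets the tests check the realised response against the analytic
## Butterworth magnitude with prewarped frequencies.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rk in r) p <- c(p, 0) - c(0, p) * rk
  p
}

#' Butterworth filter coefficients
#'
#' Digital Butterworth design of order `n` via the bilinear transform with
#' frequency prewarping.  Returns transfer-function coefficients `b`
#' (numerator) and `a` (denominator), `a[1] == 1`.
#'
#' @param n filter order
#' @param cutoff -3 dB cutoff frequency in Hz
#' @param fs sampling rate in Hz
#' @param type `"low"` or `"high"`
#' @return list with numeric vectors `b` and `a`
#' @export
butter_design <- function(n, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie strictly between 0 and fs/2")
  }
  wc <- tan(pi * cutoff / fs)                      # prewarped analog cutoff
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # LHP prototype poles
  if (type == "low") {
    poles <- wc * proto
    zeros <- rep(-1 + 0i, n)                       # analog zeros at infinity
    zpoles <- (1 + poles) / (1 - poles)
    b <- Re(poly_from_roots(zeros))
    a <- Re(poly_from_roots(zpoles))
    g <- sum(a) / sum(b)                           # unit gain at DC (z = 1)
  } else {
    poles <- wc / proto
    zpoles <- (1 + poles) / (1 - poles)
    zzeros <- rep(1 + 0i, n)                       # analog zeros at s = 0
    b <- Re(poly_from_roots(zzeros))
    a <- Re(poly_from_roots(zpoles))
    s <- c(1, -1)[(seq_along(a) - 1) %% 2 + 1]     # evaluate at z = -1
    g <- sum(a * s) / sum(b * s)                   # unit gain at Nyquist
  }
  list(b = b * g, a = a)
}

## one-pass IIR (direct form II transposed)
iir_filter <- function(b, a, x, zi = NULL) {
  nb <- max(length(b), length(a))
  b <- c(b, rep(0, nb - length(b)))
  a <- c(a, rep(0, nb - length(a)))
  if (is.null(zi)) zi <- numeric(max(nb - 1L, 1L))
  iir_filter_cpp(b / a[[1L]], a / a[[1L]], x, zi)
}

## steady-state delay-line state of the DF2T filter for a unit step input
## (the lfilter_zi construction: solve (I - companion(a)^T) zi = B)
iir_steady_state <- function(b, a) {
  nb <- max(length(b), length(a))
  b <- c(b, rep(0, nb - length(b)))
  a <- c(a, rep(0, nb - length(a)))
  b <- b / a[[1L]]; a <- a / a[[1L]]
  if (nb < 2L) return(numeric(1L))
  comp_t <- cbind(-a[-1L], rbind(diag(1, nb - 2L),
                                 rep(0, nb - 2L)))
  B <- b[-1L] - a[-1L] * b[[1L]]
  solve(diag(nb - 1L) - comp_t, B)
}

#' Zero-phase IIR filtering
#'
#' Applies the filter forward and backward (squares the magnitude response,
#' cancels the phase).  Edges are stabilised by odd-reflection padding and
#' steady-state initial conditions scaled to the first padded sample, as
#' in the conventional filtfilt construction.
#'
#' @param b,a transfer-function coefficients
#' @param x numeric signal
#' @return filtered signal, same length as `x`
#' @export
filtfilt_ba <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 9L * (length(a) + length(b)))
  if (pad > 0) {
    pre <- 2 * x[[1L]] - x[seq.int(pad + 1L, 2L)]
    post <- 2 * x[[n]] - x[seq.int(n - 1L, n - pad)]
    xx <- c(pre, x, post)
  } else {
    xx <- x
  }
  zi <- iir_steady_state(b, a)
  y <- iir_filter(b, a, xx, zi * xx[[1L]])
  y <- rev(y)
  y <- rev(iir_filter(b, a, y, zi * y[[1L]]))
  y[seq.int(pad + 1L, pad + n)]
}

#' High-pass filter a signal
#'
#' Zero-phase 4th-order Butterworth high-pass, the standard step used to
#' strip motion artifact (and any DC) from EMG before amplitude analysis.
#' The default 20 Hz cutoff sits just below the EMG energy band
#' (roughly 20-250 Hz) and well above movement-artifact frequencies.
#'
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @param cutoff high-pass cutoff (Hz), must be `< fs/2`
#' @param order filter order of the one-pass design (applied twice)
#' @return filtered signal, same length as `x`
#' @export
highpass <- function(x, fs, cutoff = 20, order = 4L) {
  ba <- butter_design(order, cutoff, fs, type = "high")
  filtfilt_ba(ba$b, ba$a, x)
}

#' Moving-window RMS envelope
#'
#' Centered moving-window root-mean-square.  Windows are truncated at the
#' record edges (no padding), so no fabricated samples can enter breath
#' means computed from the envelope.
#'
#' @param x numeric signal (volts)
#' @param fs sampling rate (Hz)
#' @param window_s window length in seconds; `window_s * fs` must be >= 1
#' @return object of class `emgdi_envelope`: numeric vector of RMS values
#'   (same length as `x`) with attributes `fs` and `window_s`
#' @export
rms_envelope <- function(x, fs, window_s = 0.05) {
  if (window_s <= 0) stop("window_s must be positive")
  w <- as.integer(round(window_s * fs))
  if (w < 1L) stop("window_s * fs must be at least 1 sample")
  n <- length(x)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  cs <- c(0, cumsum(x * x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  env <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  structure(env, fs = fs, window_s = window_s, class = "emgdi_envelope")
}
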