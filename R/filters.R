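#' Butterworth IIR filter design
#'
#' Designs digital low-pass or high-pass Butterworth filters via the analog
#' prototype and bilinear transform (with frequency pre-warping), returning
#' transfer-function coefficients in the usual `b` (numerator) / `a`
#' (denominator) convention.  This is the standard design also produced by
#' scientific signal-processing libraries; it is provided here because the
#' package needs only a handful of fixed filters (acquisition band-pass and
#' notch, lock-in amplifier low-pass, P300 low-pass).
#'
#' @param order filter order (>= 1).
#' @param cutoff cutoff frequency in Hz (-3 dB point).
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return list with numeric vectors `b` and `a` (length `order + 1`).
#' @export
butter_filter <- function(order, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (order < 1) stopf("filter order must be >= 1")
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stopf("cutoff must lie strictly between 0 and fs/2 = %g Hz", fs / 2)
  }
  # analog Butterworth prototype poles (unit cutoff)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # pre-warped analog cutoff
  warped <- 2 * fs * tan(pi * cutoff / fs)
  if (type == "low") {
    p <- warped * p
    zd <- rep(-1 + 0i, order)   # analog zeros at infinity -> z = -1
  } else {
    p <- warped / p             # s -> warped / s
    zd <- rep(1 + 0i, order)    # analog zeros at s = 0 -> z = +1
  }
  # bilinear transform: z = (1 + s/(2 fs)) / (1 - s/(2 fs))
  fs2 <- 2 * fs
  pd <- (1 + p / fs2) / (1 - p / fs2)
  b <- Re(poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  # normalize gain exactly: unity at DC (low) or Nyquist (high)
  ref <- if (type == "low") sum(b) / sum(a) else
    sum(b * (-1)^(seq_along(b) - 1)) / sum(a * (-1)^(seq_along(a) - 1))
  list(b = b / ref, a = a)
}

# Expand a monic polynomial from its roots (complex-safe).
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Second-order IIR notch filter
#'
#' Standard biquad notch at `freq` with quality factor `q`
#' (bandwidth = freq / q).
#'
#' @param freq notch frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param q quality factor.
#' @return list with `b` and `a` coefficient vectors.
#' @export
iir_notch <- function(freq, fs, q = 35) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Single-pass direct-form IIR filtering built on stats::filter:
# FIR part by one-sided convolution, AR part recursively.
filter_iir <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb - 1 + seq_along(x)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase forward-backward IIR filtering
#'
#' Applies the filter forwards and backwards (squaring the magnitude
#' response, cancelling the phase), with odd-reflection padding at both ends
#' to suppress edge transients.
#'
#' @param filt list with `b` and `a` as returned by [butter_filter()] or
#'   [iir_notch()].
#' @param x numeric signal.
#' @param padlen reflection pad length in samples; default
#'   `3 * (max(length(b), length(a)) - 1)`, capped at `length(x) - 1`.
#'   Narrow-band filters (cutoff far below Nyquist) benefit from a longer
#'   pad, e.g. a few filter time constants.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt_iir <- function(filt, x, padlen = NULL) {
  b <- filt$b; a <- filt$a
  n <- length(x)
  if (n < 2) return(x)
  padlen <- padlen %||% (3 * (max(length(b), length(a)) - 1))
  padlen <- min(padlen, n - 1)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[1 + padlen:1]
    post <- 2 * x[n] - x[n - 1:padlen]
    xe <- c(pre, x, post)
  } else xe <- x
  y <- filter_iir(b, a, xe)
  y <- rev(filter_iir(b, a, rev(y)))
  y[padlen + seq_len(n)]
}

# Band-pass a signal in a narrow band `bw` around `center` by complex
# demodulation: shift the band to baseband, low-pass at bw/2 (zero-phase),
# shift back.  Numerically robust for very narrow bands where a direct IIR
# band-pass would have poles hugging the unit circle.
bandpass_demod <- function(x, center, bw, fs, order = 4, padlen = NULL) {
  lp <- butter_filter(order, bw / 2, fs)
  t <- (seq_along(x) - 1) / fs
  cs <- cos(2 * pi * center * t)
  sn <- sin(2 * pi * center * t)
  padlen <- padlen %||% round(3 * fs / bw)
  i <- filtfilt_iir(lp, x * cs, padlen = padlen)
  q <- filtfilt_iir(lp, x * sn, padlen = padlen)
  2 * (i * cs + q * sn)
}
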