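# Zero-phase Butterworth low-pass ----------------------------------------
#
# Pupil diameter cannot reverse direction faster than about 4 Hz, so
# everything above that is recording noise. We use a 2nd-order digital
# Butterworth (bilinear transform, -3 dB at the cutoff) applied forward and
# backward: zero phase lag, effective 4th-order magnitude response.

#' Second-order Butterworth low-pass coefficients
#'
#' Digital coefficients via the bilinear transform with frequency
#' pre-warping; cutoff defined at -3 dB.
#'
#' @param cutoff_hz Cutoff frequency (Hz), 0 < cutoff < rate/2.
#' @param rate Sampling rate (Hz).
#' @return List with numerator `b` and denominator `a` (length 3 each,
#'   `a[1] = 1`).
#' @export
butter2_lowpass <- function(cutoff_hz, rate) {
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2) {
    stop("cutoff must lie in (0, rate/2)", call. = FALSE)
  }
  w <- tan(pi * cutoff_hz / rate)       # pre-warped analog frequency
  k1 <- sqrt(2) * w
  k2 <- w^2
  a0 <- 1 + k1 + k2
  list(
    b = c(k2, 2 * k2, k2) / a0,
    a = c(1, 2 * (k2 - 1) / a0, (1 - k1 + k2) / a0)
  )
}

# Direct-form IIR, initialised at steady state for the first input value so
# a constant series passes through exactly. The moving-average part is
# vectorised and the recursion delegated to stats::filter (C level).
iir_filter <- function(b, a, x) {
  n <- length(x)
  xm1 <- c(x[1], x[-n])
  xm2 <- c(x[1], x[1], x[-c(n - 1, n)])
  z <- b[1] * x + b[2] * xm1 + b[3] * xm2
  as.numeric(stats::filter(z, -a[2:3], method = "recursive",
                           init = c(x[1], x[1])))
}

#' Theoretical amplitude response of the zero-phase filter
#'
#' Evaluates `|B(e^{-i w}) / A(e^{-i w})|^2` (squared because the filter is
#' applied forward and backward) from the polynomial coefficients. This is
#' the independent oracle for the time-domain implementation.
#'
#' @param freq_hz Frequencies at which to evaluate (Hz).
#' @param cutoff_hz,rate As in [butter2_lowpass()].
#' @return Amplitude gain at each frequency.
#' @export
butter2_filtfilt_gain <- function(freq_hz, cutoff_hz, rate) {
  co <- butter2_lowpass(cutoff_hz, rate)
  w <- 2 * pi * freq_hz / rate
  z <- exp(-1i * w)
  H <- (co$b[1] + co$b[2] * z + co$b[3] * z^2) /
    (co$a[1] + co$a[2] * z + co$a[3] * z^2)
  Mod(H)^2
}

#' Zero-phase 4-Hz low-pass filter
#'
#' Forward-backward application of [butter2_lowpass()] with odd-symmetric
#' edge padding (one second or as much as the series allows), so that edge
#' transients die out inside the padding. DC gain is exactly 1: a constant
#' series is returned unchanged.
#'
#' @param series Gap-free numeric series.
#' @param rate Sampling rate (Hz).
#' @param cutoff_hz Cutoff (Hz), default 4.
#' @return Filtered series, same length.
#' @export
#' @examples
#' lowpass_4hz(rep(3.5, 100), 120)[1]  # 3.5
lowpass_4hz <- function(series, rate, cutoff_hz = 4) {
  n <- length(series)
  min_len <- 10L
  if (n < min_len) {
    stop(sprintf("series too short to filter: %d samples, need >= %d", n, min_len),
         call. = FALSE)
  }
  if (anyNA(series)) {
    stop("lowpass_4hz() requires a gap-free series; interpolate first",
         call. = FALSE)
  }
  co <- butter2_lowpass(cutoff_hz, rate)
  pad <- min(n - 1L, as.integer(rate))   # ~1 s of padding
  # odd reflection: continues the series through the end points
  pre <- 2 * series[1] - series[(pad + 1):2]
  post <- 2 * series[n] - series[(n - 1):(n - pad)]
  x <- c(pre, series, post)
  y <- iir_filter(co$b, co$a, x)
  y <- rev(iir_filter(co$b, co$a, rev(y)))
  y[(pad + 1):(pad + n)]
}
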