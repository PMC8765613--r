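# Windowed-sinc FIR design and zero-phase filtering.
#
# No DSP toolbox is assumed: kernels are symmetric (linear-phase) windowed-sinc
# designs, applied as centred FFT convolutions. A symmetric kernel applied once
# with its group delay removed is already zero-phase; applying it twice gives
# the two-pass magnitude response |H(f)|^2 that a forward-backward filter has.

#' Design a windowed-sinc FIR kernel
#'
#' @param fs sampling rate in Hz.
#' @param kind one of `"lowpass"`, `"highpass"`, `"bandpass"`, `"bandstop"`.
#' @param edges cutoff frequency in Hz (length 1 for low/highpass, length 2
#'   for bandpass/bandstop). Edges are -6 dB points.
#' @param transition transition width in Hz; the kernel order is
#'   `ceiling(3.3 * fs / transition)` (Hamming window), forced odd. If `NULL`
#'   a default tied to the band edges is used: a quarter of the cutoff for
#'   lowpass, half the lower edge (capped at half the bandwidth) for bandpass,
#'   and half the stop bandwidth for bandstop.
#' @return numeric kernel of odd length, summing to the appropriate DC gain.
#' @keywords internal
fir_design <- function(fs, kind = c("lowpass", "highpass", "bandpass", "bandstop"),
                       edges, transition = NULL) {
  kind <- match.arg(kind)
  nyq <- fs / 2
  if (any(edges <= 0) || any(edges >= nyq)) {
    stop("filter edges must lie strictly inside (0, Nyquist = ", nyq, " Hz)")
  }
  if (is.null(transition)) {
    transition <- switch(kind,
      lowpass  = max(edges[1] / 4, 0.5),
      highpass = max(edges[1] / 2, 0.5),
      bandpass = max(min(edges[1] / 2, (edges[2] - edges[1]) / 2), 0.25),
      bandstop = max((edges[2] - edges[1]) / 2, 0.5)
    )
  }
  n_taps <- ceiling(3.3 * fs / transition)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  m <- (n_taps - 1) / 2
  t <- seq(-m, m)
  win <- 0.54 + 0.46 * cos(pi * t / m)
  sinc_lp <- function(fc) {
    # ideal lowpass with -6 dB point at fc
    h <- 2 * fc / fs * sinc(2 * fc / fs * t)
    h * win
  }
  h <- switch(kind,
    lowpass  = sinc_lp(edges[1]),
    highpass = delta_kernel(n_taps) - sinc_lp(edges[1]),
    bandpass = sinc_lp(edges[2]) - sinc_lp(edges[1]),
    bandstop = delta_kernel(n_taps) - (sinc_lp(edges[2]) - sinc_lp(edges[1]))
  )
  # normalize passband gain to exactly 1
  gain_at <- function(f) abs(sum(h * exp(-2i * pi * f / fs * t)))
  g <- switch(kind,
    lowpass  = sum(h),
    highpass = gain_at(nyq * 0.999),
    bandpass = gain_at(mean(edges)),
    bandstop = sum(h)
  )
  h / g
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

delta_kernel <- function(n) {
  h <- numeric(n)
  h[(n + 1) / 2] <- 1
  h
}

#' Magnitude response of a symmetric FIR kernel
#'
#' @param h kernel from [fir_design()].
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz.
#' @param passes 1 for single application, 2 for the zero-phase two-pass chain.
#' @return magnitude response at `f`.
#' @keywords internal
fir_response <- function(h, f, fs, passes = 2) {
  m <- (length(h) - 1) / 2
  t <- seq(-m, m)
  r <- vapply(f, function(fi) abs(sum(h * exp(-2i * pi * fi / fs * t))), numeric(1))
  r^passes
}

# full linear convolution via zero-padded FFTs at a fast composite length
fft_conv <- function(x, h) {
  n_out <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n_out, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n_out)] / nfft
}

# Centred FFT convolution of x with symmetric kernel h, reflect-padded by one
# kernel length so onset transients stay outside the data.
filter_once <- function(x, h) {
  n <- length(x)
  m <- (length(h) - 1) / 2
  pad <- min(length(h), n - 1)
  xp <- c(rev(x[seq_len(pad) + 1]), x, rev(x[n - seq_len(pad)]))
  y <- fft_conv(xp, h)
  y[(pad + m) + seq_len(n)]
}

#' Zero-phase (two-pass) FIR filtering
#'
#' Applies a symmetric FIR kernel twice with group-delay compensation and
#' reflection padding; the effective magnitude response is the square of the
#' kernel's one-pass response and the phase response is identically zero.
#'
#' @param x numeric vector (one channel).
#' @param h kernel from [fir_design()].
#' @return filtered vector, same length as `x`.
#' @keywords internal
filtfilt_fir <- function(x, h) {
  filter_once(filter_once(x, h), h)
}

#' Analytic signal via the Hilbert transform
#'
#' @param x numeric vector.
#' @return complex vector of the same length; `Mod()` gives instantaneous
#'   amplitude, `Arg()` instantaneous phase.
#' @keywords internal
hilbert_analytic <- function(x) {
  n0 <- length(x)
  nfft <- stats::nextn(n0, c(2, 3, 5))
  if (nfft > n0) {
    # reflect-pad to a fast FFT length; trimmed after the transform
    pad <- nfft - n0
    x <- c(x, rev(x[n0 - seq_len(pad)]))
  }
  out <- hilbert_core(x)
  out[seq_len(n0)]
}

hilbert_core <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

#' Centred moving-average smoothing
#'
#' Uses partial windows at the edges so output length equals input length and
#' no NA values are introduced.
#'
#' @param x numeric vector.
#' @param k kernel length in samples (coerced to at least 1).
#' @return smoothed vector.
#' @keywords internal
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(x)
  n <- length(x)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k - 1L - half_lo
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# kernel length in samples for a smoothing window given in seconds
kernel_samples <- function(seconds, fs) max(1L, as.integer(round(seconds * fs)))
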