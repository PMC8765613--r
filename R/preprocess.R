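# Preprocessing chain for continuous recordings: low-pass, line-noise notches,
# resampling to the analysis rate, and common-average re-referencing. All
# filters are two-pass zero-phase FIR with reflection padding.

apply_by_channel <- function(rec, fun) {
  out <- rec
  for (ch in seq_len(nrow(rec$samples))) {
    out$samples[ch, ] <- fun(rec$samples[ch, ])
  }
  out
}

#' Low-pass filter a recording
#'
#' @param rec a [continuous_recording()].
#' @param cutoff -6 dB cutoff in Hz (default 235).
#' @return filtered recording, same length and rate.
#' @export
lowpass_filter <- function(rec, cutoff = 235) {
  nyq <- rec$sampling_rate / 2
  if (cutoff >= nyq) stop("lowpass cutoff (", cutoff, " Hz) must be below Nyquist (", nyq, " Hz)")
  h <- fir_design(rec$sampling_rate, "lowpass", cutoff)
  apply_by_channel(rec, function(x) filtfilt_fir(x, h))
}

#' Notch out line noise and its harmonics
#'
#' Applies a band-stop at `base` and every harmonic below `upper_limit`
#' (harmonics above the low-pass cutoff are already attenuated and skipped).
#'
#' @param rec a [continuous_recording()].
#' @param base line frequency in Hz (default 60).
#' @param bandwidth full stop-band width in Hz (default 4, i.e. +-2 Hz).
#' @param upper_limit highest frequency to notch (default 235, the low-pass
#'   cutoff); also capped at Nyquist.
#' @return filtered recording.
#' @export
notch_harmonics <- function(rec, base = 60, bandwidth = 4, upper_limit = 235) {
  nyq <- rec$sampling_rate / 2
  if (base >= nyq) stop("notch base frequency must be below Nyquist")
  freqs <- seq(base, min(upper_limit, nyq - bandwidth), by = base)
  out <- rec
  for (f0 in freqs) {
    h <- fir_design(rec$sampling_rate, "bandstop",
                    c(f0 - bandwidth / 2, f0 + bandwidth / 2))
    out <- apply_by_channel(out, function(x) filtfilt_fir(x, h))
  }
  out
}

#' Resample a recording to a target rate
#'
#' Integer downsampling ratios use anti-alias filtering followed by
#' decimation; non-integer ratios use anti-alias filtering followed by linear
#' interpolation onto the target grid. Event times stay on the absolute clock
#' (seconds), so no event bookkeeping is needed.
#'
#' @param rec a [continuous_recording()].
#' @param target target sampling rate in Hz (default 500).
#' @return recording at `target` Hz.
#' @export
downsample <- function(rec, target = 500) {
  if (rec$sampling_rate < target) stop("target rate exceeds the recording rate")
  if (rec$sampling_rate == target) return(rec)
  # anti-alias below the new Nyquist
  h <- fir_design(rec$sampling_rate, "lowpass", 0.8 * target / 2,
                  transition = 0.2 * target / 2)
  rec <- apply_by_channel(rec, function(x) filtfilt_fir(x, h))
  ratio <- rec$sampling_rate / target
  n <- ncol(rec$samples)
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1L, n, by = as.integer(round(ratio)))
    samples <- rec$samples[, idx, drop = FALSE]
  } else {
    t_old <- sample_times(rec)
    t_new <- seq(rec$start_time, t_old[n], by = 1 / target)
    samples <- t(vapply(seq_len(nrow(rec$samples)), function(ch) {
      stats::approx(t_old, rec$samples[ch, ], xout = t_new)$y
    }, numeric(length(t_new))))
  }
  continuous_recording(samples, target, rec$channel_labels, rec$start_time)
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous across-channel mean from every channel.
#'
#' @param rec a [continuous_recording()] with at least 2 channels.
#' @return re-referenced recording; the across-channel mean of the output is
#'   zero at every sample.
#' @export
common_average_reference <- function(rec) {
  if (nrow(rec$samples) < 2) {
    stop("common average reference needs at least 2 channels")
  }
  rec$samples <- sweep(rec$samples, 2, colMeans(rec$samples))
  rec
}

#' Full preprocessing chain
#'
#' Low-pass at `cutoff`, notch line harmonics, resample to `target_rate`, and
#' (for multichannel data) re-reference to the common average, in that order.
#'
#' @inheritParams lowpass_filter
#' @inheritParams notch_harmonics
#' @param target_rate analysis sampling rate (default 500 Hz).
#' @param car apply common-average referencing (default TRUE when >= 2 channels).
#' @return preprocessed recording.
#' @export
preprocess_recording <- function(rec, cutoff = 235, base = 60, bandwidth = 4,
                                 target_rate = 500, car = nrow(rec$samples) >= 2) {
  cutoff <- min(cutoff, 0.95 * rec$sampling_rate / 2)
  fs <- rec$sampling_rate
  # compose the low-pass and all notch kernels into one two-pass magnitude
  # response and apply it with a single FFT round trip per channel; magnitude
  # responses of zero-phase stages multiply, so this equals running the
  # stages sequentially (up to padding treatment)
  kernels <- list(fir_design(fs, "lowpass", cutoff))
  for (f0 in seq(base, min(cutoff, fs / 2 - bandwidth), by = base)) {
    kernels <- c(kernels, list(
      fir_design(fs, "bandstop", c(f0 - bandwidth / 2, f0 + bandwidth / 2))))
  }
  n <- ncol(rec$samples)
  pad <- min(max(lengths(kernels)), n - 1)
  nfft <- stats::nextn(n + 2 * pad, c(2, 3, 5))
  H2 <- rep(1, nfft)
  for (h in kernels) {
    H2 <- H2 * Mod(stats::fft(c(h, numeric(nfft - length(h)))))^2
  }
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    xp <- c(rev(x[seq_len(pad) + 1]), x, rev(x[n - seq_len(pad)]))
    X <- stats::fft(c(xp, numeric(nfft - length(xp))))
    rec$samples[ch, ] <- Re(stats::fft(X * H2, inverse = TRUE))[pad + seq_len(n)] / nfft
  }
  rec <- downsample(rec, target_rate)
  if (car) rec <- common_average_reference(rec)
  rec
}
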