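# Filter-bank amplitude extraction, sniff-aligned epoching, baseline
# correction, permutation-normalized spectrograms, and the evoked/induced
# decomposition.

#' Build the logarithmic analysis filter bank
#'
#' 100 center frequencies log-spaced from 1 to 200 Hz
#' (`c_k = 200^((k-1)/99)`) with bandwidths log-spaced from 2 to 50 Hz
#' (`w_k = 2 * 25^((k-1)/99)`); only the first `n_kept` (default 95, spanning
#' ~1-153 Hz) are retained for analysis. The phase-amplitude-coupling
#' amplitude subset is the 47 kept centers above 13 Hz (13.05-153.04 Hz).
#'
#' @param n_total total designed bands (default 100).
#' @param n_kept bands retained (default 95).
#' @return a `filter_bank` data.frame with columns `center`, `width`, `lo`,
#'   `hi` (band edges in Hz).
#' @export
build_filter_bank <- function(n_total = 100, n_kept = 95) {
  k <- seq_len(n_total)
  center <- 200^((k - 1) / (n_total - 1))
  width <- 2 * 25^((k - 1) / (n_total - 1))
  bank <- data.frame(center = center, width = width,
                     lo = center - width / 2, hi = center + width / 2)
  bank <- bank[seq_len(n_kept), ]
  class(bank) <- c("filter_bank", "data.frame")
  bank
}

#' Amplitude-band subset used for phase-amplitude coupling
#'
#' @param bank a [build_filter_bank()] result.
#' @param min_center lowest center frequency retained (default 13 Hz,
#'   exclusive).
#' @return the subset of `bank` with `center > min_center` (47 bands for the
#'   default bank).
#' @export
pac_band_subset <- function(bank = build_filter_bank(), min_center = 13) {
  out <- bank[bank$center > min_center, ]
  class(out) <- class(bank)
  out
}

#' Band-limited analytic amplitudes of a recording
#'
#' For each bank band: two-pass zero-phase FIR band-pass at
#' `[center - width/2, center + width/2]`, analytic amplitude via the Hilbert
#' transform, then moving-average smoothing (10 ms kernel). Bands whose lower
#' edge is not positive are realized as low-pass filters; bands reaching
#' Nyquist are skipped with a warning.
#'
#' @param rec a single-channel [continuous_recording()] (for multichannel
#'   input, `channel` selects the channel of interest).
#' @param bank a [build_filter_bank()] result (possibly subset).
#' @param channel channel index (default 1).
#' @param smooth_s smoothing kernel in seconds (default 0.010).
#' @return an `amplitude_stack`: list with `amplitudes` (band x time matrix),
#'   `band_centers`, `sampling_rate`, `start_time`.
#' @export
amplitude_stack <- function(rec, bank = build_filter_bank(), channel = 1,
                            smooth_s = 0.010) {
  fs <- rec$sampling_rate
  nyq <- fs / 2
  x <- rec$samples[channel, ]
  keep <- bank$hi < nyq
  if (any(!keep)) {
    warning(sum(!keep), " band(s) at or above Nyquist skipped")
    bank <- bank[keep, ]
  }
  k_smooth <- kernel_samples(smooth_s, fs)
  amp <- matrix(0, nrow(bank), length(x))
  # Shared-FFT evaluation: reflect-pad once, transform once, then per band
  # apply the FIR kernel's two-pass magnitude response |H(f)|^2 (zero phase by
  # construction) together with the analytic-signal mask, and invert. This is
  # numerically equivalent to filtfilt + Hilbert up to the padding treatment.
  kernels <- lapply(seq_len(nrow(bank)), function(b) {
    if (bank$lo[b] <= 0) {
      fir_design(fs, "lowpass", bank$hi[b])
    } else {
      fir_design(fs, "bandpass", c(bank$lo[b], bank$hi[b]))
    }
  })
  n <- length(x)
  pad <- min(max(lengths(kernels)), n - 1)
  xp <- c(rev(x[seq_len(pad) + 1]), x, rev(x[n - seq_len(pad)]))
  nfft <- stats::nextn(length(xp), c(2, 3, 5))
  X <- stats::fft(c(xp, numeric(nfft - length(xp))))
  analytic_w <- numeric(nfft)
  analytic_w[1] <- 1
  if (nfft %% 2 == 0) {
    analytic_w[nfft / 2 + 1] <- 1
    analytic_w[2:(nfft / 2)] <- 2
  } else {
    analytic_w[2:((nfft + 1) / 2)] <- 2
  }
  for (b in seq_len(nrow(bank))) {
    h <- kernels[[b]]
    H2 <- Mod(stats::fft(c(h, numeric(nfft - length(h)))))^2
    xa <- stats::fft(X * H2 * analytic_w, inverse = TRUE)[pad + seq_len(n)] / nfft
    amp[b, ] <- moving_average(Mod(xa), k_smooth)
  }
  structure(list(amplitudes = amp, band_centers = bank$center,
                 sampling_rate = fs, start_time = rec$start_time),
            class = "amplitude_stack")
}

#' @export
print.amplitude_stack <- function(x, ...) {
  cat(sprintf("<amplitude_stack> %d bands (%.2f-%.2f Hz) x %d samples @ %g Hz\n",
              nrow(x$amplitudes), min(x$band_centers), max(x$band_centers),
              ncol(x$amplitudes), x$sampling_rate))
  invisible(x)
}

stack_time_to_sample <- function(stack, t) {
  as.integer(round((t - stack$start_time) * stack$sampling_rate)) + 1L
}

#' Cut sniff-aligned epochs from an amplitude stack
#'
#' One trial x band x time slice per event, aligned to `sniff_time_s`, over a
#' half-open window (default `[-2, 4)` s). Events whose window falls outside
#' the recording are dropped with a warning (the drop count is kept in the
#' result).
#'
#' @param stack an [amplitude_stack()].
#' @param events event data.frame with at least `sniff_time_s`; other columns
#'   (`condition`, `correct`, `cue_time_s`, ...) are carried as trial metadata.
#' @param window alignment window in seconds, half-open.
#' @return a `trial_tensor`: list with `amplitudes` (trial x band x time
#'   array), `time_axis` (s, relative to sniff onset), `band_centers`, `meta`
#'   (data.frame), `n_dropped`.
#' @export
epoch_stack <- function(stack, events, window = c(-2, 4)) {
  fs <- stack$sampling_rate
  n_time <- as.integer(round((window[2] - window[1]) * fs))
  rel_idx <- seq_len(n_time) - 1L
  start_idx <- stack_time_to_sample(stack, events$sniff_time_s + window[1])
  ok <- start_idx >= 1 & (start_idx + n_time - 1L) <= ncol(stack$amplitudes)
  if (any(!ok)) {
    warning(sum(!ok), " event(s) outside the recording were dropped")
  }
  events <- events[ok, , drop = FALSE]
  start_idx <- start_idx[ok]
  n_band <- nrow(stack$amplitudes)
  amp <- array(0, c(nrow(events), n_band, n_time))
  for (i in seq_along(start_idx)) {
    amp[i, , ] <- stack$amplitudes[, start_idx[i] + rel_idx, drop = FALSE]
  }
  structure(list(amplitudes = amp,
                 time_axis = window[1] + rel_idx / fs,
                 band_centers = stack$band_centers,
                 meta = as.data.frame(events), n_dropped = sum(!ok),
                 sampling_rate = fs),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$amplitudes)
  cat(sprintf("<trial_tensor> %d trials x %d bands x %d samples (t in [%.2f, %.2f] s)\n",
              d[1], d[2], d[3], min(x$time_axis), max(x$time_axis)))
  invisible(x)
}

# per-trial, per-band mean amplitude in the pre-cue baseline window, read from
# the continuous stack (the baseline precedes the epoch window)
baseline_means_from_stack <- function(stack, cue_times, window = c(-0.55, -0.05)) {
  i0 <- stack_time_to_sample(stack, cue_times + window[1])
  i1 <- stack_time_to_sample(stack, cue_times + window[2]) - 1L
  n_band <- nrow(stack$amplitudes)
  out <- matrix(NA_real_, length(cue_times), n_band)
  for (i in seq_along(cue_times)) {
    if (i0[i] >= 1 && i1[i] <= ncol(stack$amplitudes) && i1[i] >= i0[i]) {
      out[i, ] <- rowMeans(stack$amplitudes[, i0[i]:i1[i], drop = FALSE])
    }
  }
  out
}

baseline_sds_from_stack <- function(stack, cue_times, window = c(-0.55, -0.05)) {
  i0 <- stack_time_to_sample(stack, cue_times + window[1])
  i1 <- stack_time_to_sample(stack, cue_times + window[2]) - 1L
  out <- matrix(NA_real_, length(cue_times), nrow(stack$amplitudes))
  for (i in seq_along(cue_times)) {
    if (i0[i] >= 1 && i1[i] <= ncol(stack$amplitudes) && i1[i] >= i0[i]) {
      out[i, ] <- apply(stack$amplitudes[, i0[i]:i1[i], drop = FALSE], 1, stats::sd)
    }
  }
  out
}

#' Baseline-correct a trial tensor
#'
#' Subtracts, per trial and band, the mean amplitude in a pre-cue window
#' (default `[-0.55, -0.05]` s before cue onset, read from the continuous
#' stack since the window precedes the epoch). Trials with no usable baseline
#' (missing cue or window outside the recording) are excluded with a warning.
#' The baseline means are retained in `$baseline` for percent-change use.
#'
#' @param trials a [epoch_stack()] result whose `meta` has `cue_time_s`.
#' @param stack the same [amplitude_stack()] the trials were cut from.
#' @param window baseline window in seconds relative to cue onset.
#' @param z_normalize also divide by the per-trial baseline standard
#'   deviation (default FALSE).
#' @return the corrected `trial_tensor`, with `$baseline` (trial x band
#'   matrix of baseline means) attached.
#' @export
baseline_correct <- function(trials, stack, window = c(-0.55, -0.05),
                             z_normalize = FALSE) {
  if (is.null(trials$meta$cue_time_s)) stop("trial metadata lacks cue_time_s")
  bl <- baseline_means_from_stack(stack, trials$meta$cue_time_s, window)
  ok <- stats::complete.cases(bl)
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) without a usable baseline window were excluded")
    trials$amplitudes <- trials$amplitudes[ok, , , drop = FALSE]
    trials$meta <- trials$meta[ok, , drop = FALSE]
    bl <- bl[ok, , drop = FALSE]
  }
  if (z_normalize) {
    bs <- baseline_sds_from_stack(stack, trials$meta$cue_time_s, window)
    bs[bs == 0] <- NA
  }
  for (i in seq_len(dim(trials$amplitudes)[1])) {
    trials$amplitudes[i, , ] <- trials$amplitudes[i, , ] - bl[i, ]
    if (z_normalize) trials$amplitudes[i, , ] <- trials$amplitudes[i, , ] / bs[i, ]
  }
  trials$baseline <- bl
  trials
}

# mean spectrogram (band x time) over trials of a tensor
tensor_mean <- function(trials) {
  apply(trials$amplitudes, c(2, 3), mean)
}

#' Circular-shift permutation z-map
#'
#' Tests the baseline-corrected trial-average spectrogram against a null in
#' which all event times are circularly shifted by one common random offset
#' (wrapping at the recording ends), preserving inter-event spacing. The
#' z-score at each time-frequency point is the observed baseline-corrected
#' average divided by the standard deviation of the permutation averages;
#' two-sided p values are Benjamini-Hochberg corrected across all points.
#'
#' @param stack an [amplitude_stack()].
#' @param events event data.frame (`sniff_time_s`, `cue_time_s`).
#' @param window epoch window (s).
#' @param baseline_window baseline window (s, relative to cue).
#' @param n_perm number of permutations (default 10000).
#' @param q FDR level (default 0.05).
#' @param seed optional RNG seed.
#' @return a `zmap`: list with `z`, `significance_mask`, `p_adj`, `null_sd`,
#'   `null_mean`, `band_centers`, `time_axis`, `n_perm`, `q`.
#' @export
circular_shift_zmap <- function(stack, events, window = c(-2, 4),
                                baseline_window = c(-0.55, -0.05),
                                n_perm = 10000, q = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(events) < 2) stop("need at least 2 events")
  fs <- stack$sampling_rate
  n_rec <- ncol(stack$amplitudes)
  n_time <- as.integer(round((window[2] - window[1]) * fs))
  if (n_rec < 2 * n_time) stop("recording is shorter than twice the epoch span")

  trials <- epoch_stack(stack, events, window)
  trials <- baseline_correct(trials, stack, baseline_window)
  observed <- tensor_mean(trials)

  # common-shift null on the raw (uncorrected) trial-average amplitude
  rel_idx <- seq_len(n_time) - 1L
  ev_idx <- stack_time_to_sample(stack, events$sniff_time_s + window[1])
  n_band <- nrow(stack$amplitudes)
  null_mean_acc <- matrix(0, n_band, n_time)
  null_m2_acc <- matrix(0, n_band, n_time)
  offsets <- sample.int(n_rec - 1L, n_perm, replace = TRUE)
  for (p in seq_len(n_perm)) {
    idx <- (ev_idx + offsets[p] - 1L) %% n_rec + 1L
    acc <- matrix(0, n_band, n_time)
    for (i in seq_along(idx)) {
      cols <- (idx[i] + rel_idx - 1L) %% n_rec + 1L
      acc <- acc + stack$amplitudes[, cols, drop = FALSE]
    }
    acc <- acc / length(idx)
    null_mean_acc <- null_mean_acc + acc
    null_m2_acc <- null_m2_acc + acc^2
  }
  null_mean <- null_mean_acc / n_perm
  null_sd <- sqrt(pmax(null_m2_acc / n_perm - null_mean^2, 0)) *
    sqrt(n_perm / (n_perm - 1))
  z <- observed / null_sd
  z[observed == 0 & null_sd == 0] <- 0   # degenerate constant data
  finalize_zmap(z, null_mean, null_sd, trials, n_perm, q)
}

finalize_zmap <- function(z, null_mean, null_sd, trials, n_perm, q) {
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- matrix(stats::p.adjust(p, method = "BH"), nrow(z), ncol(z))
  structure(list(z = z, significance_mask = p_adj < q, p_adj = p_adj,
                 null_mean = null_mean, null_sd = null_sd,
                 band_centers = trials$band_centers,
                 time_axis = trials$time_axis, n_perm = n_perm, q = q),
            class = "zmap")
}

#' @export
print.zmap <- function(x, ...) {
  cat(sprintf("<zmap> %d bands x %d times, %d permutations, %.1f%% significant (q = %g)\n",
              nrow(x$z), ncol(x$z), x$n_perm,
              100 * mean(x$significance_mask), x$q))
  invisible(x)
}

#' Condition-difference permutation z-map
#'
#' Statistic: difference of baseline-corrected trial-mean spectrograms
#' (A minus B). Null: condition labels shuffled across the pooled trials; the
#' per-point null is summarized by a Gaussian maximum-likelihood fit (mean,
#' sd) and `z = (observed - null mean) / null sd`, FDR-corrected across
#' points. Unequal trial counts are allowed.
#'
#' @param trialsA,trialsB baseline-corrected [epoch_stack()] tensors sharing
#'   band and time axes.
#' @param n_perm number of label shuffles (default 10000).
#' @param q FDR level.
#' @param seed optional RNG seed.
#' @return a `zmap`.
#' @export
condition_difference_zmap <- function(trialsA, trialsB, n_perm = 10000,
                                      q = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dA <- dim(trialsA$amplitudes); dB <- dim(trialsB$amplitudes)
  if (dA[1] == 0 || dB[1] == 0) stop("empty condition")
  if (!all(dA[-1] == dB[-1])) stop("tensors must share band and time axes")
  nA <- dA[1]; nB <- dB[1]
  observed <- tensor_mean(trialsA) - tensor_mean(trialsB)

  pooled <- array(0, c(nA + nB, dA[2], dA[3]))
  pooled[seq_len(nA), , ] <- trialsA$amplitudes
  pooled[nA + seq_len(nB), , ] <- trialsB$amplitudes
  pm <- matrix(aperm(pooled, c(1, 2, 3)), nrow = nA + nB)  # trial x (band*time)

  mean_acc <- matrix(0, dA[2], dA[3])
  m2_acc <- matrix(0, dA[2], dA[3])
  tot <- colSums(pm)
  for (p in seq_len(n_perm)) {
    ia <- sample.int(nA + nB, nA)
    sa <- colSums(pm[ia, , drop = FALSE])
    diff_p <- matrix(sa / nA - (tot - sa) / nB, dA[2], dA[3])
    mean_acc <- mean_acc + diff_p
    m2_acc <- m2_acc + diff_p^2
  }
  null_mean <- mean_acc / n_perm
  null_sd <- sqrt(pmax(m2_acc / n_perm - null_mean^2, 0))  # Gaussian ML fit
  z <- (observed - null_mean) / null_sd
  finalize_zmap(z, null_mean, null_sd, trialsA, n_perm, q)
}

#' Evoked/induced decomposition of voltage epochs
#'
#' Splits sniff-aligned voltage epochs into a phase-locked (evoked) and a
#' non-phase-locked (induced) part: the evoked spectrogram is the filter-bank
#' amplitude of the event-related potential (trial-average waveform); the
#' induced tensor is the filter-bank amplitude of each trial after the ERP is
#' subtracted.
#'
#' @param voltage_epochs trial x time matrix of raw voltage epochs (all
#'   aligned the same way).
#' @param sampling_rate Hz.
#' @param bank filter bank (default [build_filter_bank()]).
#' @param baseline_idx optional sample indices used to baseline-correct the
#'   evoked spectrogram (mean over these columns subtracted per band).
#' @return list with `erp` (time vector), `evoked` (band x time), `induced`
#'   (trial x band x time array), `band_centers`.
#' @export
decompose_evoked_induced <- function(voltage_epochs, sampling_rate,
                                     bank = build_filter_bank(),
                                     baseline_idx = NULL) {
  if (nrow(voltage_epochs) < 5) {
    warning("fewer than 5 trials: the ERP (and thus the split) is unstable")
  }
  erp <- colMeans(voltage_epochs)
  amp_of <- function(x) {
    rec <- continuous_recording(x, sampling_rate)
    amplitude_stack(rec, bank)$amplitudes
  }
  evoked <- amp_of(erp)
  if (!is.null(baseline_idx)) {
    evoked <- evoked - rowMeans(evoked[, baseline_idx, drop = FALSE])
  }
  n_band <- nrow(evoked)
  induced <- array(0, c(nrow(voltage_epochs), n_band, ncol(voltage_epochs)))
  for (i in seq_len(nrow(voltage_epochs))) {
    induced[i, , ] <- amp_of(voltage_epochs[i, ] - erp)
  }
  list(erp = erp, evoked = evoked, induced = induced,
       band_centers = bank$center)
}
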