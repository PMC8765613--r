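# Phase-amplitude coupling: Kullback-Leibler modulation index of theta phase
# against the 47 higher-frequency amplitude bands, with circular-shift and
# trial-order-shuffle permutation nulls.

#' Sniff-aligned theta phase epochs
#'
#' Band-passes the recording at the theta band, extracts the analytic phase,
#' cuts a post-sniff window per event, and concatenates across trials
#' preserving trial order.
#'
#' @param rec a preprocessed [continuous_recording()].
#' @param events event data.frame with `sniff_time_s`.
#' @param window post-sniff window in seconds (default `[0, 1)`).
#' @param band theta band edges in Hz (default 4-8).
#' @param channel channel of interest.
#' @return list with `phase` (concatenated vector), `epochs` (trial x time
#'   matrix), `events` (the events kept), `n_dropped`.
#' @export
theta_phase_epochs <- function(rec, events, window = c(0, 1), band = c(4, 8),
                               channel = 1) {
  fs <- rec$sampling_rate
  h <- fir_design(fs, "bandpass", band)
  phase <- Arg(hilbert_analytic(filtfilt_fir(rec$samples[channel, ], h)))
  n_time <- as.integer(round((window[2] - window[1]) * fs))
  start_idx <- time_to_sample(rec, events$sniff_time_s + window[1])
  ok <- start_idx >= 1 & (start_idx + n_time - 1L) <= length(phase)
  if (any(!ok)) warning(sum(!ok), " event(s) outside the recording were dropped")
  start_idx <- start_idx[ok]
  epochs <- t(vapply(start_idx, function(i) phase[i:(i + n_time - 1L)],
                     numeric(n_time)))
  list(phase = as.vector(t(epochs)), epochs = epochs,
       events = events[ok, , drop = FALSE], n_dropped = sum(!ok))
}

# cut and concatenate amplitude epochs for every band of a stack
amplitude_epochs_concat <- function(stack, events, window = c(0, 1)) {
  fs <- stack$sampling_rate
  n_time <- as.integer(round((window[2] - window[1]) * fs))
  start_idx <- stack_time_to_sample(stack, events$sniff_time_s + window[1])
  ok <- start_idx >= 1 & (start_idx + n_time - 1L) <= ncol(stack$amplitudes)
  if (any(!ok)) warning(sum(!ok), " event(s) outside the recording were dropped")
  start_idx <- start_idx[ok]
  cols <- as.vector(vapply(start_idx, function(i) i:(i + n_time - 1L),
                           integer(n_time)))
  list(amp = stack$amplitudes[, cols, drop = FALSE], ok = ok,
       n_time = n_time)
}

#' Kullback-Leibler modulation index
#'
#' Phases are binned into `n_bins` equal bins over `(-pi, pi]`; the
#' phase-binned mean amplitude distribution `P` (normalized to sum 1) is
#' compared to uniform: `MI = (log N + sum(P * log P)) / log N`, bounded in
#' `[0, 1]` (0 = no modulation, 1 = all amplitude in one bin). Empty bins
#' contribute 0 via the `0 * log 0 = 0` limit and raise a warning.
#'
#' @param phase phase angles in radians.
#' @param amplitude non-negative amplitudes, same length, positive sum.
#' @param n_bins number of phase bins (default 18).
#' @return MI in `[0, 1]`.
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18) {
  stopifnot(length(phase) == length(amplitude))
  if (any(amplitude < 0)) stop("amplitude must be non-negative")
  if (sum(amplitude) <= 0) stop("amplitude must have a positive sum")
  bins <- phase_bins(phase, n_bins)
  mi_from_bins(bins, amplitude, n_bins, warn_empty = TRUE)
}

phase_bins <- function(phase, n_bins) {
  b <- ceiling((phase + pi) / (2 * pi / n_bins))
  pmin(pmax(b, 1L), n_bins)
}

mi_from_bins <- function(bins, amplitude, n_bins, warn_empty = FALSE) {
  sums <- numeric(n_bins)
  agg <- rowsum(amplitude, bins)
  sums[as.integer(rownames(agg))] <- agg
  counts <- tabulate(bins, n_bins)
  if (warn_empty && any(counts == 0)) {
    warning(sum(counts == 0), " empty phase bin(s); treated as zero probability")
  }
  p <- ifelse(counts > 0, sums / pmax(counts, 1), 0)
  p <- p / sum(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  (log(n_bins) + sum(plogp)) / log(n_bins)
}

#' Raw modulation-index spectrum over the amplitude bands
#'
#' Computes the MI between concatenated post-sniff theta phase and the
#' concatenated amplitude of each band of `bank` (by default the 47 kept
#' filter-bank bands above 13 Hz).
#'
#' @param rec a preprocessed [continuous_recording()].
#' @param events event data.frame.
#' @param window post-sniff window (s).
#' @param bank amplitude filter bank (default [pac_band_subset()]).
#' @param n_bins phase bins.
#' @param channel channel of interest.
#' @param stack optional precomputed [amplitude_stack()] for `bank` (avoids
#'   refiltering).
#' @return list with `mi` (per band), `band_centers`, `phase` (concatenated),
#'   `phase_epochs`, `amp` (band x concatenated-time matrix), `n_time`
#'   (samples per trial), `n_bins`.
#' @export
mi_spectrum <- function(rec, events, window = c(0, 1),
                        bank = pac_band_subset(), n_bins = 18, channel = 1,
                        stack = NULL) {
  ph <- theta_phase_epochs(rec, events, window, channel = channel)
  if (is.null(stack)) stack <- amplitude_stack(rec, bank, channel = channel)
  ae <- amplitude_epochs_concat(stack, ph$events, window)
  bins <- phase_bins(ph$phase, n_bins)
  mi <- apply(ae$amp, 1, function(a) mi_from_bins(bins, a, n_bins))
  list(mi = mi, band_centers = stack$band_centers, phase = ph$phase,
       phase_epochs = ph$epochs, amp = ae$amp, n_time = ae$n_time,
       n_bins = n_bins)
}

pac_result <- function(spec, null_mat, null_kind, q, excluded = NULL) {
  null_mean <- rowMeans(null_mat)
  null_sd <- apply(null_mat, 1, stats::sd)
  flagged <- null_sd == 0
  if (!is.null(excluded)) flagged <- flagged | excluded
  z <- (spec$mi - null_mean) / ifelse(flagged, NA, null_sd)
  p <- stats::pnorm(z, lower.tail = FALSE)          # one-sided: coupling > null
  p_adj <- rep(NA_real_, length(p))
  p_adj[!flagged] <- stats::p.adjust(p[!flagged], method = "BH")
  structure(list(amp_band_centers = spec$band_centers, mi_raw = spec$mi,
                 mi_z = z, p = p, p_adj = p_adj,
                 fdr_mask = !is.na(p_adj) & p_adj < q,
                 null_kind = null_kind, n_permutations = ncol(null_mat),
                 null_mean = null_mean, null_sd = null_sd,
                 excluded = flagged, q = q, n_bins = spec$n_bins),
            class = "pac_result")
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("<pac_result> %d bands, null = %s (%d perms), %d significant at q = %g\n",
              length(x$mi_raw), x$null_kind, x$n_permutations,
              sum(x$fdr_mask), x$q))
  if (any(x$fdr_mask)) {
    top <- which.max(ifelse(x$fdr_mask, x$mi_z, -Inf))
    cat(sprintf("  peak z = %.2f at %.2f Hz (MI = %.4g)\n",
                x$mi_z[top], x$amp_band_centers[top], x$mi_raw[top]))
  }
  invisible(x)
}

#' Modulation index with a circular-shift permutation null
#'
#' Per band, the null MI distribution is obtained by circularly shifting the
#' concatenated amplitude series by a uniform random offset (identity shift
#' excluded) against the unshifted theta phase; `z = (MI - null mean) / null
#' sd`, one-sided p, Benjamini-Hochberg across the bands. Bands with zero
#' null sd are flagged and excluded from the FDR.
#'
#' @inheritParams mi_spectrum
#' @param n_perm permutations per band (default 1000).
#' @param q FDR level.
#' @param seed optional RNG seed.
#' @return a `pac_result`.
#' @export
mi_null_circular_shift <- function(rec, events, window = c(0, 1),
                                   bank = pac_band_subset(), n_bins = 18,
                                   n_perm = 1000, q = 0.05, seed = NULL,
                                   channel = 1, stack = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- mi_spectrum(rec, events, window, bank, n_bins, channel, stack)
  bins <- phase_bins(spec$phase, n_bins)
  L <- length(spec$phase)
  null_mat <- matrix(0, nrow(spec$amp), n_perm)
  offsets <- sample.int(L - 1L, n_perm, replace = TRUE)  # 1..L-1, never 0
  for (p in seq_len(n_perm)) {
    idx <- (seq_len(L) + offsets[p] - 1L) %% L + 1L
    shifted <- spec$amp[, idx, drop = FALSE]
    for (b in seq_len(nrow(shifted))) {
      null_mat[b, p] <- mi_from_bins(bins, shifted[b, ], n_bins)
    }
  }
  pac_result(spec, null_mat, "circular_shift", q)
}

#' Modulation index with a trial-order-shuffle null
#'
#' Controls for coupling induced by a stereotyped (evoked) waveform occurring
#' in every trial: per permutation the trial order of the phase epochs is
#' permuted (within-trial samples intact) and re-concatenated against the
#' unshuffled amplitude. Coupling that does not depend on the trial-specific
#' phase survives in the null, so only trial-specific coupling yields large z.
#'
#' @inheritParams mi_null_circular_shift
#' @return a `pac_result`.
#' @export
mi_null_trial_shuffle <- function(rec, events, window = c(0, 1),
                                  bank = pac_band_subset(), n_bins = 18,
                                  n_perm = 1000, q = 0.05, seed = NULL,
                                  channel = 1, stack = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- mi_spectrum(rec, events, window, bank, n_bins, channel, stack)
  n_trials <- nrow(spec$phase_epochs)
  if (n_trials < 5) stop("need at least 5 trials for the trial-shuffle null")
  null_mat <- matrix(0, nrow(spec$amp), n_perm)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n_trials)
    phase_p <- as.vector(t(spec$phase_epochs[ord, , drop = FALSE]))
    bins <- phase_bins(phase_p, n_bins)
    for (b in seq_len(nrow(spec$amp))) {
      null_mat[b, p] <- mi_from_bins(bins, spec$amp[b, ], n_bins)
    }
  }
  pac_result(spec, null_mat, "trial_shuffle", q)
}
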