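# Band-averaged time courses, pointwise condition tests, bootstrap stability
# maps, cluster-mass permutation timing statistics, and respiratory-phase-of-
# peak circular statistics.

#' Canonical frequency-band definitions
#'
#' theta 4-8 Hz, beta 13-30 Hz, gamma 30-150 Hz.
#'
#' @return named list of `c(lo, hi)` ranges in Hz.
#' @export
band_definitions <- function() {
  list(theta = c(4, 8), beta = c(13, 30), gamma = c(30, 150))
}

#' Average a trial tensor over a frequency band
#'
#' Unweighted mean over all filter-bank bands with `lo <= center <= hi`.
#'
#' @param trials a `trial_tensor`.
#' @param band `c(lo, hi)` in Hz, or a name from [band_definitions()].
#' @return trial x time matrix with the tensor's `time_axis` as an attribute.
#' @export
band_average <- function(trials, band) {
  if (is.character(band)) band <- band_definitions()[[band]]
  stopifnot(length(band) == 2, band[1] < band[2])
  sel <- trials$band_centers >= band[1] & trials$band_centers <= band[2]
  if (!any(sel)) stop("no filter-bank centers inside [", band[1], ", ", band[2], "] Hz")
  sub <- trials$amplitudes[, sel, , drop = FALSE]
  # mean over the band dimension, vectorized (apply() is too slow here)
  out <- colMeans(aperm(sub, c(2, 1, 3)))
  attr(out, "time_axis") <- trials$time_axis
  if (!is.null(trials$baseline)) {
    attr(out, "baseline") <- rowMeans(trials$baseline[, sel, drop = FALSE])
  }
  out
}

#' Percent change relative to baseline
#'
#' `(amplitude - baseline) / baseline`, elementwise per trial. Trials with a
#' non-positive baseline are flagged invalid (set to NA) with a warning.
#'
#' @param series trial x time matrix of raw amplitudes.
#' @param baseline_means per-trial baseline means (length = rows of `series`).
#' @return trial x time matrix of fractional change.
#' @export
percent_change <- function(series, baseline_means) {
  stopifnot(length(baseline_means) == nrow(series))
  bad <- !(baseline_means > 0)
  if (any(bad)) {
    warning(sum(bad), " trial(s) with non-positive baseline flagged invalid")
    baseline_means[bad] <- NA
  }
  sweep(sweep(series, 1, baseline_means), 1, baseline_means, "/")
}

# vectorized per-column one-sample / paired t statistics
col_t_stats <- function(mat) {
  n <- nrow(mat)
  m <- colMeans(mat)
  s <- sqrt(pmax(colSums(mat^2) - n * m^2, 0) / (n - 1))
  list(t = m / (s / sqrt(n)), df = n - 1)
}

#' Pointwise paired condition test with FDR correction
#'
#' Paired t test at each time point between two matched trial x time series,
#' Benjamini-Hochberg corrected across time points; reports the first and
#' last significant time (onset/offset latency).
#'
#' @param seriesA,seriesB trial x time matrices with equal dimensions and
#'   matched trial order.
#' @param q FDR level.
#' @param time_axis optional time axis (taken from `seriesA`'s attribute if
#'   present).
#' @return list with `t`, `p`, `p_adj`, `mask`, `onset`, `offset` (s, NA when
#'   nothing is significant).
#' @export
pointwise_condition_test <- function(seriesA, seriesB, q = 0.05,
                                     time_axis = attr(seriesA, "time_axis")) {
  stopifnot(all(dim(seriesA) == dim(seriesB)))
  if (nrow(seriesA) < 3) stop("need at least 3 trial pairs")
  d <- seriesA - seriesB
  st <- col_t_stats(d)
  # zero-variance columns: t is 0 for identical data, +-Inf for a constant
  # nonzero difference
  degen <- !is.finite(st$t)
  st$t[degen] <- sign(colMeans(d))[degen] * Inf
  st$t[degen & colMeans(d) == 0] <- 0
  p <- 2 * stats::pt(-abs(st$t), df = st$df)
  p_adj <- stats::p.adjust(p, method = "BH")
  mask <- p_adj < q
  if (is.null(time_axis)) time_axis <- seq_len(ncol(seriesA))
  list(t = st$t, p = p, p_adj = p_adj, mask = mask,
       onset = if (any(mask)) time_axis[which(mask)[1]] else NA_real_,
       offset = if (any(mask)) time_axis[max(which(mask))] else NA_real_)
}

#' Bootstrap stability map of a band time course
#'
#' Each row is the trial-mean time course of one bootstrap resample (trials
#' drawn with replacement).
#'
#' @param series trial x time matrix (typically z-normalized).
#' @param reps bootstrap repetitions (default 2000).
#' @param seed optional RNG seed.
#' @return reps x time matrix.
#' @export
bootstrap_band_map <- function(series, reps = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(series)
  if (n < 10) stop("need at least 10 trials")
  out <- matrix(0, reps, ncol(series))
  for (r in seq_len(reps)) {
    out[r, ] <- colMeans(series[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }
  out
}

cluster_masses <- function(t_vals, t_thresh) {
  supra <- abs(t_vals) > t_thresh
  if (!any(supra)) {
    return(data.frame(start = integer(0), end = integer(0), mass = numeric(0)))
  }
  # maximal runs of supra-threshold points with a consistent sign
  state <- ifelse(supra, sign(t_vals), 0)
  grp <- cumsum(c(1, diff(state) != 0))
  idx <- which(supra)
  g <- grp[idx]
  data.frame(start = as.integer(tapply(idx, g, min)),
             end = as.integer(tapply(idx, g, max)),
             mass = as.numeric(tapply(t_vals[idx], g, sum)))
}

#' Cluster-mass permutation test on a band time course
#'
#' One-sample t test against 0 at each time point; contiguous supra-threshold
#' runs (initial threshold `p_cluster`, two-sided, sign-consistent) form
#' clusters with mass = sum of t values. Null: on each permutation every
#' trial is circularly shifted in time by its own random offset (destroying
#' the alignment while preserving each trial's autocorrelation); the maximal
#' absolute cluster mass is recorded. A cluster is significant when its
#' |mass| exceeds the 95th percentile of the null (cluster-corrected
#' p < 0.05); reported per-cluster p values are permutation tail
#' probabilities. (Shifting only a random subset of trials leaves the null
#' correlated with the observed alignment, which is both conservative and
#' unable to detect effects that occupy most of the epoch.)
#'
#' @param series trial x time matrix (typically z-normalized amplitude).
#' @param p_cluster initial clustering threshold (default 0.01).
#' @param n_perm permutations (default 10000).
#' @param seed optional RNG seed.
#' @param time_axis optional time axis (defaults to the matrix attribute).
#' @return a `cluster_result`: data.frame `clusters` (start_s, end_s, mass,
#'   p, significant), plus `t`, `threshold_t`, `null_max_mass`, `mass_threshold`.
#' @export
cluster_mass_test <- function(series, p_cluster = 0.01, n_perm = 10000,
                              seed = NULL, time_axis = attr(series, "time_axis")) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(series); n_time <- ncol(series)
  if (n < 10) stop("need at least 10 trials")
  if (is.null(time_axis)) time_axis <- seq_len(n_time)
  t_thresh <- stats::qt(1 - p_cluster / 2, df = n - 1)
  obs_t <- col_t_stats(series)$t
  obs_clusters <- cluster_masses(obs_t, t_thresh)

  null_max <- numeric(n_perm)
  perm <- series
  for (p in seq_len(n_perm)) {
    offs <- sample.int(n_time - 1L, n, replace = TRUE)
    for (j in seq_len(n)) {
      perm[j, ] <- shift_vector(series[j, ], offs[j])
    }
    cm <- cluster_masses(col_t_stats(perm)$t, t_thresh)
    null_max[p] <- if (nrow(cm)) max(abs(cm$mass)) else 0
  }
  mass_threshold <- stats::quantile(null_max, 0.95, names = FALSE)
  p_vals <- vapply(obs_clusters$mass, function(m) {
    (sum(null_max >= abs(m)) + 1) / (n_perm + 1)
  }, numeric(1))
  clusters <- data.frame(
    start_s = time_axis[obs_clusters$start],
    end_s = time_axis[obs_clusters$end],
    mass = obs_clusters$mass, p = p_vals,
    significant = abs(obs_clusters$mass) > mass_threshold
  )
  structure(list(clusters = clusters, t = obs_t, threshold_t = t_thresh,
                 null_max_mass = null_max, mass_threshold = mass_threshold,
                 n_perm = n_perm, time_axis = time_axis),
            class = "cluster_result")
}

#' Cluster-mass test with an event-level permutation null
#'
#' Variant of [cluster_mass_test()] that works from the continuous band
#' amplitude: trials are cut at the sniff times and z-normalized to their
#' pre-cue baselines, and the null re-cuts every trial at an independently
#' circularly-shifted event time (wrapping at the recording ends) with its
#' baseline shifted identically, re-running the identical processing. Unlike
#' shifting within the epoch, a re-cut null epoch carries no event-locked
#' signal at all, so effects occupying most of the epoch remain detectable.
#'
#' @param stack an [amplitude_stack()].
#' @param events event data.frame (`sniff_time_s`, `cue_time_s`).
#' @param band `c(lo, hi)` in Hz or a [band_definitions()] name.
#' @param window epoch window (s).
#' @param baseline_window baseline window (s, relative to cue onset).
#' @param p_cluster initial clustering threshold.
#' @param n_perm permutations.
#' @param decimate integer decimation factor applied to the band series
#'   (moving-average then subsample) before testing; cluster timing
#'   resolution drops accordingly.
#' @param seed optional RNG seed.
#' @return a `cluster_result` (see [cluster_mass_test()]).
#' @export
cluster_mass_recut <- function(stack, events, band, window = c(-2, 4),
                               baseline_window = c(-0.55, -0.05),
                               p_cluster = 0.01, n_perm = 10000,
                               decimate = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(band)) band <- band_definitions()[[band]]
  sel <- stack$band_centers >= band[1] & stack$band_centers <= band[2]
  if (!any(sel)) stop("no filter-bank centers inside [", band[1], ", ", band[2], "] Hz")
  v <- colMeans(stack$amplitudes[sel, , drop = FALSE])
  decimate <- max(1L, as.integer(decimate))
  if (decimate > 1L) {
    v <- moving_average(v, decimate)[seq(1, length(v), by = decimate)]
  }
  fs <- stack$sampling_rate / decimate
  N <- length(v)
  n <- nrow(events)
  if (n < 10) stop("need at least 10 trials")
  t_thresh <- stats::qt(1 - p_cluster / 2, df = n - 1)

  rel_ep <- seq_len(as.integer(round((window[2] - window[1]) * fs))) - 1L
  rel_bl <- seq_len(max(1L, as.integer(round(diff(baseline_window) * fs)))) - 1L
  ep_start <- as.integer(round((events$sniff_time_s + window[1] - stack$start_time) * fs)) + 1L
  bl_start <- as.integer(round((events$cue_time_s + baseline_window[1] - stack$start_time) * fs)) + 1L
  if (any(ep_start < 1 | ep_start + length(rel_ep) - 1L > N) ||
      any(bl_start < 1)) {
    stop("event or baseline window outside the recording")
  }
  z_epochs <- function(offsets) {
    ei <- (outer(ep_start + offsets, rel_ep, "+") - 1L) %% N + 1L
    bi <- (outer(bl_start + offsets, rel_bl, "+") - 1L) %% N + 1L
    ep <- matrix(v[ei], n)
    bl <- matrix(v[bi], n)
    m <- rowMeans(bl)
    s <- sqrt(pmax(rowMeans(bl^2) - m^2, 1e-300))
    (ep - m) / s
  }
  obs_t <- col_t_stats(z_epochs(integer(n)))$t
  obs_clusters <- cluster_masses(obs_t, t_thresh)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    cm <- cluster_masses(col_t_stats(z_epochs(sample.int(N - 1L, n, replace = TRUE)))$t,
                         t_thresh)
    null_max[p] <- if (nrow(cm)) max(abs(cm$mass)) else 0
  }
  mass_threshold <- stats::quantile(null_max, 0.95, names = FALSE)
  time_axis <- window[1] + rel_ep / fs
  clusters <- data.frame(
    start_s = time_axis[obs_clusters$start],
    end_s = time_axis[obs_clusters$end],
    mass = obs_clusters$mass,
    p = vapply(obs_clusters$mass, function(m) {
      (sum(null_max >= abs(m)) + 1) / (n_perm + 1)
    }, numeric(1)),
    significant = abs(obs_clusters$mass) > mass_threshold
  )
  structure(list(clusters = clusters, t = obs_t, threshold_t = t_thresh,
                 null_max_mass = null_max, mass_threshold = mass_threshold,
                 n_perm = n_perm, time_axis = time_axis),
            class = "cluster_result")
}

shift_vector <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d significant (mass threshold %.1f)\n",
              nrow(x$clusters), sum(x$clusters$significant), x$mass_threshold))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Respiratory phase of bootstrapped amplitude peaks
#'
#' On each repetition, trials are resampled with replacement (keeping the
#' pairwise LFP/respiration relationship), the band amplitude and respiration
#' epochs are averaged, the amplitude is smoothed (50 ms kernel), the peak
#' time inside the search window is found (ties broken by earliest time), and
#' the respiratory phase of the averaged breathing signal at that time is
#' recorded. The collected angles are summarized as a [phase_stats()] object.
#'
#' @param series trial x time band-amplitude matrix.
#' @param resp_epochs trial x time respiration matrix on the same time axis.
#' @param time_axis time axis in seconds (relative to sniff onset).
#' @param sampling_rate Hz.
#' @param reps bootstrap repetitions (default 1000).
#' @param smooth_s smoothing kernel (s).
#' @param search_window window searched for the amplitude peak (default
#'   `[0, 4]` s post-sniff).
#' @param seed optional RNG seed.
#' @return a `phase_stats` object (see [phase_stats()]).
#' @export
peak_phase_bootstrap <- function(series, resp_epochs, time_axis, sampling_rate,
                                 reps = 1000, smooth_s = 0.05,
                                 search_window = c(0, 4), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(series) == nrow(resp_epochs),
            ncol(series) == ncol(resp_epochs))
  n <- nrow(series)
  k <- kernel_samples(smooth_s, sampling_rate)
  in_window <- which(time_axis >= search_window[1] & time_axis <= search_window[2])
  angles <- rep(NA_real_, reps)
  n_skipped <- 0L
  for (r in seq_len(reps)) {
    rows <- sample.int(n, n, replace = TRUE)
    amp <- moving_average(colMeans(series[rows, , drop = FALSE]), k)
    if (stats::sd(amp[in_window]) == 0) { n_skipped <- n_skipped + 1L; next }
    peak_idx <- in_window[which.max(amp[in_window])]
    resp_mean <- colMeans(resp_epochs[rows, , drop = FALSE])
    phase <- respiratory_phase(resp_mean)
    angles[r] <- phase[peak_idx]
  }
  if (n_skipped) warning(n_skipped, " repetition(s) with a flat series skipped")
  phase_stats(angles[!is.na(angles)])
}
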