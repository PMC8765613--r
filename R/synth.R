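# Synthetic sniff-locked LFP generator.
#
# Emulates the raw structure the analysis assumes: a quasi-periodic nasal
# airflow trace, an event table of cued odor sniffs with long intertrial
# intervals, and a multichannel 1/f LFP in which odor trials carry oscillatory
# bursts (early theta, later beta and gamma) whose parameters are known ground
# truth. The gamma burst envelope can be locked to the theta carrier phase
# (a(t) = A * (1 + kappa * cos(phase_theta(t)))), and correct trials scale the
# accuracy-linked (beta/gamma) burst amplitudes.

#' Specification of one oscillatory burst
#'
#' @param name band name (informational).
#' @param center_freq carrier frequency in Hz; must be below Nyquist.
#' @param onset_latency burst onset in seconds relative to sniff onset
#'   (negative = before the sniff).
#' @param duration burst duration in seconds (> 0); the envelope is a Hann
#'   window over this span.
#' @param amplitude peak envelope amplitude in the recording's units; `NULL`
#'   (default) means "snr times the band-limited noise standard deviation",
#'   resolved when the recording is generated.
#' @param snr target peak signal-to-noise ratio used when `amplitude` is NULL.
#' @param respiratory_lock `"none"` or `"theta_phase"`; the latter multiplies
#'   the envelope by `1 + pac_depth * cos(theta phase)`.
#' @param accuracy_linked if TRUE the amplitude is multiplied by the config's
#'   `accuracy_gain` on correct trials.
#' @return a `burst_spec` list.
#' @export
burst_spec <- function(name, center_freq, onset_latency, duration,
                       amplitude = NULL, snr = 3,
                       respiratory_lock = c("none", "theta_phase"),
                       accuracy_linked = FALSE) {
  respiratory_lock <- match.arg(respiratory_lock)
  stopifnot(duration > 0, center_freq > 0)
  structure(list(name = name, center_freq = center_freq,
                 onset_latency = onset_latency, duration = duration,
                 amplitude = amplitude, snr = snr,
                 respiratory_lock = respiratory_lock,
                 accuracy_linked = accuracy_linked),
            class = "burst_spec")
}

default_band_specs <- function() {
  # carrier frequencies and onset latencies follow the odor-response peaks
  # (theta 4.72 Hz from -126 ms, gamma 84.94 Hz from +116 ms, beta 18.98 Hz
  # from +144 ms); theta lasts 1.2 s so its phase physically spans the 1 s
  # coupling window, beta persists into exhale.
  list(
    theta = burst_spec("theta", 4.72, -0.126, 1.2),
    beta  = burst_spec("beta", 18.98, 0.144, 3.4, accuracy_linked = TRUE),
    gamma = burst_spec("gamma", 84.94, 0.116, 1.9,
                       respiratory_lock = "theta_phase", accuracy_linked = TRUE)
  )
}

#' Configuration of the synthetic world
#'
#' Defaults reproduce the statistical structure of a cued odor-identification
#' session: ~21.3 s intertrial intervals, 3-7 s cue-to-sniff delays, 4 s
#' breathing with asymmetric inhale/exhale, 1/f^2 background, sniff-locked
#' bursts, kappa = 0.8 theta-phase coupling of the gamma envelope, and a 1.5x
#' beta/gamma amplitude gain on correct trials (78% of trials correct).
#'
#' @param sampling_rate Hz.
#' @param n_trials number of odor trials.
#' @param intertrial_interval c(mean, jitter) in seconds; intervals are drawn
#'   uniformly from mean +- jitter.
#' @param breath_period c(mean, sd) of the breath period in seconds.
#' @param cue_to_sniff_delay c(lo, hi) range of the cue-to-sniff delay (s).
#' @param band_specs list of [burst_spec()] objects injected on odor trials.
#' @param pac_depth coupling depth kappa in `[0, 1]` for theta-phase-locked bursts.
#' @param noise_exponent 1/f slope beta of the background (power ~ f^-beta).
#' @param noise_sd standard deviation of the background noise.
#' @param evoked_amplitude amplitude of the phase-locked (identical every
#'   trial) slow evoked transient added at sniff onset.
#' @param p_correct probability a trial is correct.
#' @param accuracy_gain multiplicative amplitude factor applied to
#'   accuracy-linked bursts on correct trials.
#' @param amplitude_jitter_sd lognormal sd of per-trial burst amplitude
#'   variability (free parameter; the source data do not constrain it).
#' @param n_decoy_channels burst-free channels added to exercise re-referencing.
#' @param inhale_fraction fraction of the breath period spent inhaling.
#' @param seed integer seed; identical seed + config gives identical output.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(sampling_rate = 500, n_trials = 323,
                         intertrial_interval = c(21.3, 4),
                         breath_period = c(4, 0.5),
                         cue_to_sniff_delay = c(3, 7),
                         band_specs = default_band_specs(),
                         pac_depth = 0.8, noise_exponent = 2, noise_sd = 1,
                         evoked_amplitude = 0.3, p_correct = 0.78,
                         accuracy_gain = 1.5, amplitude_jitter_sd = 0.25,
                         n_decoy_channels = 3, inhale_fraction = 0.4,
                         seed = 1) {
  cfg <- list(sampling_rate = sampling_rate, n_trials = n_trials,
              intertrial_interval = intertrial_interval,
              breath_period = breath_period,
              cue_to_sniff_delay = cue_to_sniff_delay,
              band_specs = band_specs, pac_depth = pac_depth,
              noise_exponent = noise_exponent, noise_sd = noise_sd,
              evoked_amplitude = evoked_amplitude, p_correct = p_correct,
              accuracy_gain = accuracy_gain,
              amplitude_jitter_sd = amplitude_jitter_sd,
              n_decoy_channels = n_decoy_channels,
              inhale_fraction = inhale_fraction, seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$sampling_rate > 0, cfg$n_trials >= 1)
  if (cfg$breath_period[1] <= 0) stop("breath_period mean must be > 0")
  if (cfg$breath_period[2] < 0) stop("breath_period sd must be >= 0")
  if (cfg$pac_depth < 0 || cfg$pac_depth > 1) stop("pac_depth must be in [0, 1]")
  if (cfg$p_correct < 0 || cfg$p_correct > 1) stop("p_correct must be in [0, 1]")
  if (cfg$intertrial_interval[1] <= 0) stop("intertrial interval must be > 0")
  if (any(cfg$cue_to_sniff_delay <= 0) ||
      cfg$cue_to_sniff_delay[2] < cfg$cue_to_sniff_delay[1]) {
    stop("cue_to_sniff_delay must be an increasing positive range")
  }
  if (cfg$inhale_fraction <= 0 || cfg$inhale_fraction >= 1) {
    stop("inhale_fraction must be in (0, 1)")
  }
  nyq <- cfg$sampling_rate / 2
  for (b in cfg$band_specs) {
    if (b$center_freq >= nyq) stop("burst center_freq must be below Nyquist")
    if (b$duration <= 0) stop("burst duration must be > 0")
  }
  invisible(cfg)
}

# ---- respiration ------------------------------------------------------------

# area-balanced asymmetric breath waveform: positive half-sine over the inhale,
# negative half-sine (scaled so each breath integrates to zero) over the exhale;
# the rising zero crossing is the inhale onset.
breath_waveform <- function(onsets, periods, inhale_fraction, fs, n_samples) {
  x <- numeric(n_samples)
  for (i in seq_along(onsets)) {
    ti <- periods[i] * inhale_fraction
    te <- periods[i] - ti
    i0 <- as.integer(round(onsets[i] * fs)) + 1L
    i1 <- min(as.integer(round((onsets[i] + periods[i]) * fs)), n_samples)
    if (i0 > n_samples) break
    idx <- i0:i1
    tau <- (idx - 1) / fs - onsets[i]
    x[idx] <- ifelse(tau < ti,
                     sin(pi * tau / ti),
                     -(ti / te) * sin(pi * (tau - ti) / te))
  }
  x
}

#' Generate a synthetic respiration trace
#'
#' Breath periods are drawn from `N(mean, sd)` (truncated at half the mean);
#' each breath is an asymmetric, area-balanced half-sine pair so that inhale
#' onsets coincide with rising zero crossings and the trace is mean-centered.
#'
#' @param config a [synth_config()].
#' @param n_breaths number of breaths (default: enough to span the config's
#'   trial schedule).
#' @return list with `trace`, `sampling_rate`, `inhale_onsets` (s),
#'   `periods` (s), and `start_time`.
#' @export
generate_respiration <- function(config, n_breaths = NULL) {
  validate_synth_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(n_breaths)) {
    n_breaths <- ceiling((config$n_trials * config$intertrial_interval[1] + 30) /
                           config$breath_period[1])
  }
  periods <- draw_breath_periods(config, n_breaths)
  onsets <- c(0, cumsum(periods[-n_breaths]))
  fs <- config$sampling_rate
  n_samples <- as.integer(ceiling((sum(periods)) * fs))
  x <- breath_waveform(onsets, periods, config$inhale_fraction, fs, n_samples)
  x <- x - mean(x)
  list(trace = x, sampling_rate = fs, inhale_onsets = onsets,
       periods = periods, start_time = 0)
}

draw_breath_periods <- function(config, n) {
  p <- stats::rnorm(n, config$breath_period[1], config$breath_period[2])
  pmax(p, config$breath_period[1] / 2)
}

# ---- recording --------------------------------------------------------------

# 1/f^beta background by spectral shaping of white noise; exact slope control.
one_over_f_noise <- function(n, fs, beta, sd_target, f_floor = 0.5) {
  nfft <- stats::nextn(n, c(2, 3, 5))  # fast FFT length; trimmed below
  w <- stats::rnorm(nfft)
  W <- stats::fft(w)
  f <- seq(0, nfft - 1) / nfft * fs
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  g <- pmax(f, f_floor)^(-beta / 2)
  g[1] <- 0                            # remove DC
  x <- Re(stats::fft(W * g, inverse = TRUE) / nfft)[seq_len(n)]
  x <- x - mean(x)
  if (sd_target == 0) return(numeric(n))
  x / stats::sd(x) * sd_target
}

# theoretical sd of the 1/f^beta background restricted to [lo, hi] Hz,
# after normalisation of the broadband trace to sd_total
band_noise_sd <- function(lo, hi, beta, sd_total, fs, f_floor = 0.5) {
  nyq <- fs / 2
  pw <- function(a, b) {
    if (abs(beta - 1) < 1e-9) log(b / a) else (a^(1 - beta) - b^(1 - beta)) / (beta - 1)
  }
  frac <- pw(max(lo, f_floor), min(hi, nyq)) / pw(f_floor, nyq)
  sd_total * sqrt(max(frac, 0))
}

resolve_burst_amplitude <- function(spec, config) {
  if (!is.null(spec$amplitude)) return(spec$amplitude)
  sdb <- band_noise_sd(spec$center_freq * 0.8, spec$center_freq * 1.2,
                       config$noise_exponent, config$noise_sd,
                       config$sampling_rate)
  spec$snr * sdb
}

# fixed-shape slow evoked transient (identical on every trial): one-sided
# gamma-function-like wave, ~2 Hz energy, 1 s long
evoked_waveform <- function(fs) {
  t <- seq(0, 1, by = 1 / fs)
  w <- t * exp(-t / 0.12)
  w <- w / max(w)
  w * sin(2 * pi * 2 * t)
}

#' Generate a synthetic sniff-locked LFP recording
#'
#' Builds a full session: respiration, an event table (odor, no-odor and, when
#' breaths fall between cue and sniff, attended no-odor events), a multichannel
#' LFP (one burst-carrying channel of interest plus burst-free decoys), and a
#' ground-truth table of injected per-trial burst parameters.
#'
#' @param config a [synth_config()].
#' @return list with elements `recording` ([continuous_recording()]), `events`
#'   (data.frame: trial, cue_time_s, sniff_time_s, condition, correct),
#'   `truth` (one row per odor trial: injected amplitudes, burst windows,
#'   coupling depth, correct flag), `respiration` (as from
#'   [generate_respiration()]) and `config`.
#' @export
generate_recording <- function(config) {
  validate_synth_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$sampling_rate
  iti <- config$intertrial_interval
  epoch_span <- 6.5   # [-2, 4] s epochs plus margin
  if (iti[1] - iti[2] < epoch_span) {
    stop("intertrial interval shorter than the epoch span: trial windows would overlap")
  }

  # --- breath schedule: draw breaths, designate sniff breaths by the ITI ----
  n_breaths <- ceiling((config$n_trials + 2) * (iti[1] + iti[2]) /
                         (0.9 * config$breath_period[1])) + 50
  periods <- draw_breath_periods(config, n_breaths)
  onsets <- 12 + c(0, cumsum(periods[-n_breaths]))  # 12 s lead-in for cue + epoch
  sniff_idx <- integer(config$n_trials)
  target <- onsets[1]
  for (k in seq_len(config$n_trials)) {
    i <- which(onsets >= target)[1]
    if (is.na(i)) stop("internal: breath schedule too short")
    sniff_idx[k] <- i
    target <- onsets[i] + stats::runif(1, iti[1] - iti[2], iti[1] + iti[2])
  }
  sniff_times <- onsets[sniff_idx]
  cue_times <- sniff_times - stats::runif(config$n_trials,
                                          config$cue_to_sniff_delay[1],
                                          config$cue_to_sniff_delay[2])
  correct <- stats::runif(config$n_trials) < config$p_correct

  total_dur <- sniff_times[config$n_trials] + 10
  n_samples <- as.integer(ceiling(total_dur * fs))

  # --- respiration over the same clock -------------------------------------
  resp <- breath_waveform(onsets, periods, config$inhale_fraction, fs, n_samples)
  resp <- resp - mean(resp)

  # --- secondary event classes ---------------------------------------------
  # no-odor: the inhalation nearest the midpoint of each intertrial gap
  no_odor <- numeric(0)
  for (k in seq_len(config$n_trials - 1)) {
    mid <- (sniff_times[k] + sniff_times[k + 1]) / 2
    cand <- onsets[onsets > sniff_times[k] + 5 & onsets < cue_times[k + 1] - 1]
    if (length(cand)) no_odor <- c(no_odor, cand[which.min(abs(cand - mid))])
  }
  # attended no-odor: inhalations strictly between cue and odor sniff
  attended <- numeric(0)
  for (k in seq_len(config$n_trials)) {
    cand <- onsets[onsets > cue_times[k] + 0.2 & onsets < sniff_times[k] - 1]
    attended <- c(attended, cand)
  }

  # --- LFP channels ----------------------------------------------------------
  n_ch <- 1L + config$n_decoy_channels
  lfp <- matrix(0, n_ch, n_samples)
  for (ch in seq_len(n_ch)) {
    lfp[ch, ] <- one_over_f_noise(n_samples, fs, config$noise_exponent,
                                  config$noise_sd)
  }

  specs <- config$band_specs
  amps <- vapply(specs, resolve_burst_amplitude, numeric(1), config = config)
  evoked <- evoked_waveform(fs) * config$evoked_amplitude

  truth_rows <- vector("list", config$n_trials)
  theta_spec <- specs[["theta"]]
  for (k in seq_len(config$n_trials)) {
    st <- sniff_times[k]
    # shared theta carrier phase offset for this trial (used by locked bursts)
    phi0_theta <- stats::runif(1, 0, 2 * pi)
    trial_amp <- numeric(length(specs))
    names(trial_amp) <- names(specs)
    win <- matrix(NA_real_, length(specs), 2,
                  dimnames = list(names(specs), c("onset_s", "offset_s")))
    for (j in seq_along(specs)) {
      b <- specs[[j]]
      a <- amps[j] * stats::rlnorm(1, 0, config$amplitude_jitter_sd)
      if (b$accuracy_linked && correct[k]) a <- a * config$accuracy_gain
      t0 <- st + b$onset_latency
      i0 <- as.integer(round(t0 * fs)) + 1L
      len <- as.integer(round(b$duration * fs))
      idx <- i0:(i0 + len - 1L)
      idx <- idx[idx >= 1 & idx <= n_samples]
      tau <- (idx - 1) / fs - t0
      env <- a * 0.5 * (1 - cos(2 * pi * tau / b$duration))     # Hann envelope
      theta_phase <- 2 * pi * (if (is.null(theta_spec)) 5 else theta_spec$center_freq) *
        ((idx - 1) / fs - st) + phi0_theta
      if (b$respiratory_lock == "theta_phase") {
        env <- env * (1 + config$pac_depth * cos(theta_phase))
      }
      phi0 <- if (identical(b$name, "theta")) phi0_theta else stats::runif(1, 0, 2 * pi)
      carrier_phase <- 2 * pi * b$center_freq * ((idx - 1) / fs - st) + phi0
      lfp[1, idx] <- lfp[1, idx] + env * cos(carrier_phase)
      trial_amp[j] <- a
      win[j, ] <- c(t0, t0 + b$duration)
    }
    # phase-locked (identical every trial) evoked transient
    i0 <- as.integer(round(st * fs)) + 1L
    idx <- i0:(i0 + length(evoked) - 1L)
    keep <- idx >= 1 & idx <= n_samples
    lfp[1, idx[keep]] <- lfp[1, idx[keep]] + evoked[keep]

    truth_rows[[k]] <- data.frame(
      trial = k, sniff_time_s = st, correct = correct[k],
      theta_phi0 = phi0_theta,
      t(trial_amp),
      theta_onset_s = win["theta", 1], theta_offset_s = win["theta", 2],
      beta_onset_s = win["beta", 1], beta_offset_s = win["beta", 2],
      gamma_onset_s = win["gamma", 1], gamma_offset_s = win["gamma", 2],
      pac_depth = config$pac_depth
    )
  }
  truth <- do.call(rbind, truth_rows)

  events <- rbind(
    data.frame(cue_time_s = cue_times, sniff_time_s = sniff_times,
               condition = "odor", correct = correct),
    if (length(no_odor)) data.frame(
      cue_time_s = no_odor - mean(config$cue_to_sniff_delay),
      sniff_time_s = no_odor, condition = "no_odor", correct = NA),
    if (length(attended)) data.frame(
      cue_time_s = vapply(attended, function(t) max(cue_times[cue_times < t]), numeric(1)),
      sniff_time_s = attended, condition = "attended_no_odor", correct = NA)
  )
  events <- events[order(events$sniff_time_s), ]
  events <- data.frame(trial = seq_len(nrow(events)), events, row.names = NULL)

  rec <- continuous_recording(
    lfp, fs, c("piriform", paste0("decoy", seq_len(config$n_decoy_channels))))
  list(recording = rec, events = events, truth = truth,
       respiration = list(trace = resp, sampling_rate = fs,
                          inhale_onsets = onsets[onsets + periods <= total_dur],
                          periods = periods[onsets + periods <= total_dur],
                          start_time = 0),
       config = config)
}
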