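# Synthetic generator: respiration, recording, ground truth, reproducibility.

test_that("config validation rejects out-of-range parameters", {
  expect_error(synth_config(pac_depth = 1.5), "pac_depth")
  expect_error(synth_config(p_correct = -0.1), "p_correct")
  expect_error(synth_config(breath_period = c(-1, 0.5)), "breath_period")
  expect_error(synth_config(breath_period = c(4, -0.5)), "sd")
  expect_error(synth_config(band_specs = list(burst_spec("x", 400, 0, 1))),
               "Nyquist")
  expect_error(burst_spec("x", 10, 0, -1), "duration")
})

test_that("respiration is zero-mean, periodic in the no-jitter limit, and has
           the requested period distribution", {
  # deterministic limit: sd 0 gives onsets exactly 4 s apart
  cfg0 <- synth_config(n_trials = 4, breath_period = c(4, 0), seed = 1)
  r0 <- generate_respiration(cfg0, n_breaths = 12)
  expect_equal(diff(r0$inhale_onsets), rep(4, 11), tolerance = 1e-12)
  # drawn periods behave like the stated distribution
  cfg <- synth_config(n_trials = 4, breath_period = c(4, 0.5), seed = 2)
  r <- generate_respiration(cfg, n_breaths = 200)
  se <- 0.5 / sqrt(200)
  expect_lt(abs(mean(r$periods) - 4), 3 * se)
  # mean-centered by construction
  expect_lt(abs(mean(r$trace)), 1e-10 * stats::sd(r$trace))
  # inhale onsets sit on rising zero crossings of the trace
  fs <- r$sampling_rate
  idx <- round(r$inhale_onsets[2:10] * fs) + 1
  expect_true(all(r$trace[idx + 3] > r$trace[pmax(idx - 3, 1)]))
})

test_that("identical seed and config give bit-identical output", {
  cfg <- synth_config(n_trials = 6, seed = 11)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
})

test_that("ground truth reflects the stated burst timing and event causality", {
  sim <- fix_sim()
  # theta window (from -126 ms) precedes the beta window (from +144 ms)
  expect_true(all(sim$truth$theta_onset_s < sim$truth$beta_onset_s))
  expect_true(all(sim$truth$theta_onset_s - sim$truth$sniff_time_s + 0.126 <
                    1e-9))
  # cue precedes sniff within the configured delay range
  odor <- sim$events[sim$events$condition == "odor", ]
  delay <- odor$sniff_time_s - odor$cue_time_s
  expect_true(all(delay >= 3 & delay <= 7))
  # intertrial intervals respect the configured floor
  expect_true(all(diff(odor$sniff_time_s) >= 21.3 - 4 - 1e-9))
  expect_equal(nrow(sim$truth), 20)
  # overlap guard
  expect_error(generate_recording(synth_config(n_trials = 4,
                                               intertrial_interval = c(5, 1))),
               "overlap")
})

test_that("accuracy_gain = 1 leaves correct and incorrect amplitudes alike", {
  cfg <- synth_config(n_trials = 40, accuracy_gain = 1, seed = 21,
                      p_correct = 0.5)
  sim <- generate_recording(cfg)
  for (band in c("theta", "beta", "gamma")) {
    a <- sim$truth[[band]][sim$truth$correct]
    b <- sim$truth[[band]][!sim$truth$correct]
    pooled <- stats::sd(sim$truth[[band]])
    expect_lt(abs(mean(a) - mean(b)), pooled)
  }
})

test_that("gamma envelope is coupled to theta phase only when pac_depth > 0", {
  # per trial, the envelope-weighted mean theta phase (preferred phase) is a
  # single quasi-independent observation; across trials the preferred phases
  # are uniform under kappa = 0 (random theta phase offset per trial) and
  # pinned near 0 under coupling, so the Rayleigh test is calibrated here
  preferred_phases <- function(seed, kappa, n_trials = 12) {
    cfg <- synth_config(n_trials = n_trials, pac_depth = kappa, seed = seed,
                        noise_sd = 0.05, evoked_amplitude = 0)
    sim <- generate_recording(cfg)
    rec <- sim$recording
    fs <- rec$sampling_rate
    hg <- odorosc:::fir_design(fs, "bandpass", c(70, 100))
    env <- Mod(odorosc:::hilbert_analytic(odorosc:::filtfilt_fir(rec$samples[1, ], hg)))
    vapply(seq_len(nrow(sim$truth)), function(k) {
      s <- sim$truth$sniff_time_s[k]
      i <- (round((s + 0.3) * fs)):(round((s + 1) * fs))
      phi <- 2 * pi * 4.72 * ((i - 1) / fs - s) + sim$truth$theta_phi0[k]
      w <- env[i] - mean(env[i])
      Arg(sum(w * exp(1i * phi)))
    }, numeric(1))
  }
  p_null <- vapply(1:20, function(s) {
    rayleigh_test(preferred_phases(s, kappa = 0))$p
  }, numeric(1))
  expect_gte(mean(p_null > 0.05), 0.9)
  p_coupled <- vapply(1:3, function(s) {
    rayleigh_test(preferred_phases(s, kappa = 0.8))$p
  }, numeric(1))
  expect_true(all(p_coupled < 0.001))
})

test_that("background noise has the configured 1/f slope (Welch check)", {
  cfg <- synth_config(n_trials = 2, seed = 5)
  x <- odorosc:::one_over_f_noise(2^17, 500, 2, 1)
  sp <- stats::spec.pgram(stats::ts(x, frequency = 500), spans = 31,
                          plot = FALSE, taper = 0.1)
  sel <- sp$freq > 1 & sp$freq < 100
  slope <- stats::coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2]
  expect_lt(abs(slope - (-2)), 0.3)
})

test_that("full-depth coupling pins the phase-binned envelope minimum near pi", {
  # isolate the locked gamma burst (no noise, no other bursts) and bin its
  # analytic envelope by the ground-truth theta phase
  specs <- default_band_specs()
  specs$theta$amplitude <- 0
  specs$beta$amplitude <- 0
  specs$gamma$amplitude <- 1   # explicit: snr-relative sizing is 0 at zero noise
  cfg <- synth_config(n_trials = 6, pac_depth = 1, seed = 9, noise_sd = 0,
                      evoked_amplitude = 0, band_specs = specs,
                      amplitude_jitter_sd = 0)
  sim <- generate_recording(cfg)
  rec <- sim$recording
  fs <- rec$sampling_rate
  env <- Mod(odorosc:::hilbert_analytic(rec$samples[1, ]))
  idx <- phi <- numeric(0)
  for (k in seq_len(nrow(sim$truth))) {
    s <- sim$truth$sniff_time_s[k]
    i <- (round((s + 0.3) * fs)):(round((s + 1.5) * fs))
    idx <- c(idx, i)
    phi <- c(phi, 2 * pi * 4.72 * ((i - 1) / fs - s) + sim$truth$theta_phi0[k])
  }
  bins <- odorosc:::phase_bins(((phi + pi) %% (2 * pi)) - pi, 18)
  binned <- tapply(env[idx], bins, mean)
  centers <- -pi + (as.numeric(names(binned)) - 0.5) * 2 * pi / 18
  expect_lt(min(binned) / max(binned), 0.1)
  expect_gt(abs(centers[which.min(binned)]), pi - 0.8)
})
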