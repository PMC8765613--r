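# Phase-amplitude coupling: modulation index, MI spectrum, permutation nulls.

test_that("theta phase epochs have the right length and analytic slope", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  rec <- continuous_recording(sin(2 * pi * 6 * t), fs)
  ev <- data.frame(sniff_time_s = seq(3, 48, by = 5))
  ph <- theta_phase_epochs(rec, ev, window = c(0, 1))
  expect_equal(length(ph$phase), nrow(ev) * fs)      # 10 trials x 1 s
  expect_equal(dim(ph$epochs), c(10, fs))
  # unwrapped slope 2*pi*6 rad/s within 1%
  d <- diff(ph$epochs[1, ])
  d[d < -pi] <- d[d < -pi] + 2 * pi
  slope <- mean(d) * fs
  expect_equal(slope, 2 * pi * 6, tolerance = 0.01)
  # phase of a long sinusoid is uniform across the 18 bins
  bins <- odorosc:::phase_bins(ph$phase, 18)
  cs <- stats::chisq.test(tabulate(bins, 18))
  expect_gt(cs$p.value, 0.01)
  # out-of-range events are dropped
  expect_warning(theta_phase_epochs(rec, data.frame(sniff_time_s = 59.9)),
                 "dropped")
})

test_that("modulation index matches its closed forms and a brute-force oracle", {
  n_bins <- 18
  phase <- seq(-pi + 1e-9, pi, length.out = 36000)
  # constant amplitude: uniform distribution, MI = 0
  expect_equal(modulation_index(phase, rep(2, length(phase)), n_bins), 0,
               tolerance = 1e-12)
  # all amplitude in one bin: MI = 1
  amp1 <- as.numeric(phase > -pi & phase <= -pi + 2 * pi / n_bins)
  expect_equal(modulation_index(phase, amp1, n_bins), 1, tolerance = 1e-9)
  # independent brute-force evaluation of the binned KL formula
  amp <- 1 + cos(phase)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  p_oracle <- vapply(seq_len(n_bins), function(j) {
    sel <- phase > edges[j] & phase <= edges[j + 1]
    mean(amp[sel])
  }, numeric(1))
  p_oracle <- p_oracle / sum(p_oracle)
  mi_oracle <- (log(n_bins) + sum(p_oracle * log(p_oracle))) / log(n_bins)
  expect_equal(modulation_index(phase, amp, n_bins), mi_oracle,
               tolerance = 1e-6)
  # invariances: amplitude scaling and rotation by a whole bin width
  expect_equal(modulation_index(phase, 10 * amp, n_bins),
               modulation_index(phase, amp, n_bins))
  rot <- ((phase + 2 * pi / n_bins + pi) %% (2 * pi)) - pi
  expect_equal(modulation_index(rot, amp, n_bins),
               modulation_index(phase, amp, n_bins), tolerance = 1e-9)
  # monotone in coupling depth for the sinusoidal envelope family
  mi_k <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(k) {
    modulation_index(phase, 1 + k * cos(phase), n_bins)
  }, numeric(1))
  expect_true(all(diff(mi_k) > 0))
  expect_true(all(mi_k >= 0 & mi_k <= 1))
  # errors
  expect_error(modulation_index(phase, rep(0, length(phase))), "positive sum")
  expect_error(modulation_index(phase, -amp), "non-negative")
})

test_that("MI spectrum localizes injected gamma coupling across the 47 bands", {
  pr_env <- fix_processed()                      # kappa = 0.8 into ~85 Hz
  rec <- pr_env$rec
  odor <- pr_env$odor
  pac_bank <- pac_band_subset()
  stack <- fix_pac_stack()
  spec <- mi_spectrum(rec, odor, stack = stack)
  expect_length(spec$mi, 47)
  peak <- which.max(spec$mi)
  target <- which.min(abs(pac_bank$center - 85))
  expect_lte(abs(peak - target), 1)
  # uncoupled session: maximum raw MI falls below the coupled session's
  cfg0 <- synth_config(n_trials = 20, pac_depth = 0, seed = 3)
  sim0 <- generate_recording(cfg0)
  rec0 <- preprocess_recording(sim0$recording)
  odor0 <- sim0$events[sim0$events$condition == "odor", ]
  spec0 <- mi_spectrum(rec0, odor0, stack = amplitude_stack(rec0, pac_bank))
  expect_lt(max(spec0$mi), max(spec$mi))
  # circular-shift null flags the coupled band, not the bulk
  pr <- mi_null_circular_shift(rec, odor, n_perm = 200, seed = 5,
                               stack = stack)
  expect_true(any(pr$fdr_mask[(target - 2):(target + 2)]))
  expect_equal(length(pr$mi_raw), 47)
})

test_that("identity shift and identity permutation reproduce the raw MI", {
  set.seed(16)
  phase <- runif(5000, -pi, pi)
  amp <- 1 + 0.5 * cos(phase) + abs(rnorm(5000, sd = 0.1))
  bins <- odorosc:::phase_bins(phase, 18)
  mi_raw <- modulation_index(phase, amp, 18)
  # zero-offset circular shift
  expect_equal(odorosc:::mi_from_bins(bins, amp, 18), mi_raw)
  # identity trial ordering
  epochs <- matrix(phase, 10, byrow = TRUE)
  phase_id <- as.vector(t(epochs))
  expect_equal(modulation_index(phase_id, amp, 18), mi_raw)
})

test_that("trial-shuffle null distinguishes stereotyped from trial-specific
           coupling", {
  fs <- 200
  n_tr <- 12
  t1 <- seq(0, 1 - 1 / fs, by = 1 / fs)
  # stereotyped: the same phase ramp and the same amplitude modulation every
  # trial; shuffling trials changes nothing, so z stays near 0
  set.seed(18)
  jitter <- rnorm(n_tr, sd = 0.1)   # slight trial-to-trial phase wobble
  phase_tr <- matrix(rep(2 * pi * 5 * t1, n_tr), n_tr, byrow = TRUE) + jitter
  phase_tr <- ((phase_tr + pi) %% (2 * pi)) - pi
  amp_tr <- 1 + 0.8 * cos(phase_tr)
  stereo <- make_fake_pac(phase_tr, amp_tr)
  ns <- trial_shuffle_null(stereo, n_perm = 200, seed = 6)
  # shuffle-invariant construction: the null reproduces the raw MI (up to the
  # small deliberate phase wobble)
  expect_equal(ns$null_mean, ns$mi, tolerance = 0.05)
  # trial-specific: a random phase offset per trial carried by both signals;
  # shuffling breaks the pairing and z grows large
  set.seed(17)
  offs <- runif(n_tr, 0, 2 * pi)
  phase_sp <- ((sweep(phase_tr, 1, -offs) + pi) %% (2 * pi)) - pi
  amp_sp <- 1 + 0.8 * cos(phase_sp)
  spec <- make_fake_pac(phase_sp, amp_sp)
  ns2 <- trial_shuffle_null(spec, n_perm = 200, seed = 6)
  expect_gt(ns2$z, 4)
  expect_lt(ns2$null_mean, 0.5 * ns2$mi)
  # the exported null on generator data: trial-specific coupling (random
  # theta phase per trial) comes out significant near the injected band
  pr_env <- fix_processed()
  pac_bank <- pac_band_subset()
  pr <- mi_null_trial_shuffle(pr_env$rec, pr_env$odor, n_perm = 150, seed = 8,
                              stack = fix_pac_stack())
  target <- which.min(abs(pac_bank$center - 85))
  expect_gt(max(pr$mi_z[(target - 2):(target + 2)]), 3)
})
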