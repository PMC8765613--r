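# Filter bank, amplitude stack, epoching, baseline, permutation z-maps,
# evoked/induced decomposition.

test_that("the filter bank reproduces the published band arithmetic", {
  full <- build_filter_bank(n_kept = 100)
  expect_equal(full$center[1], 1)
  expect_equal(full$center[100], 200)
  expect_equal(full$width[1], 2)
  expect_equal(full$width[100], 50)
  bank <- build_filter_bank()
  expect_equal(nrow(bank), 95)
  expect_equal(round(bank$center[95], 2), 153.04)
  expect_true(all(diff(bank$center) > 0))
  pac <- pac_band_subset(bank)
  expect_equal(nrow(pac), 47)
  expect_equal(round(min(pac$center), 2), 13.05)
  expect_equal(round(max(pac$center), 2), 153.04)
})

test_that("amplitude extraction recovers sinusoid envelopes and scales with
           bandwidth on noise", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  bank <- build_filter_bank()
  rec <- continuous_recording(sin(2 * pi * 19 * t), fs)
  nearest <- which.min(abs(bank$center - 19))
  st <- amplitude_stack(rec, bank[nearest, , drop = FALSE])
  core <- st$amplitudes[1, (2 * fs):(18 * fs)]
  expect_equal(mean(core), 1, tolerance = 0.1)
  expect_lt(stats::sd(core) / mean(core), 0.05)   # flat away from edges
  # white-noise amplitude grows with bandwidth
  set.seed(8)
  noise <- continuous_recording(rnorm(length(t)), fs)
  sub <- bank[c(20, 50, 80), ]
  stn <- amplitude_stack(noise, sub)
  m <- rowMeans(stn$amplitudes[, (2 * fs):(18 * fs)])
  expect_true(all(diff(m) > 0))
  expect_true(all(diff(sub$width) > 0))
  # zero in, zero out
  z <- amplitude_stack(continuous_recording(numeric(4000), fs),
                       bank[50, , drop = FALSE])
  expect_lt(max(z$amplitudes), 1e-12)
})

test_that("epoching slices the right samples and drops out-of-bounds events", {
  fs <- 500
  amp <- matrix(seq_len(2 * 20 * fs), nrow = 2, byrow = TRUE)
  stack <- make_stack(amp, fs)
  ev <- data.frame(sniff_time_s = 10)
  tr <- epoch_stack(stack, ev)
  expect_equal(dim(tr$amplitudes), c(1, 2, 3000))
  # the slice covers t in [8, 14): first sample is index 4001 of the stack
  expect_equal(tr$amplitudes[1, 1, 1], amp[1, 8 * fs + 1])
  expect_equal(tr$amplitudes[1, 1, 3000], amp[1, 14 * fs])
  # early event dropped with count
  expect_warning(tr2 <- epoch_stack(stack, data.frame(sniff_time_s = c(1, 10))),
                 "dropped")
  expect_equal(tr2$n_dropped, 1L)
  expect_equal(dim(tr2$amplitudes)[1], 1)
  # constant stack gives identical epochs
  cst <- make_stack(matrix(3, 1, 20 * fs), fs)
  tr3 <- epoch_stack(cst, data.frame(sniff_time_s = c(6, 10, 13)))
  expect_equal(tr3$amplitudes[1, , ], tr3$amplitudes[3, , ])
})

test_that("baseline correction subtracts the pre-cue mean and keeps it", {
  fs <- 500
  n <- 30 * fs
  base <- 5
  amp <- matrix(base, 1, n)
  sniff <- 12; cue <- 8
  # step of 2 from sniff onset
  amp[1, (sniff * fs + 1):n] <- base + 2
  stack <- make_stack(amp, fs)
  ev <- data.frame(sniff_time_s = sniff, cue_time_s = cue)
  tr <- baseline_correct(epoch_stack(stack, ev), stack)
  ta <- tr$time_axis
  expect_equal(max(abs(tr$amplitudes[1, 1, ta < -0.2])), 0)
  expect_equal(tr$amplitudes[1, 1, ta > 0.1][1], 2)
  # stored baseline equals a direct mean over the raw window
  direct <- mean(amp[1, (round((cue - 0.55) * fs) + 1):(round((cue - 0.05) * fs))])
  expect_equal(tr$baseline[1, 1], direct)
  # missing baseline window: trial excluded with warning
  ev2 <- data.frame(sniff_time_s = c(sniff, 4), cue_time_s = c(cue, 0.2))
  expect_warning(tr2 <- baseline_correct(epoch_stack(stack, ev2), stack),
                 "excluded")
  expect_equal(dim(tr2$amplitudes)[1], 1)
})

make_null_stack <- function(n_band = 4, dur = 240, fs = 50, seed = 1,
                            ar = 0.9) {
  set.seed(seed)
  n <- dur * fs
  amp <- t(vapply(seq_len(n_band), function(b) {
    abs(as.numeric(stats::arima.sim(list(ar = ar), n))) + 0.5
  }, numeric(n)))
  make_stack(amp, fs)
}

null_events <- function(n_ev, dur, seed = 1) {
  set.seed(seed + 1000)
  sniff <- sort(stats::runif(n_ev, 12, dur - 6))
  data.frame(sniff_time_s = sniff, cue_time_s = sniff - 4)
}

test_that("circular-shift z-map: null z is centred, constant-offset invariant,
           and detects an injected burst", {
  fs <- 50; dur <- 240
  stack <- make_null_stack(seed = 2, fs = fs, dur = dur)
  ev <- null_events(24, dur, seed = 2)
  zm <- circular_shift_zmap(stack, ev, window = c(-2, 4),
                            baseline_window = c(-0.55, -0.05),
                            n_perm = 300, seed = 1)
  # null data: z values roughly standard normal, few significant points
  expect_lt(abs(mean(zm$z)), 0.5)
  expect_lt(mean(zm$significance_mask), 0.05)
  # adding a constant to the whole stack leaves the map unchanged
  stack2 <- stack; stack2$amplitudes <- stack2$amplitudes + 10
  zm2 <- circular_shift_zmap(stack2, ev, n_perm = 300, seed = 1)
  expect_equal(zm2$z, zm$z, tolerance = 1e-8)
  # injected post-sniff burst in band 2 comes out significant there
  stack3 <- stack
  for (s in ev$sniff_time_s) {
    i <- (round(s * fs) + 1):(round((s + 1) * fs))
    stack3$amplitudes[2, i] <- stack3$amplitudes[2, i] +
      3 * stats::sd(stack$amplitudes[2, ])
  }
  zm3 <- circular_shift_zmap(stack3, ev, n_perm = 300, seed = 1)
  post <- zm3$time_axis > 0.1 & zm3$time_axis < 0.9
  expect_gt(mean(zm3$significance_mask[2, post]), 0.8)
  expect_lt(mean(zm3$significance_mask[c(1, 3, 4), ]), 0.05)
  # degenerate: observed equal to the null mean gives z = 0
  cst <- make_stack(matrix(2, 2, dur * fs), fs)
  zc <- circular_shift_zmap(cst, ev, n_perm = 50, seed = 1)
  expect_equal(max(abs(zc$z), na.rm = TRUE), 0)
})

test_that("condition-difference z-map is antisymmetric and flags a uniform
           band offset", {
  fs <- 50
  set.seed(3)
  mk <- function(offset_band = NULL) {
    amp <- array(abs(rnorm(16 * 3 * 100)) + 1, c(16, 3, 100))
    if (!is.null(offset_band)) amp[, offset_band, ] <- amp[, offset_band, ] + 1
    make_tensor(amp, seq(0, by = 1 / fs, length.out = 100), c(5, 20, 85))
  }
  a <- mk(); b <- mk(offset_band = 2)
  zab <- condition_difference_zmap(a, b, n_perm = 300, seed = 4)
  zba <- condition_difference_zmap(b, a, n_perm = 300, seed = 4)
  # swapping conditions flips the sign of the statistic
  expect_lt(max(abs((zab$z + zba$z) / (abs(zab$z) + 1))), 0.35)
  expect_equal(sign(mean(zab$z[2, ])), -1)   # A - B with B larger
  expect_gt(mean(zab$significance_mask[2, ]), 0.95)
  expect_lt(mean(zab$significance_mask[c(1, 3), ]), 0.05)
  empty <- make_tensor(array(0, c(0, 3, 100)),
                       seq(0, by = 1 / fs, length.out = 100), c(5, 20, 85))
  expect_error(condition_difference_zmap(a, empty), "empty")
})

test_that("evoked/induced decomposition separates phase-locked from
           phase-random components", {
  fs <- 500
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  bank <- build_filter_bank()[c(30, 60), ]   # ~7.5 and ~30 Hz
  n_tr <- 24
  # identical waveform on every trial: everything is evoked
  wave <- sin(2 * pi * bank$center[1] * t) * exp(-((t - 1) / 0.3)^2)
  same <- matrix(rep(wave, n_tr), n_tr, byrow = TRUE)
  d1 <- decompose_evoked_induced(same, fs, bank)
  expect_lt(max(apply(d1$induced, c(2, 3), mean)), 0.05 * max(d1$evoked))
  # random phase per trial: evoked ~ 0, induced ~ full amplitude
  set.seed(6)
  rand <- t(vapply(seq_len(n_tr), function(i) {
    sin(2 * pi * bank$center[2] * t + runif(1, 0, 2 * pi))
  }, numeric(length(t))))
  d2 <- decompose_evoked_induced(rand, fs, bank)
  ind_amp <- mean(apply(d2$induced[, 2, (0.3 * fs):(1.7 * fs)], 1, mean))
  expect_lt(max(d2$evoked[2, (0.3 * fs):(1.7 * fs)]), 0.35)
  expect_equal(ind_amp, 1, tolerance = 0.15)
  # mixture recovers both components in their own bands
  d3 <- decompose_evoked_induced(same + rand, fs, bank)
  expect_gt(max(d3$evoked[1, ]), 3 * max(d3$evoked[2, (0.3 * fs):(1.7 * fs)]))
  ind_band <- apply(d3$induced, c(2, 3), mean)[, (0.3 * fs):(1.7 * fs)]
  expect_gt(mean(ind_band[2, ]), 3 * mean(ind_band[1, ]))
  expect_warning(decompose_evoked_induced(same[1:3, ], fs, bank), "unstable")
})
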