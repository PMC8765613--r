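# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# one small synthetic session shared across module tests
fix_sim <- function() {
  cached("sim", generate_recording(synth_config(n_trials = 20, seed = 3)))
}

# the same session preprocessed, with a reduced-bank amplitude stack and
# sniff-aligned tensors (reduced bank keeps every 4th band: test-scale only)
fix_processed <- function() {
  cached("processed", {
    sim <- fix_sim()
    rec <- preprocess_recording(sim$recording)
    bank <- build_filter_bank()
    stack <- amplitude_stack(rec, bank[seq(1, nrow(bank), by = 4), ])
    odor <- sim$events[sim$events$condition == "odor", ]
    trials <- epoch_stack(stack, odor)
    tz <- baseline_correct(trials, stack, z_normalize = TRUE)
    list(sim = sim, rec = rec, stack = stack, odor = odor, tz = tz)
  })
}

# hand-built trial tensor for dynamics/behavior tests: bands at 5/20/85 Hz
make_tensor <- function(amplitudes, time_axis, band_centers,
                        meta = NULL, baseline = NULL, fs = NULL) {
  if (is.null(meta)) meta <- data.frame(trial = seq_len(dim(amplitudes)[1]))
  structure(list(amplitudes = amplitudes, time_axis = time_axis,
                 band_centers = band_centers, meta = meta,
                 baseline = baseline, n_dropped = 0L,
                 sampling_rate = if (is.null(fs))
                   1 / diff(time_axis[1:2]) else fs),
            class = "trial_tensor")
}

# minimal amplitude_stack object from a band x time matrix
make_stack <- function(amp, fs, band_centers = seq_len(nrow(amp)),
                       start_time = 0) {
  structure(list(amplitudes = amp, band_centers = band_centers,
                 sampling_rate = fs, start_time = start_time),
            class = "amplitude_stack")
}

# measured amplitude of a (possibly filtered) sinusoid, robust to the sample
# grid missing the crest: sqrt(2) * RMS over the central half
sine_amplitude <- function(x) {
  n <- length(x)
  core <- x[floor(n / 4):ceiling(3 * n / 4)]
  sqrt(2) * sqrt(mean(core^2))
}

# the shared session's PAC-band amplitude stack (47 bands), cached
fix_pac_stack <- function() {
  cached("pac_stack", amplitude_stack(fix_processed()$rec, pac_band_subset()))
}

# hand-built phase/amplitude epoch pair for PAC null tests
make_fake_pac <- function(phase_epochs, amp_epochs, n_bins = 18) {
  phase <- as.vector(t(phase_epochs))
  amp <- matrix(as.vector(t(amp_epochs)), nrow = 1)
  list(mi = odorosc:::mi_from_bins(odorosc:::phase_bins(phase, n_bins),
                                   amp[1, ], n_bins),
       phase = phase, phase_epochs = phase_epochs, amp = amp,
       n_bins = n_bins)
}

# trial-shuffle null for a fake PAC object (mirrors the exported null's
# shuffle); returns the raw MI, the null mean, and the z score
trial_shuffle_null <- function(spec, n_perm = 200, seed = 1) {
  set.seed(seed)
  n_tr <- nrow(spec$phase_epochs)
  null_mi <- vapply(seq_len(n_perm), function(p) {
    ord <- sample.int(n_tr)
    ph <- as.vector(t(spec$phase_epochs[ord, , drop = FALSE]))
    odorosc:::mi_from_bins(odorosc:::phase_bins(ph, spec$n_bins),
                           spec$amp[1, ], spec$n_bins)
  }, numeric(1))
  list(mi = spec$mi, null_mean = mean(null_mi),
       z = (spec$mi - mean(null_mi)) / stats::sd(null_mi))
}

# circular-linear correlation (Mardia) and its chi-square p value
circ_lin_cor <- function(phase, x) {
  rxc <- stats::cor(x, cos(phase))
  rxs <- stats::cor(x, sin(phase))
  rcs <- stats::cor(cos(phase), sin(phase))
  r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
  r2 <- min(max(r2, 0), 1)
  p <- stats::pchisq(length(x) * r2, df = 2, lower.tail = FALSE)
  list(r = sqrt(r2), p = p)
}
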