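---
title: "Methods: sniff-aligned oscillation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sniff-aligned oscillation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(odorosc)
```

# The problem and the pipeline

Human piriform (olfactory) cortex responds to an odor-bearing sniff with a
stereotyped sequence of oscillatory bursts: an early theta (4-8 Hz) increase
beginning shortly before inhalation, followed by gamma (30-150 Hz) and beta
(13-30 Hz) increases that extend into exhalation. `odorosc` implements the
analysis chain used to characterize such responses in intracranial LFP
recordings, plus a synthetic generator that emulates the raw data structure so
every stage can be tested against known ground truth.

The stages, in dependency order:

1. **Preprocessing** (`preprocess_recording`): two-pass zero-phase FIR
   low-pass at 235 Hz, 4 Hz-wide band-stops at 60 Hz and harmonics below the
   cutoff, resampling to 500 Hz, common-average re-referencing.
2. **Respiration** (`detect_breaths`, `respiratory_phase`): breath features
   from nasal airflow; instantaneous phase via the Hilbert transform with
   phase 0 at the inhale peak and +pi/2 at the inhale-to-exhale transition.
3. **Spectral decomposition** (`build_filter_bank`, `amplitude_stack`): 100
   log-spaced bands, centers `200^((k-1)/99)` Hz with widths `2*25^((k-1)/99)`
   Hz, first 95 kept (~1-153 Hz); per band, zero-phase band-pass, analytic
   amplitude, 10 ms moving-average smoothing.
4. **Event-locked statistics** (`epoch_stack`, `baseline_correct`,
   `circular_shift_zmap`, `condition_difference_zmap`): sniff-aligned
   `[-2, 4)` s epochs, additive baseline correction against the
   `[-0.55, -0.05]` s pre-cue window, permutation-normalized z-maps with
   Benjamini-Hochberg FDR across all time-frequency points.
5. **Band dynamics** (`band_average`, `percent_change`,
   `pointwise_condition_test`, `bootstrap_band_map`, `cluster_mass_test`,
   `cluster_mass_recut`, `peak_phase_bootstrap`): band-averaged time courses,
   FDR-masked pointwise tests with onset/offset latencies, bootstrap
   stability maps, cluster-mass permutation timing statistics, and circular
   statistics (`plv`, `rayleigh_test`) of the respiratory phase at
   bootstrapped amplitude peaks.
6. **Behavior** (`balanced_outcome_difference`,
   `bootstrap_accuracy_correlation`, `svm_separability`): links between band
   amplitude and identification accuracy via balanced resampling, bootstrap
   accuracy-amplitude correlations, and a linear SVM on (inhale, exhale)
   percent-change features with 5-fold cross-validation and ROC/AUC.
7. **Phase-amplitude coupling** (`modulation_index`, `mi_spectrum`,
   `mi_null_circular_shift`, `mi_null_trial_shuffle`): Kullback-Leibler
   modulation index of theta phase against the 47 amplitude bands above
   13 Hz (13.05-153.04 Hz), on concatenated `[0, 1)` s post-sniff epochs,
   with circular-shift and trial-order-shuffle nulls.

# Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| low-pass cutoff | 235 | Hz | below all clinical Nyquist rates; precedes 500 Hz resampling |
| notch bandwidth | 4 | Hz | narrow stop bands at 60/120/180 Hz |
| filter-bank size | 100 designed / 95 kept | - | log spacing 1-200 Hz; kept span ~1-153 Hz |
| epoch window | [-2, 4) | s | covers pre-sniff anticipation through exhale |
| baseline window | [-0.55, -0.05] | s pre-cue | pre-cue so anticipation is not subtracted |
| amplitude smoothing | 10 | ms | suppress ripple without smearing bursts |
| peak-search smoothing | 50 | ms | stabilizes the per-bootstrap amplitude peak |
| cluster threshold | p = 0.01 | - | initial pointwise threshold before mass correction |
| MI phase bins | 18 | - | convention of the KL-MI method; MI depends on the bin count, so it is explicit |
| PAC window | [0, 1) | s post-sniff | where theta amplitude (hence meaningful phase) is high |
| n_perm | 10000 (full) | - | analyses accept smaller values; tests use 200-500 |

# Filter design

The original toolchain's FIR order rule is not recoverable from its
description, and a fixed `3 * fs / f_low` rule cannot realize a 4 Hz-wide
notch (at fs = 500 that is a 26-tap filter with a ~60 Hz transition band).
Kernels here are Hamming-windowed sincs with order `ceiling(3.3 * fs / tw)`,
where the transition width `tw` is tied to the band: a quarter of the cutoff
for low-pass, half the lower edge (capped at half the bandwidth) for
band-pass, half the stop width for band-stop. Filters are applied twice with
group-delay compensation and reflection padding, so the effective response is
`|H(f)|^2` at exactly zero phase; `fir_response()` exposes the designed
response so tests can compare measured attenuation against an independent
frequency-domain evaluation. For speed, chains of zero-phase stages are
composed in the frequency domain (magnitudes multiply); this is numerically
equivalent to sequential application up to the padding treatment (relative
differences ~1e-4 at the edges).

# Permutation nulls: three readings, two survivors

Three permutation constructions coexist in the pipeline and are deliberately
distinct:

* **Event-level circular shift** (`circular_shift_zmap`,
  `cluster_mass_recut`): all event times move by a common (z-map) or
  per-trial (cluster null) random offset over the *continuous recording*,
  wrapping at the ends; epochs and baselines are re-cut and re-processed
  identically. A shifted epoch carries no event-locked signal, so the null
  fully destroys alignment while preserving the amplitude distribution and
  autocorrelation.
* **Epoch-level circular shift** (`cluster_mass_test` on trial matrices):
  every trial's series is rotated within the epoch. This is appropriate when
  only epoch-level data exist, but it cannot detect effects that occupy most
  of the epoch: rotated bursts tile the window and elevate the null mean
  everywhere. During development we verified this directly - a sustained
  beta-like burst covering 3.4 of 6 s is undetectable under epoch-level
  shifting at any trial count, while the event-level null recovers it. The
  package therefore uses the event-level null wherever the continuous data
  are available.
* **Partial-subset shifting** (shifting only `k ~ Uniform{1..n}` trials) was
  also evaluated and rejected: retaining unshifted trials leaves the null
  correlated with the observed alignment, which is conservative under the
  global null (measured FWER ~0.02 vs ~0.04 for all-trials shifting at a
  nominal 0.05) and powerless against sustained effects.

The z-map convention follows the source analysis: the observed
baseline-corrected trial average is divided by the standard deviation of the
permutation distribution (no null-mean subtraction for the event-shift map;
the condition-label map subtracts the Gaussian-fit null mean). Two-sided p
values are FDR-corrected across all map points; the PAC analysis corrects
across its 47 bands only.

One calibration caveat is inherited from the source construction: the
event-shift null measures the variability of the *raw* shifted-epoch
average, while the observed statistic additionally carries the noise of its
subtracted baseline mean. The resulting per-point error rate is therefore
mildly above nominal (measured ~0.06-0.08 at a nominal 0.05 on stationary
synthetic data). The map-level conclusions are protected by the FDR step,
but exact per-point calibration would require baseline-subtracting the null
epochs as well, which the source analysis does not do.

# Bootstrap statistics: what the spread means

Two analyses resample trials with replacement and then test the resampled
statistics. Here the distinction between *resampling noise* and *estimation
uncertainty* matters:

* `balanced_outcome_difference` reports the conventional one-sample t test
  across the bootstrap differences (`t_vs_zero`) and a calibrated reading
  (`bootstrap_z = mean / sd` of the differences). The t test's standard
  error shrinks with the number of repetitions, not with the number of
  trials, so under a true null it rejects far too often; the bootstrap sd is
  the correct standard error of the difference estimate. The package's own
  decisions (and its acceptance tests) use `bootstrap_z`.
* `svm_separability` classifies bootstrap means, which concentrate around
  their class pools' means; any finite-pool difference is therefore
  learnable ("pool memorization"), and AUC values are optimistic in absolute
  terms. Comparisons *between* bands are still meaningful, and the chance
  control must break the pool structure: `shuffle_labels = TRUE` re-permutes
  the outcome flags on every repetition, which reproduces chance-level
  cross-validated accuracy. Shuffling once before resampling does not.

The linear classifier itself is a full-batch subgradient solver for the
hinge-loss + L2 objective (margin penalty C = 1 by default) on standardized
features; ROC and the Youden-optimized accuracy are computed from
cross-validated decision scores, never from refit scores.

# The synthetic world

`synth_config()` defaults encode the session structure the analysis assumes:
4 s breaths (sd 0.5 s) with a 40% inhale fraction and area-balanced
asymmetric airflow; 21.3 s mean intertrial intervals (jitter +-4 s, floor
well above the 6 s epoch span); cue-to-sniff delays uniform on 3-7 s; 78% of
trials correct. Odor trials inject three bursts on a 1/f^2 background
(spectral shaping of white noise, exact slope control): theta at 4.72 Hz
from -126 ms (duration 1.2 s, chosen so the modulating phase physically
spans the 1 s coupling window; only the onset is constrained by the source),
gamma at 84.94 Hz from +116 ms (1.9 s), and beta at 18.98 Hz from +144 ms
(3.4 s, persisting into exhale). Burst peak amplitudes default to 3x the
band-limited background sd (the signal-to-noise regime the recovery tests
assume), with lognormal per-trial variability (sdlog 0.25 - a free
parameter; the source data do not constrain it). The gamma envelope is
multiplied by `1 + kappa * cos(phase_theta)` with kappa = 0.8; correct
trials scale beta/gamma amplitudes by 1.5. One burst-carrying channel is
accompanied by three burst-free decoys so common-average referencing is
exercised (and attenuates the bursts by 1/4 - real referencing does this
too).

What the generator does **not** emulate: epileptiform and movement
artifacts, non-stationary breathing, electrode geometry and volume
conduction, multi-subject heterogeneity, and odor-identity structure. A
green recovery test therefore establishes that the statistical machinery
recovers known effects at realistic SNR and trial counts - not that the
pipeline is robust to clinical-data pathology.

# Numerical choices and degenerate inputs

* Time is absolute seconds on the recording clock; sample indices are
  0-based in arithmetic (`round(t * fs) + 1` in R's 1-based indexing);
  windows are half-open.
* Phase bins cover `(-pi, pi]`; empty bins contribute `0 * log 0 = 0` to the
  MI with a warning; the identity circular shift is excluded from null draws.
* A z-map point with zero observed value and zero null sd is defined as
  z = 0; a PAC band with zero null sd is flagged and excluded from the FDR.
* A pointwise t statistic over a zero-variance difference is 0 when the
  difference is 0 and +-Inf otherwise.
* Flat airflow yields an empty breath-feature set with a warning; flat
  bootstrap series skip the repetition with a warning; ties in peak search
  break to the earliest time.
* Cluster onset/offset latencies are reported from the first/last
  significant sample; `cluster_mass_recut` optionally decimates its band
  series (default 4x) purely for speed, with timing resolution reduced
  accordingly.

# Scaled-down testing

Full-scale analyses use 10000 permutations and 2000 bootstrap repetitions.
The test and acceptance suites run the identical code paths with permutation
counts in the hundreds, 10-20 seeds per calibration claim, a reduced
filter-bank subset (every 4th-6th band) for band-level analyses, and one
323-trial session (the pooled odor-trial count, needed so the ~71-trial
incorrect pool gives the outcome analyses their published power) per
recovery seed. These are compute scalings only: effect sizes, thresholds,
windows, and tolerances are the stated defaults throughout.

# Known limitations

* EDF input is out of scope in this environment; recordings use a plain
  TSV container (`read_recording`/`write_recording`) with the sampling
  clock in a header line.
* The respiration detector implements mean-centering, smoothing, zero
  crossings, and extrema - not the full published breath-analysis toolbox
  (no pause detection or volume calibration).
* Absolute AUC values from `svm_separability` inherit the pool-memorization
  optimism discussed above; interpret them comparatively.
* `bootstrap_accuracy_correlation` follows the source in using a single
  inhale/exhale split time from the trial-averaged breathing signal (first
  post-sniff crossing of phase +pi/2), not per-trial splits.
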