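# odorosc

Sniff-aligned oscillation analysis for intracranial olfactory recordings.

Odor-bearing sniffs drive a stereotyped oscillatory response in human
piriform cortex: an early theta (4-8 Hz) burst starting just before
inhalation, followed by gamma (30-150 Hz) and beta (13-30 Hz) bursts that
extend into exhale, with theta phase organizing the higher-frequency
amplitudes and beta/gamma amplitude tracking whether the odor is correctly
identified. `odorosc` implements the full analysis chain needed to
characterize such responses in local field potentials (LFPs), for
electrophysiologists working with event-locked intracranial data:

* zero-phase two-pass FIR preprocessing (235 Hz low-pass, 4 Hz-wide line
  notches, 500 Hz resampling, common-average reference);
* a logarithmic Hilbert filter bank: 100 bands with centers
  `c_k = 200^((k-1)/99)` Hz and widths `w_k = 2 * 25^((k-1)/99)` Hz, the
  first 95 kept (~1-153 Hz), analytic amplitude per band;
* permutation-normalized spectrograms: sniff-aligned `[-2, 4)` s epochs,
  pre-cue `[-0.55, -0.05]` s baseline, event-time circular-shift null with
  `z = observed / sd(null)` and Benjamini-Hochberg FDR, plus
  condition-label shuffle difference maps;
* band dynamics: percent change `(A - A_base) / A_base`, FDR-masked
  pointwise tests with onset/offset latencies, bootstrap stability maps,
  cluster-mass permutation statistics (cluster mass = sum of pointwise t),
  and circular statistics of the respiratory phase at amplitude peaks
  (PLV = `|mean(exp(i*theta))|`, Rayleigh `z = n * PLV^2`);
* accuracy analyses: balanced correct/incorrect resampling, bootstrap
  accuracy-amplitude correlations with an inhale/exhale split at
  respiratory phase pi/2, and a linear SVM on (inhale, exhale)
  percent-change features with 5-fold cross-validation and ROC/AUC;
* phase-amplitude coupling: Kullback-Leibler modulation index
  `MI = (log N + sum P_j log P_j) / log N` of theta phase against the 47
  bands spanning 13.05-153.04 Hz, with circular-shift and
  trial-order-shuffle nulls;
* a synthetic sniff-locked LFP generator (`synth_config`,
  `generate_recording`) producing respiration, event tables, multichannel
  1/f LFP with ground-truth bursts, coupling, and accuracy effects, for
  end-to-end parameter-recovery testing.

## Worked example

```r
library(odorosc)

cfg   <- synth_config(n_trials = 40, seed = 42)   # defaults: kappa = 0.8 gamma
sim   <- generate_recording(cfg)                  # coupling, 1.5x gain on correct
rec   <- preprocess_recording(sim$recording)
odor  <- subset(sim$events, condition == "odor")
bank  <- build_filter_bank()
stack <- amplitude_stack(rec, bank[seq(1, 95, by = 4), ])

zm <- circular_shift_zmap(stack, odor, n_perm = 500, seed = 7)
cl <- cluster_mass_recut(stack, odor, "theta", n_perm = 500, seed = 7)
pr <- mi_null_circular_shift(rec, odor, n_perm = 300, seed = 7)
```

Printed output (exactly as produced by the code above):

```
<continuous_recording> 4 channel(s) x 474808 samples @ 500 Hz (949.6 s from t=0 s)
<zmap> 24 bands x 3000 times, 500 permutations, 8.6% significant (q = 0.05)
peak z = 25.96 at 89.62 Hz, t = 1.006 s
<cluster_result> 2 cluster(s), 1 significant (mass threshold 70.8)
  start_s end_s      mass           p significant
1  -0.136 0.768 597.05938 0.001996008        TRUE
2   1.088 1.128  16.94941 0.343313373       FALSE
<pac_result> 47 bands, null = circular_shift (300 perms), 10 significant at q = 0.05
  peak z = 5.35 at 89.62 Hz (MI = 0.01325)
```

Reading it: the spectrogram shows significant sniff-locked amplitude
increases (8.6% of time-frequency points; the map peak sits in the gamma
band, where the generator injects its strongest relative effect). The theta
cluster spans -0.136 to 0.768 s around sniff onset - recovering the injected
theta burst that starts 126 ms *before* inhalation - and survives the
cluster-mass permutation correction (p = 0.002). The modulation-index
spectrum peaks near the 85 Hz band into which theta-phase coupling
(kappa = 0.8) was injected, and clears the FDR threshold against the
circular-shift null.

A one-call orchestration of all stages on a synthetic session is available
via `run_pipeline(pipeline_config())`, which writes TSV/JSON results plus a
resolved-config echo; `inst/cli/odorosc.R` exposes the same stages on the
command line.

## Documentation

The methods vignette (`vignettes/odor-oscillations.Rmd`) describes the
model and its assumptions, every tunable parameter with units and defaults,
what the synthetic generator does and does not emulate, the permutation-null
design trade-offs, and known limitations.
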