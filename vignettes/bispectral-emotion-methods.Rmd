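---
title: "Bispectral EEG features for emotion classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bispectral EEG features for emotion classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegbispec)
```

## The problem and the model

Emotion assessment from EEG looks for class-specific structure in brain
signals recorded while subjects perceive emotional stimuli. Second-order
tools (the power spectrum) only see amplitude; they are blind to the phase
relations that nonlinear neuronal interactions produce. The bispectrum — the
third-order spectrum

$$B(f_1, f_2) = E\left[X(f_1)\,X(f_2)\,X^*(f_1+f_2)\right]$$

— retains phase. Its key diagnostic is quadratic phase coupling (QPC):
when components at $f_1$, $f_2$ and $f_1+f_2$ satisfy
$\theta_3 = \theta_1 + \theta_2$, the triple product has a fixed phase, its
expectation survives averaging, and $|B|$ peaks at $(f_1, f_2)$. When
$\theta_3$ is independent, the expectation vanishes. Because third-order
cumulants of Gaussian processes are zero, Gaussian background activity is
suppressed, which is what makes bispectral features attractive for EEG.

This package implements that analysis end to end for a six-emotion design
(anger, disgust, fear, happiness, sadness, surprise; labels `A D F H S SU`)
over three groups of subjects (left-brain-damage and right-brain-damage
stroke patients, and normal controls), on 14-channel, 128 Hz recordings.
The original clinical recordings are not publicly deposited, so the package
ships a synthetic generator with the statistical structure the analysis
assumes; every pipeline stage is exercised and tested against that
generator and against analytic oracles.

## Bispectrum estimation

Two estimators are provided.

**Indirect (cumulant) method** — the default throughout the pipeline. The
epoch is split into records (default 256 samples, 50% overlap), each record
is mean-removed and its biased third-order cumulant
$C(\tau_1,\tau_2) = \tfrac1N\sum_k x(k)x(k+\tau_1)x(k+\tau_2)$ estimated
over lags up to `max_lag` (default 127); record estimates are averaged,
tapered by a separable Hanning lag window, zero-padded to `nfft` (default
1024) and transformed by the 2-D DFT. Mean removal matters because the
cumulant definition presumes a zero-mean process and real EEG has drift.
The biased ($1/N$) normalization stabilizes the variance of short records.

**Direct (FFT) method.** Per windowed record, the triple product
$X(f_1)X(f_2)X^*(f_1+f_2)$ is accumulated on the full grid and averaged
over records. The two estimators serve as mutual cross-checks: on coupled
test epochs their region argmaxes agree to one bin and their magnitude maps
correlate above 0.8 *when their spectral resolutions are matched* — the
indirect method's smoothing kernel is the transform of the lag window, so
`max_lag` should be of the order of `record_len`/2 for comparisons against
the direct method with the same record length.

Both grids are centred (`[-0.5, 0.5)` cycles/sample). By the symmetries of
real-signal bispectra, the triangle $0 \le f_1 \le f_2$,
$f_1+f_2 \le 1/2$ — the non-redundant region $\Omega$ — describes the whole
surface; all features are computed there. The printed orientation
($f_2 \ge f_1$) is adopted; by $B(f_1,f_2)=B(f_2,f_1)$ it is equivalent to
the transposed convention.

## The six features

With $\Omega$ the region, $N$ its size, and $m = 1..N_{diag}$ indexing the
diagonal bins $(f_m, f_m)$ in increasing frequency:

| feature | definition |
|---|---|
| `v`  | $\frac{1}{N-1}\sum_\Omega |B_i - \mu|^2$, $\mu$ the complex mean |
| `H1` | $\sum_\Omega \log |B(f_1,f_2)|$ |
| `H2` | $\sum_m \log |B(f_m,f_m)|$ |
| `H3` | $\sum_m m \log |B(f_m,f_m)|$ |
| `H4` | $\sum_m (m - H3)^2 \log |B(f_m,f_m)|$ |
| `H5` | $\sum_\Omega (f_1^2+f_2^2)\,|B(f_1,f_2)|$ |

Numerical choices, made once and tested:

* **Logarithms** are natural (the base is a free convention) and floored as
  $\log(|B| + \varepsilon)$, $\varepsilon = 10^{-12}$, so degenerate bins
  keep the features finite.
* **`H3`/`H4` are the unnormalized printed forms**, not centroid-normalized
  variants found elsewhere in the literature; the worked three-bin example
  (diagonal magnitudes $e^1,e^2,e^3 \Rightarrow$ H2 = 6, H3 = 14,
  H4 = 820) is frozen as a regression test. `H4` computed this way is a
  second moment about a *sum*, which makes it wildly scale-sensitive — one
  reason it tends to fail the significance screen.
* **`H5` is implemented as a sum over $\Omega$** with normalized
  frequencies: the printed form carries no summation symbol, but a
  single-bin "moment" would be ill-defined without a chosen bin, and
  normalized frequencies keep the weights scale-free across `nfft`.
* **`v` uses the complex values with the complex mean**, modulus of the
  deviations, as printed.

Useful invariants (all tested): scaling an epoch by $c$ scales $|B|$ by
$|c|^3$, so `H1` shifts by $3N\log c$ and `v` by $|c|^6$.

## Preprocessing

Artifacts are handled by **clipping at ±80 µV** — the thresholding rule is
interpreted as saturation because it preserves epoch count and timing; an
`artifact_mode = "reject_epoch"` alternative drops supra-threshold windows
instead. Filtering is a **6th-order Butterworth** (design order passed to
the filter design; the bandpass transformation doubles the pole count)
applied **forward-backward**: zero-phase application is essential here
because a causal filter's phase response would distort the very phase
relations the bispectrum measures. The effective magnitude response is the
squared design response, which the tests verify against the analytic
Butterworth formula with bilinear prewarping. Processing order is clip →
broadband (0.5–49 Hz) → band filter (alpha 8–13, beta 13–30, gamma
30–49 Hz) → segmentation, so band splitting happens before epoching and
per-epoch filter transients never arise. Epochs are the first six
non-overlapping 6 s windows (768 samples at 128 Hz) of each channel;
placement within the trial is a free choice (the design only fixes six
windows) and taking them from the start is the simplest deterministic rule.

## The synthetic generator

`generate_dataset()` emulates the study design: per group, 15 subjects × 6
emotions × 6 trials (36 trials/subject), 14 channels at 128 Hz, 48 s
trials. Its defaults are the study conditions; they are not adjusted per
experiment.

* **Class structure.** Nothing in the source design states *how* emotions
  differ spectrally, so class separation is induced by distinct QPC rows
  (f1, f2, amplitude) per emotion and band, chosen once: within each band
  two emotions share a row (alpha confuses {A,D}, {F,H}, {S,SU}; beta
  {A,F}, {D,H}, {S,SU}; gamma {A,H}, {D,F}), while every pair is separated
  by at least one band. Single-band features are therefore partially
  informative and the three-band combination disambiguates — the structure
  behind the band-combination property the tests check. Carriers sit
  inside their band with $f_1+f_2$ below Nyquist; amplitudes span 7–13 µV.
* **Noise** is white Gaussian at 15 µV SD per channel, a typical resting
  EEG background magnitude relative to evoked band activity.
* **Subjects** contribute a multiplicative lognormal(0, 0.1) gain per
  channel — between-subject variance without altering coupling structure.
* **Blinks** are raised-cosine pulses, 300 ms wide, peak 130 µV, Poisson
  at 6/min, added to the frontal channels (AF3, AF4, F7, F8 where
  present); no artifact model is given in the source, and a band-limited
  smooth frontal deflection is the simplest realistic stand-in.

What the generator does **not** emulate: real stroke-EEG spectra (1/f
background, band-limited rhythms beyond the coupled triples), volume
conduction and channel correlation, reference-electrode effects,
non-stationarity within trials. Passing tests therefore demonstrate that
the pipeline recovers the structure it is designed to detect — not that
any particular accuracy is attainable on clinical recordings.

## Statistical screening and classification

Each (feature, band) cell is screened by **one-way ANOVA** across the six
emotions on pooled epoch-level observations (one per channel × window ×
trial × subject; at full scale 7,560 per emotion, hence 45,354 within-group
degrees of freedom). No subject-level nesting and no multiple-testing
correction are applied, matching the screening design (a Bonferroni flag
exists, default off). A feature is retained only if $p \le 0.05$ in
**every** band — the group-wide rule under which a feature failing in any
single band is discarded outright (the fate of `H4`); per-band retention is
available behind a flag.

Classification is **per feature type** and **per trial**: the sample vector
of one trial is the feature over channels × windows (84 values per band at
full scale, channel-major then window), concatenated across bands when
combining. The epoch-level/trial-level ambiguity in the source design is
resolved trial-level because the printed confusion-matrix column totals
(54 = 540 trials / 10 folds) only make sense for trial units.

* **KNN** uses cityblock distance, k swept 1–15; vote ties fall back to
  the single nearest neighbour's label.
* **PNN** scores each class with the mean Gaussian Parzen kernel
  $\exp(-d^2/2\sigma^2)$ (Euclidean $d$, equal priors), spread swept
  0.1–1.5; score ties take the lowest class index; kernel sums are shifted
  by the nearest-point distance before exponentiation so small spreads do
  not underflow (the argmax is unchanged). As spread → 0 the decision
  approaches 1-NN; as spread → ∞ class scores converge and selectivity is
  lost — both limits are tested.
* **Cross-validation** is stratified, seeded, 10-fold at full scale;
  confusion matrices are summed over folds (rows = predicted, columns =
  actual) and also emitted column-normalized.

## Problem sizes used in tests and scripts

The shipped tests and the acceptance script run a reduced design chosen
once for Monte-Carlo stability at desk scale: 4 subjects × 2 trials × 4
channels × 2 windows, `nfft = 128`, `max_lag = 63`, 4-fold
cross-validation (8 trials per class cannot stratify over 10 folds), with
`full_scale = TRUE` in `pipeline_config()` restoring the full design.
Realization counts for the QPC checks follow from estimator variance: the
magnitude of an average of $n$ unit-phase triple products is Rayleigh with
mean $\sqrt{\pi/4n}$, which is 11% of the coupled peak at $n = 64$ —
above the 10% contrast bound — so the uncoupled control uses $n = 512$
(expected 4.4%). The band-combination comparison averages 8 generator
seeds. The null behavior of the ANOVA gate is measured over 400
repetitions, where a binomial 3-standard-error band around the nominal
0.05 discard rate is ±0.033.

## Known limitations

* The indirect method's absolute magnitudes depend on record/lag/window
  choices that the source never prints; only structural properties (peak
  locations, symmetries, suppression ratios, cross-method agreement) are
  verifiable, not published magnitudes or F values from the undeposited
  recordings.
* `H4`'s second moment about an unnormalized sum makes it numerically
  fragile; it is retained for completeness and routinely discarded by the
  gate.
* The generator's emotion structure is a modeling choice; accuracies on it
  say nothing quantitative about clinical EEG.
* EDF input is not implemented (no EDF reader among the package's
  dependencies); datasets are exchanged as delimited channel matrices with
  a manifest, as written by `write_dataset()`.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 1)       # reduced scale; full_scale = TRUE
                                       # restores 15 x 6 x 14 x 6
report <- run_pipeline(cfg)
report$anova                           # 6 features x 3 bands
report$retained                        # features passing the gate
report$best                            # best CV accuracy per band set
```
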