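---
title: "Gamma oscillation and spike-phase analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma oscillation and spike-phase analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammaphase)
```

## What this package analyses

Pharmacologically induced gamma oscillations in hippocampal slices —
carbachol or kainate perfusion driving persistent ~40 Hz field activity in
CA3 that propagates to CA1 — and the phase relationship between those
oscillations and the spiking of parvalbumin-expressing interneurons (PVINs)
recorded in cell-attached mode. The pipeline has five analysis stages
(spectral metrics with slice inclusion rules, rhythmicity, spike metrics,
circular phase statistics, cohort contingency analysis) plus a synthetic-data
generator that emulates the recordings so every stage can be validated
against known ground truth.

## Spectral stage

Signals are band-pass filtered 5–120 Hz with a 3rd-order Butterworth filter
applied forward and backward (`bandpass()`). Zero-phase filtering matters
here: any filter delay would systematically rotate the spike-phase estimates
downstream. The effective amplitude response is the squared Butterworth
magnitude, which the tests verify against the analog-prototype transfer
function.

Power spectra (`power_spectrum()`) are Welch estimates: Hann-windowed
segments at 50% overlap, averaged over consecutive 10 s epochs. The default
segment length of 2^14 samples gives ~0.61 Hz resolution at the 10 kHz
acquisition rate — enough to read "frequency at peak power" to about 1 Hz.
The estimator is density-scaled (µV²/Hz), so the integral of the PSD equals
the signal variance (Parseval); this identity is asserted within 2% in the
tests for every generated signal.

`gamma_metrics()` reports three per-slice numbers:

* **peak frequency** — argmax of the PSD inside the 5–120 Hz search band,
  ties resolved to the lower frequency;
* **peak power** — the PSD at that argmax (µV²/Hz);
* **bandwidth power** — the trapezoidal integral of the PSD over 20–80 Hz
  (µV²). The 20–80 Hz band (rather than the textbook 30–90 Hz) reflects the
  lower recording temperature of interface chambers, which shifts gamma
  frequency down roughly linearly.

**Inclusion (QC) rules** (`qc_slice()`): a region's oscillation counts only
when the peak frequency lies strictly between 19 and 80 Hz and peak power
exceeds 1 µV²/Hz (CA3) or 0.1 µV²/Hz (CA1); mains-contaminated records are
discarded. Since no quantitative mains criterion is standard, we define
contamination as mean PSD in 58–62 Hz exceeding 5× the mean of the flanking
53–57/63–67 Hz bands; the ratio threshold is a config key. During the peak
search the 58–62 Hz window can additionally be skipped (default on), while
bandwidth power always integrates the full fixed 20–80 Hz band — whether the
original analyses excluded the mains window from the peak search or simply
discarded contaminated slices is not documented, so both behaviours are
available behind `exclude_mains_in_search`.

## Rhythmicity stage

The coefficient of rhythmicity is read from the normalized autocorrelogram
of a 10 s epoch: with α the height of the second peak and β the height of
the first trough,

Cr = (α − β) / (α + β).

The raw autocorrelation r ranges over [−1, 1]; heights are measured after
the affine rescale (r + 1)/2 to [0, 1]. This convention is a deliberate
design choice: read directly on signed correlations, a perfect oscillation
(α = 1, β = −1) would make Cr divide 2 by 0, while the rescale maps a
perfect rhythm to Cr = 1 (α = 1, β = 0) and white noise to Cr ≈ 0
(α ≈ β ≈ ½), matching the reported 0–1 range and the reading that higher Cr
means better oscillation quality. The antecedent literature does not fix the
convention; it is isolated in `coefficient_of_rhythmicity()` so an
alternative can be swapped in. Trough and peak are discrete local extrema on
the positive-lag branch (lags > 1 ms, up to 100 ms by default) refined by
three-point parabolic interpolation; a monotone correlogram yields the
degenerate result Cr = 0, not rhythmic, with a reason string. Values ≥ 0.01
are classed rhythmic.

Cross-correlation between CA3 and CA1 (`cross_correlogram()`) is
Pearson-normalized (biased estimator), so identical signals give a peak of
exactly 1 at lag 0, and a positive peak lag means CA1 follows CA3. Equal
peaks resolve to the smallest |lag|. Small-instance tests pin both
correlograms to direct O(N²) sum oracles at 1e-10.

The noise-robustness of Cr is checked on a ladder of white-noise amplitudes
{0, 0.25, 0.5, 1, 2} (relative to a unit 40 Hz carrier), 20 seeds per rung:
mean Cr must not increase along the ladder. The rungs were chosen so the
expected Cr strictly decreases between consecutive rungs; beyond roughly
2× noise Cr sits at its noise floor, where the ordering of two rungs is no
longer identifiable from 20 seeds.

## Spike stage

`detect_spikes()` emulates a threshold detection tool but with a robust
data-driven default: the cell-attached trace is high-pass filtered (100 Hz)
and events are excursions of the residual beyond median ± 5 robust SDs
(MAD/0.6745); an absolute-µV override reproduces fixed-threshold behaviour.
Polarity is auto-detected from the largest excursion in the first 10 s.
Detections within a 1 ms refractory window of a previous one are suppressed.
Snippets of 2 ms pre / 3 ms post are cut around each extremum.

Spike half-width (`spike_halfwidth()`) is full width at half amplitude,
with amplitude measured from the extremum to the median of the pre-extremum
baseline window and crossings located by linear interpolation — invariant to
amplitude scaling and polarity by construction. Per-condition firing metrics
(`epoch_spike_metrics()`) use the first 180 s of each annotated condition
(baseline / drug / washout), matching the three-minute analysis epochs used
for cell-attached recordings.

Interictal-like events (`detect_iie()`) are spans where the 10 ms-smoothed
rectified signal exceeds 5 robust SDs for ≥ 50 ms, with events closer than
100 ms merged. All three constants are our own operational definitions (the
original event boundaries were chosen manually) and are exposed as config
keys; the detector is validated only against synthetic injected bursts.

## Circular phase stage

Instantaneous gamma phase is the argument of the analytic signal (Hilbert
transform via FFT) of the 20–80 Hz filtered LFP, expressed in [0, 2π) with
the convention: **cycle peak = 0, trough = π**, phase advancing through the
falling edge (0 → π) and rising edge (π → 2π). PVINs firing on the rising
phase therefore show mean angles around 255–290°. A polarity flag inverts
the signal first for recordings with reversed field polarity. Spike phases
are linearly interpolated on the unwrapped phase at each spike time.

First-order (per-cell) statistics: circular mean angle and resultant length
r (`cell_mean_vector()`), and the Rayleigh test of uniformity with
z = n r² and the standard four-term series approximation for p
(`rayleigh_test()`), validated against Monte-Carlo permutation at small n
and for type-I calibration under the null.

Second-order (population) statistics treat each cell's mean vector as a
point (Xⱼ, Yⱼ) = (rⱼ cos aⱼ, rⱼ sin aⱼ). Cells are thereby implicitly
weighted by their own concentration rⱼ — not by spike count, which the
source analyses do not document; the choice is deliberate and keeps a
heavily sampled but weakly locked cell from dominating the population mean.
Cells with fewer than 10 spikes in the analysis epoch are excluded from
population tests by default (configurable). `hotelling_one_sample()` tests
whether the population of points is centred away from the origin with
F ~ F(2, n−2); `batschelet_two_sample()` compares two population centres on
the pooled within-group scatter with F ~ F(2, N−3). Both are validated by
simulation: type-I error 0.047 and 0.051 at α = 0.05 in 4000-replicate runs
during development, re-measured at 2000 replicates in the tests.

Modulation-strength distributions are compared with a two-sided
variance-ratio F test (larger variance in the numerator) and a two-sample
Kolmogorov–Smirnov test with exact small-sample p. All p-values are reported
raw; no multiplicity correction is applied inside this module.

## Cohort stage

CA1 participation — whether a slice with CA3 gamma also shows CA1 gamma —
is compared between genotypes with a Pearson χ² test on the 2×2 table,
df = 1, **without** continuity correction by default: the published
participation p-values (0.59, 0.03, 0.001) are recovered from the
figure-legend slice counts only without Yates' correction. The correction
remains available as a flag. Slices failing CA3 QC are excluded from both
margins, since only CA3-positive slices entered the published analysis. The
young-kainate comparison is the known exception: its printed p = 0.085 is
not reproducible from the legend counts (they give p ≈ 0.13), suggesting a
different per-analysis n, and is not used as a reference value. Omnibus
group comparisons (two-way ANOVA with Šidák post-hoc tests, REML mixed
models) are delegated to standard statistical routines and are not part of
this package's scope.

## Synthetic-data generator

`gen_lfp()` builds a two-channel recording as

* CA3: `gamma_amp · envelope(t) · cos(2π f₀ t + jitter(t))` + 1/f^χ noise
  (+ optional 60 Hz line), with the envelope an exponentiated
  Ornstein–Uhlenbeck process (timescale 0.5 s) emulating the waxing/waning
  of carbachol/kainate gamma, and optional phase diffusion to degrade
  rhythmicity;
* CA1: the same oscillatory component delayed by `ca1_delay` (default 5 ms)
  and scaled by `ca1_gain` (default 0.5), plus independent noise.

Defaults are the study conditions: 10 kHz sampling, 40 Hz carrier of ~50 µV,
20 µV 1/f noise, a 300 s washout-scale span. Every generator is a pure
function of its spec including the seed (same seed, bit-identical samples).

`gen_phase_locked_spikes()` draws an inhomogeneous Poisson train with
intensity λ(t) = λ₀ exp(κ cos(φ(t) − µ)) / I₀(κ). The I₀ normalization
makes the mean rate independent of κ, so modulation strength and firing rate
can be varied orthogonally; the refractory pass (default 2 ms) removes a few
percent of spikes at high κ, which biases the realized rate slightly below
λ₀. A Gaussian waveform template of configurable half-width (default
0.4 ms, PVIN-like) is summed onto a Gaussian noise floor to synthesize the
cell-attached channel. `gen_iie_trace()` injects flat-topped bursts (10 ms
cosine ramps — abrupt, epileptiform-like onsets) of ≥10× RMS amplitude.

`gen_cohort()` emulates the genotype × age cohort structure: per group, the
gamma amplitude is scaled by `gamma_scale` (so measured power scales by its
square) and the CA1 channel is suppressed with probability
1 − `participation`. The default group table mirrors the kainate-cohort
scale of effects: power ratio ≈ 0.5 (amplitude × √0.5) in old mutants and
CA1 participation 0.88/0.68/0.91/0.45 for young-control/young-mutant/
old-control/old-mutant.

What the generator does **not** emulate: biophysical network dynamics, drug
pharmacokinetics and wash-in transients, electrode drift, non-stationary
mains interference, bursting or biphasic cell-attached waveforms, and
correlated noise between CA3 and CA1 electrodes beyond the propagated
oscillation. Tests passing on synthetic cohorts therefore establish the
correctness of the numerics and decision rules, not the biological validity
of conclusions drawn from any particular real dataset.

## Numerical choices and problem sizes

* Epochs are half-open intervals [start, end) in seconds from record start;
  epoching takes contiguous non-overlapping windows from the start of a
  labelled span and discards the partial tail.
* Peak/trough ties: spectral peaks resolve to the lower frequency;
  cross-correlation peaks to the smallest |lag|.
* Degenerate inputs produce typed errors (zero-variance channels, empty
  bands, zero margins) or explicit degenerate results (Cr = 0 with reason;
  NaN mean angle at zero resultant; p clipped to machine minimum on singular
  scatter) rather than silent NaNs.
* Angle reports: radians in [0, 2π), degrees rounded to the nearest degree
  (5.070 rad ↔ 290°, 4.450 rad ↔ 255°).
* Validation problem sizes were chosen to keep the full suite and the
  acceptance script in the minutes range: synthetic cohorts use 20 s slices
  at 2 kHz (the spectral conclusions are rate-independent once the band is
  resolved; the Welch segment is capped at the window length), von Mises
  recovery uses ≥ 1000 spikes per concentration over a 120 s span, and
  Monte-Carlo calibrations use 1000–2000 replicates, giving binomial
  standard errors of ~0.005–0.007 on a 0.05 rejection rate.

## Known limitations

* ABF files are not read directly; records must be exported to the CSV +
  JSON-sidecar interchange format first.
* The Cr α/β rescale convention, the mains-contamination ratio, and the IIE
  detection constants are documented package choices where the antecedent
  methods are underspecified; each is isolated behind one function or config
  key.
* The spike detector is validated against synthetic constructions only; real
  cell-attached recordings with strong movement artefacts may need the
  absolute-threshold override.
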