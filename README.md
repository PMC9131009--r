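# gammaphase

Analysis of pharmacologically induced gamma oscillations (20–80 Hz) in
hippocampal slice recordings, and of the phase-locking of parvalbumin
interneuron (PVIN) spikes to those oscillations.

In the experiments this package serves, gamma activity is induced in *ex
vivo* slices by carbachol or kainate, recorded as local field potentials
(LFPs) simultaneously in CA3 and CA1, sometimes together with a
cell-attached recording of a PVIN. The scientific questions are: how strong
and how rhythmic is the CA3 oscillation; does it propagate to CA1, and with
what delay; and do PVINs fire locked to a preferred phase of the gamma
cycle — per cell, and as a population across cohort groups (genotype × age)?

## What it computes

**Spectral metrics and slice inclusion.** Zero-phase Butterworth band-pass
(5–120 Hz), Welch power spectra over 10 s epochs, peak frequency, peak
power, and bandwidth power — the integral of the PSD over 20–80 Hz. Slices
are included only when the peak frequency lies strictly between 19 and
80 Hz, peak power exceeds 1 µV²/Hz (CA3) / 0.1 µV²/Hz (CA1), and the record
is free of 60 Hz mains contamination.

**Rhythmicity.** The coefficient of rhythmicity from the autocorrelogram,

&nbsp;&nbsp;&nbsp;&nbsp;Cr = (α − β) / (α + β),

with α the second-peak height and β the first-trough height after the
correlogram is rescaled from [−1, 1] to [0, 1]; Cr runs from 0 (arrhythmic)
to 1 (perfect rhythm), with Cr ≥ 0.01 classed rhythmic. CA3→CA1
cross-correlograms give the propagation peak and delay (positive lag = CA1
follows CA3).

**Spike metrics.** Robust-threshold spike detection on cell-attached
traces, spike half-widths (full width at half amplitude), firing
rates and inter-spike intervals over three-minute condition epochs
(baseline / drug / washout), and interictal-like event detection.

**Circular statistics of phase-locking.** Instantaneous gamma phase from
the analytic signal with the cycle peak at 0 rad and trough at π; per-cell
mean vectors (mean angle aⱼ, resultant length rⱼ) with Rayleigh tests; and
second-order population statistics on the cells' mean vectors — Hotelling's
one-sample test of a population mean direction, F(2, n−2), and Batschelet's
two-sample comparison of population means, F(2, N−3) — plus variance-F and
Kolmogorov–Smirnov comparisons of modulation strength.

**Cohort contingency analysis.** CA1 gamma participation compared between
groups by Pearson χ² on 2×2 tables (df = 1, no continuity correction by
default).

**Synthetic recordings.** A seeded generator producing two-channel gamma
LFPs (OU-modulated 40 Hz carrier, 1/f noise, optional mains line, delayed
attenuated CA1 copy), von Mises phase-locked spike trains with realistic
waveforms, ictal-like bursts, and full genotype × age cohorts with
controlled power ratios and CA1 participation probabilities.

## Worked example

```r
library(gammaphase)

## a synthetic 20 s two-channel slice recording: 40 Hz gamma, CA1 delayed 5 ms
sp  <- lfp_spec(duration = 20, fs = 2000, seed = 42)
rec <- gen_lfp(sp)
slice_gamma_metrics(rec)
#>   region peak_frequency_hz peak_power_uv2hz bandwidth_power_uv2 qc_pass   cr xcorr_lag_ms
#> 1    CA3             40.04             7798              1852.4    TRUE 0.87            5
#> 2    CA1             40.04             1943               521.3    TRUE   NA           NA
```

Both regions show a ~40 Hz peak and pass QC; CA3 is strongly rhythmic
(Cr = 0.87) and CA1 lags it by the programmed 5 ms.

```r
## phase-lock a PVIN-like spike train to the CA3 gamma and analyse it
g  <- gen_phase_locked_spikes(get_channel(rec, "CA3_LFP"), spike_spec(seed = 43))
st <- cell_phase_stats("cell01", spike_phases(g$train, g$phase))
#> cell01: n=463 spikes, mean phase 4.360 rad / 250 deg, r = 0.678, Rayleigh p = 9.31e-91
```

The cell fires on the rising phase of the gamma cycle (250°; peak = 0°,
trough = 180°) with strong modulation (r = 0.68, close to the von Mises
value I₁(2)/I₀(2) ≈ 0.70 programmed into the generator) and is significantly
phase-locked.

```r
## group contingency analysis from slice counts (CA1-coincident vs not)
tab <- contingency_2x2(20, 2, 9, 11, row_labels = c("control", "mutant"))
participation_summary(tab)
#>     group n_slices n_ca1_coincident percent chi2       p
#> 1 control       22               20    90.9 10.3 0.00131
#> 2  mutant       20                9    45.0 10.3 0.00131
```

91% of control slices show coincident CA1 gamma against 45% of mutants —
a significant participation deficit (χ² = 10.3, p = 0.0013).

A command-line wrapper is installed at `inst/scripts/gammaphase` with
`simulate`, `slice-metrics` and `phase` subcommands; every run writes its
tables as CSV plus a JSON provenance sidecar (config, package version,
seed).

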