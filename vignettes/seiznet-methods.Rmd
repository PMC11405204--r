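---
title: "Models and methods behind seiznet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seiznet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(seiznet)
```

seiznet analyzes hyperexcitability-driven network change in neuronal
cultures recorded on multiwell microelectrode arrays (MEAs), and phase
synchronization in intracranial EEG. The experimental setting it serves is
a chemoconvulsant kindling design: cultures mature on 8×8 electrode grids,
a pre-treatment baseline is recorded (Day 0), and a potassium-channel
blocker is applied on two consecutive days, with daily recordings tracking
how firing rates and the functional network evolve. This vignette explains
the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The analysis chain

The MEA path is: voltage conditioning → spike extraction → population-burst
detection → binned-count functional connectivity → per-well PCA trajectory
→ group statistics.

### Voltage conditioning

Raw traces (64 channels, 12.5 kHz) are decimated to 2.5 kHz behind an
8th-order Butterworth anti-alias low-pass at 0.4 × the target rate,
band-passed 0.1–300 Hz (Butterworth, overall order 20) to isolate
multi-unit activity, cleaned of mains interference by a cascade of order-4
Butterworth band-stops within ±1 Hz of 60, 120 and 180 Hz, and z-scored
per channel (population SD; a channel of `[1, 3]` maps to `[-1, 1]`;
`sample_sd = TRUE` selects the N−1 convention).

All infinite-impulse-response filters are designed in-house as cascaded
second-order sections: analog Butterworth prototype poles, band transform,
bilinear map, then biquads with zp2sos-style zero–pole pairing (the
lower band edge's near-unit-circle poles take the z = +1 zeros, the upper
edge's take the z = −1 zeros, and the highest-Q sections run last). A
direct transfer-function realization of an order-20 band-pass is
numerically explosive, and even a biquad cascade needs this pairing: with
naive zero assignment the 0.1 Hz poles (radius 0.99996) leak broadband
noise. The realized response of every design is verified against the
analytic transfer function evaluated on the unit circle (within 0.1 dB at
probe frequencies) in the test suite.

Filtering is causal by default, matching named design orders with no
mention of bidirectional filtering; every stage takes `zero_phase = TRUE`
for forward–backward filtering. Two numerical details matter. First, each
section is initialized at its steady state for the first input sample, so
a constant trace passes through unchanged. Second, the 0.1 Hz high-pass
corner has a time constant of seconds: no finite recording determines its
own sub-0.1 Hz content, so a settle transient of roughly two seconds at
each record edge is irreducible (zero-phase filtering pads by odd
reflection scaled to the slowest corner, which shortens but cannot remove
it). Procedures that score detection accuracy therefore exclude a 2-s
settle margin at the edges.

### Spike extraction

No threshold rule is standard-issue in the source setting, so the package
uses the de facto MEA convention: the per-channel noise level is the
robust estimate `median(|x|)/0.6745`, the threshold is `k = 5.5` times
that, both polarities count, supra-threshold runs reduce to their absolute
peak, and events closer than a dead time merge to the larger peak. The
threshold is scale-relative, so detection is invariant to rescaling. The
default dead time is 1 ms; round-trip validation uses 3 ms because an
event limited to the 0–300 Hz band is smeared to about 1/300 s, and a
merging window narrower than the event invites double detections.

Detection timing is validated with zero-phase conditioning: the causal
order-20 band-pass has a strongly frequency-dependent group delay that
disperses sub-millisecond timing, which is a property of the filter, not
of the detector.

A physical point the round-trip tests surfaced: a millisecond-scale
biphasic action potential has almost no energy below 300 Hz. A zero-area
2-ms biphasic waveform is erased by the 0.1–300 Hz chain, and giving it
net area instead pumps energy into the 0.1 Hz corner, which rings for
seconds. The default synthetic event is therefore a Gabor atom (150 Hz
center, 1.5 ms envelope SD) — a multi-unit transient whose energy lies
inside the band — and the detection round trip (recall ≥ 0.95, precision
≥ 0.95, timing error ≤ 1 ms at 8× noise SD) certifies the detector for
events the conditioning chain can transmit. What passing this test does
*not* show is single-unit AP detection through this band; no detector
could.

### Population bursts and burst-excluded connectivity

Pearson correlation between spike trains is positively biased during
epochs of high shared rate, so population bursts — brief, well-global
surges of synchronous firing — inflate every pairwise estimate and are
excluded. Spikes are counted in non-overlapping 50-ms bins (half-open
intervals; a spike on the boundary belongs to the later bin). A bin is a
burst bin when the population count exceeds its mean by 3 SD *and* at
least 25% of electrodes fired; runs merge into intervals. Detecting in
bin space avoids a second time base, since exclusion operates on bins.
`burst_bias_check()` quantifies the inflation by computing the mean
valid-pair statistic with and without burst bins from the same matrix.

Functional connectivity is the Fisher z-transform (`atanh`) of the Pearson
correlation over non-burst bins for each unordered electrode pair
(k = n(n−1)/2 = 2016 for 64 electrodes; an ordered-pairs reading is
internally inconsistent with a symmetric correlation). Correlations are
clipped to ±(1 − 10⁻⁷) so collinear pairs stay finite; pairs involving a
zero-variance electrode are invalidated rather than zero-filled, because a
silent electrode carries no correlation information and zeros would bias
distribution summaries. Networks are read off by thresholding at
Fisher z > 0.80 ("strong" connections), yielding edge lists and degrees.

### Per-well trajectory embedding

Each well's per-day pairwise-z vectors are stacked into an m × k feature
matrix A (m days, k pairs, fixed lexicographic order; a pair invalid on
any day is dropped from all rows). Embedding is per well: a pair's
connectivity is a meaningful feature only within its own well, so pooling
wells into one feature matrix would misalign features. Columns are
mean-centered but not variance-scaled — all features share Fisher-z units
and scaling would explode near-constant pairs (a documented switch
enables it). The rows are projected onto the top two right singular
directions of the centered matrix (economy SVD on the 3 × k row space),
with a deterministic sign convention (largest-magnitude loading positive).
Network change is the Euclidean distance of each day's point to the Day-0
point.

With m = 3, the centered rows span at most a plane, so the two-component
embedding is **exactly** distance-faithful; the package computes the
full-space distances alongside and the acceptance suite asserts their
equality to 10⁻⁸ relative tolerance on random matrices. This is the
property that makes two-dimensional trajectory plots trustworthy for
three-day designs.

### Statistics

Group comparisons use two-tailed t-tests (pooled Student by default, Welch
switch), Cohen's d from the pooled SD, and 95% CIs on the difference.
Normality is gated by the D'Agostino–Pearson K² omnibus (skewness and
kurtosis z-scores, χ²₂ reference; n ≥ 8 required), implemented from the
standard transformations and cross-checked against an independent
implementation at full precision. Multiple comparisons use Holm–Bonferroni
step-down with explicit reject flags; adjusted p-values are the monotone
running maximum and are cross-checked against `p.adjust`. Degenerate
inputs are flagged, never silently mangled: identical zero-variance groups
give t = 0, perfect separation gives t = ±Inf with p = 0, and a zero
baseline rate makes the normalized MFR undefined rather than divided.

## The intracranial-EEG path

Per epoch and contact: local detrending (centered running mean, 1-s
default window, shrinking at the edges), regression-based line-noise
removal (least-squares sine/cosine fit at 60 and 120 Hz, subtracted), an
equiripple type-1 FIR low-pass (order 180; passband edge 150 Hz, chosen
below the 180 Hz harmonic and well above the analysis band), then the
high-gamma band-pass (order 390, passband 70–90 Hz, 10 Hz transitions),
both Parks–McClellan designs applied with exact group-delay compensation.
Phase locking is computed from analytic-signal phases (FFT construction of
the Hilbert transform): PLV = |mean exp(i(φx − φy))|, in [0, 1], invariant
to amplitude scaling and constant phase offsets. "Phase of the analytic
signal" is the standard reading of phase-locking coherence and is the
estimator implemented. Pairs are labeled SOZ-SP (seizure-onset zone to
seizure-spread) or SOZ-control; per patient, class means are compared by a
paired t-test across patients.

## What the synthetic generator emulates

The generator is the package's ground-truth instrument, and its defaults
are the package's study conditions.

**Spike trains.** A discrete-time conditionally-Bernoulli process at 1-ms
steps: electrode i fires with probability
`base_rate·Δt·gain(t) + Σ_j coupling[j,i]·1[j fired at t−1]`, clipped at
1 − 10⁻⁶ (clips counted and warned — this keeps the process defined under
extreme gains). This is deliberately not a continuous-time Hawkes process:
it is exact to simulate, and one-step excitation is sufficient to induce
graded correlation at the 50-ms bin scale. The burst state is well-global
(all electrodes share the gain), a two-state Markov chain with on-rate
`burst_rate` (default 6/min) and mean duration `burst_duration` (0.3 s),
gain 5 — the source setting reports no burst statistics, so these are
free, realistic choices for mature cultures, not calibrated values.

**Coupling.** Two substrates. `random_coupling()` assigns a directed
weight to a random fraction of pairs (default 5% at 0.3) — the recovery
benchmark, scored against `max(w_ij, w_ji)` since direction is not
identifiable from symmetric correlation. `paired_coupling()` (the
treatment-course default: 16 disjoint pairs, weight 0.2) couples disjoint
electrode pairs reciprocally; because no electrode belongs to two pairs,
excitation cannot chain across the network and the dynamics stay
subcritical for any weight < 1. Directed random graphs boosted ×3 under a
burst gain cross a branching threshold (mean offspring per spike > 1) and
run away — biologically evocative but numerically chaotic — so the
controlled treatment substrate uses the paired form.

**Treatment design.** Day-0 multiplier 1; treated wells get rate
multipliers (defaults 1.9 and 2.5, mirroring reported normalized-MFR
elevations typical of this preparation — generator settings, not claims)
and a ×3 boost of their coupling weights on Days 1–2. Controls keep
baseline parameters with fresh draws. Child seeds follow
`(seed·1009 + well·100003 + day·7919) mod (2³¹−1)`, so adding wells never
perturbs existing wells and nearby course seeds share no stream. With
coupling present, the realized Day-2 normalized MFR exceeds the bare
multiplier (≈3.9 with defaults) because excitation adds spikes; the
multiplier is recovered exactly in uncoupled configurations, and that is
how the rate model is tested.

**Voltage.** Gaussian noise at `noise_sd`, the template at each spike time
(negative peak on the spike sample), optionally a shared 60 Hz sinusoid.
This emulates noise, events and mains — not electrode-to-electrode gain
variation, drift, or biological artifacts.

**Phase-coupled pairs.** Two unit-amplitude carriers at the band center
whose phase difference is a smooth stationary process with an exact von
Mises(0, κ) marginal: a unit-variance AR(1) Gaussian process (correlation
time 8 carrier cycles) mapped through the von Mises quantile function.
The population PLV is the Bessel ratio I₁(κ)/I₀(κ). Smoothness is load-
bearing: piecewise-constant per-cycle phase draws put jumps into the
signal that Hilbert phase extraction smooths, inflating measured PLV by
~0.03 at κ = 0.5–1; the AR construction removes that bias at the cost of
fewer effective independent draws (≈ n_cycles/8), which the calibration
tests account for. At κ = 0 the sample PLV follows the Rayleigh floor
√π/2·n_eff^(−1/2).

**Independence calibration.** The null substrate is exactly band-limited
Gaussian noise (Fourier masking). The spread of a null PLV estimate is set
by epoch duration × envelope bandwidth — not by the number of samples — so
at a fixed sample count the calibration samples at 182 Hz, just above
twice the 90 Hz band edge, making the epoch as long as possible; there the
null PLV falls below 0.05 in ≈98% of runs. At 1000 Hz the same sample
count spans only 10 s and the null PLV hovers near 0.056 regardless of
estimator quality.

**What passing these tests shows — and does not.** The synthetic wells
have stationary rates between bursts, homogeneous electrodes, and
one-step excitation; real cultures drift across days, have heterogeneous
units and electrode yields, and couple with distributed delays. Passing
says the *pipeline* recovers planted structure of realistic magnitude; it
does not certify effect sizes on real recordings, and the headline
group-level numbers from any particular biological study (MFR ratios,
distance means, PLC values) depend on those recordings and are not
reproduction targets here.

## Problem sizes and calibration designs

Validation runs at the study's native scale where the quantity demands it:
coupling recovery and treatment-direction replicates use 64-electrode,
300-s wells (20 replicates of a 9-vs-9 course for direction). The type-I
calibration of the zero-effect design instead uses 16-electrode, 60-s
wells over 100 replicates: the size of a calibrated test does not depend
on the dimension of the null wells, and the smaller design makes a
100-replicate calibration a routine part of every test run. The
D'Agostino–Pearson gate is calibrated on n = 5000 Gaussian samples (200
draws) and powered on n = 200 exponential samples.

## Known limitations

- The spike detector is validated for band-compatible multi-unit events;
  single-unit action potentials do not survive a 0.1–300 Hz band.
- Causal conditioning preserves design orders but disperses event timing;
  use `zero_phase = TRUE` when timing matters.
- The first/last ~2 s of any conditioned record carry the high-pass settle
  transient.
- Burst detection is population-level by design; per-channel burst
  statistics are out of scope.
- The PLC estimator is the standard analytic-signal PLV; alternative
  coherence estimators are not implemented.
- Directed/lagged connectivity, partial correlation and shuffle-based
  significance thresholds are out of scope.
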