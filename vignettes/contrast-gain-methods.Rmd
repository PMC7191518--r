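---
title: "Methods: models, estimators and design choices in contrastgain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in contrastgain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrastgain)
```

This vignette documents the scientific models the package implements, the
parameters that matter, and the choices made where the design was genuinely
open. The companion README shows a worked example; the test suite and
`scripts/acceptance.R` compute every empirical claim referenced here.

## Stimulus model

A dynamic random chord (DRC) is a sequence of 25-ms chords, each a
superposition of 25 pure tones on a quarter-octave grid from 1 to 64 kHz.
The level of every tone is redrawn each chord from a uniform distribution
with mean 40 dB SPL; *spectrotemporal contrast* is set by the width of that
distribution — 20 dB in the low-contrast condition, 40 dB in the
high-contrast condition — so the level SD doubles between conditions.

Choices the stimulus description leaves open:

- **Continuous levels.** Levels are drawn from the continuous uniform; a
  discrete-step option (`level_step`) is exposed. The continuous uniform's
  SD is `range / sqrt(12)` (5.77 dB and 11.55 dB for the two ranges). The
  conventional summary values for these conditions (6.2 and ~12 dB) are
  slightly larger than the continuous-uniform closed form; since the
  computation behind those summaries is not specified, the package reports
  the SD of its actual draws and does not attempt a reconciliation.
- **Ramps.** Chord onset/offset ramps are linear and overlap-added: a
  chord's 5-ms onset ramp coincides with the previous chord's offset ramp,
  so each chord occupies exactly one 25-ms period and the summed envelope
  is flat through transitions.
- **Phases.** Tone phases are randomized once per tone from the stimulus
  seed and stored, so a stimulus is exactly reproducible from
  `(seed, sample_rate)`.
- **Calibration.** dB SPL maps to linear amplitude against a configurable
  reference (default: 94 dB SPL → amplitude 1.0). Absolute calibration is
  hardware-specific; only relative levels matter for every analysis here.
- **Waveform contrast `c`.** Several definitions of the envelope
  contrast are plausible (per-chord vs whole-waveform, RMS vs analytic
  envelope). `measure_contrast()` uses the SD/mean of the analytic-signal
  (Hilbert) envelope of the full synthesized waveform and records that
  definition in its output rather than forcing any particular printed
  value.

Alternating-contrast sequences map one standard-uniform pattern affinely
onto each condition, so chord-level rank order is preserved exactly and the
40-dB midpoint is a fixed point; the first (low-contrast) segment is
flagged for exclusion to avoid silence-to-sound onset transients. Embedded
noise bursts replace whole chords with frozen Gaussian noise (default
80 dB SPL, seeded) and are recorded as metadata so the level matrix used
for receptive-field fitting is unchanged.

## Separable STRF estimation

The response model is rank-1 in frequency × lag:
`y_t = Σ_f Σ_l k_f[f] k_h[l] L[f, t−l] + b`. The design matrix holds the
stimulus levels at lags 0..`n_lags − 1` (default 8 lags = 200 ms; metric
windows are capped at 100 ms), with the response averaged within each
25-ms chord frame.

Fitting is alternating least squares: solve for `k_f` by linear regression
holding `k_h` fixed, then for `k_h` holding `k_f` fixed, to convergence.
Each subproblem includes an intercept, so the block-coordinate loss is
non-increasing; the trace is stored in `fit_meta` and asserted in tests.
Numerical choices:

- **Initialization**: `k_h` starts as a unit impulse at the second lag —
  deterministic, and on well-posed problems it reaches the same optimum as
  random starts (verified to Frobenius distance < 1e-6 over 10 random
  restarts on noiseless rank-1 data).
- **Convergence**: relative loss change < 1e-8 or 200 iterations.
- **Scale/sign convention**: at exit `||k_h|| = 1` and the
  largest-magnitude element of `k_f` is positive, making the factorization
  unique.
- **Ridge**: the default penalty is zero; a ridge floor engages
  automatically (and is flagged) only when a subproblem is numerically
  singular. A nonzero default was considered and rejected because even a
  small penalty (1e-4 of the mean Gram diagonal) biases the kernels by
  ~0.5% on the canonical design, which would defeat exact parameter
  recovery; `lambda` remains available for noisy, ill-conditioned data.
- **Optimality reference**: on rank-1 data the ALS loss is checked against
  an independent oracle — the rank-1 SVD truncation of the unconstrained
  least-squares kernel (with refitted intercept). ALS attains that loss
  (and on noisy data typically betters it, since truncating the
  unconstrained estimate is merely a feasible rank-1 point).
- **Train/test split**: the held-out 10% is the final contiguous block of
  each sequence, avoiding temporal leakage; held-out CC is computed on the
  concatenated test block. Units with CC < 0.04 are excluded as
  unpredictive.

Tuning metrics: best frequency is the bin with the largest `k_f`
coefficient; bandwidth is the contiguous half-height width around that
peak, in octaves on the log-spaced axis with linear interpolation at the
half-height crossings; the temporal window is the analogous half-height
width around the `k_h` peak within the first 100 ms. All-zero kernels are
flagged degenerate rather than producing arbitrary metrics.

Cross-condition transfer refits only a scale factor and offset
(closed-form least squares on the stimulus-driven component), the minimal
model of a pure gain change.

## Gain statistics

Per condition, `R_min` and `R_max` are the 5th and 95th percentiles of the
response (linear interpolation between order statistics — the method is
otherwise unspecified and is exposed via `probs`), and `S = R_max − R_min`
is the operating range. `G_relative` is the ratio of contrast-gain ratios
between light conditions; it is invariant to common rescaling of the four
ranges, equals 1 under a contrast-equal gain change, and its formula's
denominator for `R_offset` is taken as the *light-off* range (the printed
formula omits condition subscripts; normalizing by the control dynamic
range reads most naturally, and the choice is a documented argument).

Population tests use standard procedures (Wilcoxon signed-rank, paired t),
two-sided except where the criterion's wording implies a direction: the
photo-tagging criterion demands a significant *increase* under light, so a
one-sided paired t test is used, combined with the strict spike-width
criterion (< 0.25 ms).

## Whole-cell analysis

**Access-resistance model.** The mean voltage change evoked by a square
current pulse is `δV(t)/I = R_access(1 − e^(−t/τ_access)) +
R_input(1 − e^(−t/τ_input))`: a fast electrode component plus the slow
membrane charge. Fitting is separable nonlinear least squares: a coarse
log-spaced grid over the two time constants with an exact linear solve for
the amplitudes at each grid point (the retained error surface shows the
expected clear interior minimum), then Nelder–Mead refinement. If the grid
minimum falls on the boundary the fit is flagged and rerun on a widened
grid. Because the pulse train (20 cycles at 20 Hz, 50% duty) reaches a
periodic steady state, the observed rise amplitude of each component is
attenuated by `(1 − e^(−T_off/τ)) / (1 − e^(−T/τ))`; the fit inverts this
analytically per component, which is what lets a 20-ms membrane time
constant be recovered from 25-ms pulses. The first two cycles are dropped
from the cycle average so the periodic state has been reached.

**Up states.** Spontaneous depolarized plateaus make the pooled membrane
potential bimodal; sweeps are excluded when they stay above the pooled
mean for at least 50 ms. Because the mean-threshold rule is meaningless
for a unimodal distribution, a bimodality precondition is applied first —
the sample bimodality coefficient `(skew² + 1) / kurtosis` against the
uniform-distribution benchmark 5/9. (A formal dip test would serve the
same purpose; the moment-based coefficient is dependency-free and
sufficient for this gating role, with false-positive behavior checked
under the unimodal null in the tests.)

**Spike detection and threshold.** Spikes are upward crossings of
mean + 7 SD; the mean is taken after 3-ms median-filter despiking and the
SD is the scaled MAD of the raw trace — a running-median SD would
underestimate the noise floor, and a raw SD would be inflated by the
spikes themselves. Spike threshold is the maximum of the second
time-derivative (on a 0.2-ms Gaussian-smoothed copy) within 1 ms before
the crossing; a curvature maximum at the window edge (e.g. a pure
exponential rise) is flagged as having no interior inflection. The slope
of spike threshold against injected current, in mV/pA, converts directly
to the uncompensated access resistance in GΩ (×1000 → MΩ) and validates
the compensation.

**Conductance estimation.** At each timepoint the recorded voltage is
regressed on injected current across all sweeps (pooling trials rather
than per-level means, so every repetition contributes); the inverse slope
is `G(t)` in nS (`G = 1000 / R(MΩ)`), the intercept the zero-current
voltage. Reconstruction r² predicts every sweep from `(G, offset, I)` over
all timepoints. For a passive membrane the voltage is exactly affine in
the holding current even under a time-varying synaptic conductance, so r²
shortfall measures trial noise and nonlinearity, not model misfit.

**Power law.** `rate = k (V_m − V_rest)₊^p` is fitted jointly across
contrast conditions with a shared exponent and per-condition gains. For a
fixed `p` each gain has a closed-form nonnegative least-squares solution,
so the fit reduces to a 1-D optimization over `p` (search interval
0.2–8) — more robust than a joint 3-parameter descent. V̄m/rate pairs are
formed per 25-ms frame averaged across trials (the binning is otherwise
unspecified).

Units throughout: mV, pA, MΩ, nS, ms.

## What the simulators emulate — and what they do not

The LN simulator drives a rank-1 kernel through a selectable output
nonlinearity (half-wave-rectified linear by default; an identity option
exists for exact-recovery validation) with contrast-dependent gain, a
light-condition gain multiplier and offset, and additive Gaussian noise
floored at zero. The whole-cell simulator integrates a passive membrane
(exponential Euler at 20 kHz default — unconditionally stable for passive
dynamics) with a conductance drive derived from the DRC level matrix,
an electrode component (injected current × `R_access`, first-order
low-passed at `τ_access`), Poisson up-state plateaus with jittered
amplitude, inserted stereotyped spike waveforms at threshold crossing, and
white trial noise.

These generators reproduce the *statistical structure the analyses
assume*: rank-1 spectrotemporal drive, multiplicative gain changes, Ohmic
current–voltage relations, bimodal up-state distributions. They do not
emulate spike-sorting artifacts, electrode drift, conductance-based spike
dynamics, opsin kinetics (light effects are parameterized directly as
gain/offset), cortical-depth profiles, or correlated network noise.
Passing recovery tests therefore demonstrates that the estimators are
correct and unbiased under their stated assumptions — not that real
recordings satisfy those assumptions.

Default study conditions follow the recording protocol: 40-s DRCs of
1,600 chords, four stimuli per condition presented three times (480 s of
fitting data per condition), 90/10 train/test, 11 alternating 1-s segments
with the first excluded, 50-ms bursts 500 ms into each segment, four
holding-current levels spanning −80 to +40 pA, and 40-pA pulse trains.
Where a value is not dictated by the protocol it was chosen once for
realism: LN response noise at SD 1–2 (held-out CC roughly 0.4–0.7,
comfortably above the 0.04 inclusion floor), membrane `R_input` 100 MΩ
with τ 20 ms, electrode `R_access` 20 MΩ with τ 0.5 ms, rest −70 mV,
trial noise 0.3 mV. The BF-recovery property is evaluated at response
noise SD 1 (a moderate-SNR regime; the property is conditioned on
held-out CC ≥ 0.3, which this regime satisfies for every seed).

## Reports, formats and reproducibility

Every simulated-experiment report embeds the full configuration, an MD5
hash of it, the package version and all seeds; identical configurations
reproduce byte-identical tables. Serialization is plain text: level
matrices and per-unit ledgers as CSV, metadata and population summaries as
JSON. Functions accepting seeds restore the caller's RNG state, so seeded
generators compose without side effects.

## Known limitations

- The separable model is rank-1 by construction; genuinely inseparable
  receptive fields are out of scope (a full-rank kernel exists only as a
  test oracle).
- The parametric sigmoid gain model is not implemented; the nonparametric
  percentile ledger is the supported analysis.
- Conductance estimation assumes the compensated voltage is affine in
  holding current; strong voltage-gated conductances would violate this
  and depress the reconstruction r² rather than being modeled.
- The contrast measure `c` depends on the adopted envelope definition and
  is reported alongside it, not as a calibration target.
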