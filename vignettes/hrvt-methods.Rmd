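---
title: "Estimating heart-rate-variability thresholds from DFA alpha-1 during ramp exercise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heart-rate-variability thresholds from DFA alpha-1 during ramp exercise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvt)
```

## The measurement problem

During incremental exercise the beat-to-beat pattern of the heart loses its
fractal organisation in a characteristic way.  The short-term scaling
exponent of detrended fluctuation analysis (DFA alpha-1), computed over box
sizes of 4–16 beats, sits at or above 1.0 at low intensity (well-correlated,
1/f-like dynamics), falls through ~0.75 around the first ventilatory
transition, reaches 0.5 (uncorrelated, white-noise-like) near the second,
and continues into an anticorrelated regime below 0.5 at severe intensity.
The intensities at which alpha-1 crosses 0.75 and 0.5 are the first and
second heart-rate-variability thresholds, HRVT1 and HRVT2, and can be
expressed as a time into the test, a heart rate, or an oxygen uptake.

`hrvt` implements this estimation chain end-to-end for cycling ramp tests —
RR-interval preprocessing, time-varying DFA, threshold extraction, gas
exchange mapping — plus the method-agreement statistics used to compare
thresholds obtained under different ramp slopes, and a synthetic-participant
generator with known ground truth for validating the whole pipeline.

## DFA alpha-1 and its time-varying trace

For a window of RR intervals `x`, the profile is the cumulative sum of the
mean-centered series.  It is cut into non-overlapping boxes of `n` beats
taken from the start (leftover beats are discarded); within each box a
least-squares line is removed, and `F(n)` is the RMS of the pooled in-box
residuals.  Alpha-1 is the OLS slope of `log10 F(n)` against `log10 n` over
every integer `n` in 4–16.  Both the vectorized implementation and an
independent naive-loop implementation live in the test suite and must agree
to 1e-10.

The time-varying trace follows the rolling-recalculation convention: each
value is computed from the beats occurring 1 min before to 1 min after its
time stamp (a half-open window, `[t - 60, t + 60)`, so that beats are never
counted twice), stepping every 5 s.  A window is valid only if it holds at
least `min_beats = 64` beats (four boxes at the largest scale) and its
fraction of artifact-flagged beats is below the 5% ceiling.  No partial
windows are evaluated: the trace starts at `window/2` and ends at
`duration - window/2`.

Within each window the series may first be detrended by smoothness priors:
the trend is `(I + lambda^2 D2' D2)^{-1} x` with `D2` the second-difference
operator and `lambda = 500`, the conventional HRV preprocessing weight.  We
solve the algebraically identical dual system
`residual = lambda^2 D2'(I + lambda^2 D2 D2')^{-1} D2 x`, which remains
well-conditioned as `lambda` grows (the primal matrix is numerically
singular long before the interesting limit where the trend becomes the
best-fitting straight line).  Detrending is applied per analysis window so
each window is self-contained; it can be disabled via
`detrend_config(enabled = FALSE)`.

## Artifact handling

Missed, extra and ectopic beats corrupt alpha-1 badly, so beats are
classified before analysis using a time-varying threshold scheme: successive
RR differences and deviations from an 11-beat running median are normalized
by 5.2 times the quartile deviation estimated over a sliding 91-beat
neighborhood (with a 25 ms floor so near-constant series are not flagged).
An interval approximately equal to the sum of two local intervals is a
missed beat; two successive short intervals summing to one local interval
are an extra-beat pair; a short interval followed by a compensatory long one
is an ectopic couple; remaining outliers are flagged long/short.  A beat
immediately after a flagged one is judged only by its own deviation from the
local median, because its difference to the artifact beat is contaminated —
without this rule the detector flags two or three beats per event and whole
runs of windows become unusable.  All constants are exposed in
`artifact_detect_config()`.

Correction preserves the time axis: missed intervals are split in two,
extra pairs merged, and ectopic/long-short runs replaced by a cubic spline
through *unflagged* neighbors, rescaled so each run's elapsed time is
preserved exactly.  Flags are carried onto the corrected beats so that the
artifact fraction of any window remains computable afterwards.  The
usability ceiling (below 5% flagged beats) is applied to the threshold
interpretation span: the quality flag on an estimate is raised if the span
as a whole, or any single window overlapping the fitted segment, reaches
the ceiling.

## Gas-exchange preprocessing

Breath-by-breath oxygen uptake is cleaned in a fixed order: (1) removal of
breaths deviating more than 3 local SD from the local mean, computed over a
centered 9-breath window excluding the candidate, in a single pass; (2)
linear interpolation onto the integer-second grid; (3) a centered 20-sample
rolling mean.  An even window cannot be exactly symmetric; ours covers
`t - 10` to `t + 9` seconds, which makes a step input average to exactly
half at the step and makes a linear ramp trail by half a second's increment.
The peak of the rolled series is the V̇O2max; the same 20-s rolling rule
applied to the HR channel gives HRmax.

## Threshold extraction

The decline segment is selected automatically (the historical workflow used
visual selection; `segment = c(t0, t1)` reproduces it).  Among valid windows
at or after ramp onset, the segment ends at the first window with
`a1 <= 0.5` — or, if 0.5 is never reached, at the last attainment of the
trace minimum, so that a flat trace fits its whole extent and then fails
the negative-slope check with a "no decline" error.  The segment starts at
the latest window at or before the end with `a1 >= 1.0`, constrained to
leave at least five fit points.  An OLS line is fitted over the segment;
fits with R² below 0.7 carry a `low_r2` flag.

Crossing times come from the fitted line, `t = (level - intercept)/slope`,
not from raw trace interpolation; crossings beyond the segment end are
allowed but flagged `extrapolated`.  V̇O2 at a crossing is the 20-s rolled
value at the nearest grid second divided by body mass (linearly extrapolated
from the final 60 s, with a flag, for crossings up to 60 s past the
recording).  Heart rate at a level is obtained by regressing the window-mean
HR (from the same RR windows as alpha-1, i.e. the same elapsed frame) on
alpha-1 over the segment and evaluating the line at the level; mean HR per
window is `60000 / mean(RR)`.

## Agreement statistics

The cohort battery compares thresholds across ramp slopes, per metric
(HRVT1/HRVT2 as V̇O2 and HR): Pearson r with the standard error of estimate
from the y-on-x regression, classified low/moderate/high at 0.3–0.5,
0.6–0.8 and ≥0.8 (values in the printed gaps are left unclassified);
Bland–Altman bias with limits of agreement at exactly ±2 SD of the paired
differences (±2, not ±1.96, following the convention of the original
analysis), switching to regression-based limits (fitted line at the mean
±2 residual SD) when the slope of differences on pair means is significant
at 0.05; paired t-tests; Shapiro–Wilk normality of the differences
(delegated to `stats::shapiro.test`); ICC(3,1) — two-way mixed,
consistency, single measures — with the Shrout–Fleiss F-based 95% interval,
classified poor/fair/good/excellent at 0.40/0.60/0.75; and single-factor
repeated-measures ANOVA.  ICC and ANOVA share one sum-of-squares
decomposition, so their error mean squares are identical by construction;
the ANOVA is cross-checked against `stats::aov` in the tests.  No
multiple-testing correction is applied.

## The synthetic participant model

Because no public recordings accompany this kind of protocol, validation
runs on synthetic participants whose true thresholds are known.

*Physiology.*  Work rate follows the standard protocol (4 min at 20 W,
6 min at 60/80 W for females/males, 4 min at 20 W, then a linear ramp of
15/30/45 W·min⁻¹), capped at a participant-specific peak power with a 60-s
hold before task failure.  Both heart rate and V̇O2 are functions of the
*effective* workload, lagged by a 30-s mean response time: V̇O2 is linear in
effective work (10 mL·min⁻¹ per W above a 500 mL·min⁻¹ resting value) and
HR follows a smoothly saturating curve from its 20-W baseline to HRmax at
peak power.  Because both responses depend on effective work alone, the HR
and V̇O2 at any fixed HR anchor are identical across ramp slopes *by
construction* — slope invariance is built in, so recovery tests isolate the
estimator.  This is a construction choice, not a claim about real
physiology.

*Scaling-exponent profile.*  The target alpha-1 profile is piecewise
linear: a plateau at 1.05, a near-linear decline, and a floor at 0.30.  The
decline bounds are derived per slope so the profile crosses 0.75 exactly
when HR reaches the participant's HRVT1 anchor (default 150 bpm; drawn from
130–165 bpm across a cohort) and 0.5 at the HRVT2 anchor (default 161 bpm).

*Synthesis.*  RR fluctuations are generated in 30-s blocks by Fourier
spectral synthesis with random phases, crossfaded over 5 s, scaled to an SD
that decays exponentially with heart-rate reserve (40 ms at rest to ~4 ms
at peak; the collapse happens mostly below the first threshold, as with
parasympathetic withdrawal), and added to the mean RR `60000 / HR(t)`.
The asymptotic correspondence between the power-spectral exponent and the
DFA exponent is `beta = 2 * alpha - 1`; over the finite 4–16-beat band,
however, the estimator is biased (a white-noise series reads about 0.58,
not 0.50 — the expected band slope is computable exactly from the process
autocovariance via the in-box detrending projector, see
`dfa_band_response()`).  The generator therefore *inverts* this analytic
band response when choosing `beta`, so the emitted series carry the
prescribed exponent as measured by the estimator itself.  Without this
inversion the generated series would systematically read high and every
"ground-truth" crossing would be mis-specified by tens of seconds.

*Imperfections.*  Missed/extra/ectopic beats are injected at configurable
per-class rates (0.4% each across cohorts by default) with a truth mask for
detector evaluation; breaths carry 4% multiplicative noise and occasional
±4 SD spikes to exercise the outlier filter.

What the generator does *not* emulate: respiratory sinus arrhythmia and its
frequency structure, day-to-day biological variability between visits,
drift in electrode contact, cadence effects, or smooth (non-piecewise)
alpha-1 transitions.  Passing recovery tests therefore demonstrates that
the estimation chain is faithful to its own definition under realistic
noise and artifact burdens — not that HRVTs agree with ventilatory
thresholds in humans.

## Numerical choices

- Boxes in `F(n)` are non-overlapping from the window start; leftover beats
  are discarded (classic formulation, oracle-tested).
- Window membership is half-open on beat occurrence times; beat `i` occurs
  at the cumulative sum of intervals `1..i` (recordings start at `t = 0`).
- `min_beats = 64` guarantees at least four boxes at `n = 16`.
- Ties at the trace minimum resolve to the last index; the segment-start
  rule is applied among windows leaving ≥5 fit points.
- The detrending solve uses the dual (n−2)-dimensional SPD system; `lambda
  = 0` short-circuits to a zero residual.
- Degenerate inputs error early with stage-named messages: constant windows
  ("zero fluctuation"), flat traces ("no decline"), zero-variance paired
  differences, identical ICC columns (ICC 1 with a degenerate interval).
- All generator randomness flows from one integer seed per participant and
  slope; identical seeds reproduce byte-identical files.

## Problem sizes

The validation suite runs at desk scale by design: DFA calibration uses 20
replicates of 10 000-sample series cut into 150-sample windows; oracle
equivalence uses ≥20 random instances per statistic; the recovery study
uses a 17-participant × 3-slope cohort (51 recordings of 20–40 min
simulated time each); artifact robustness uses 20 seeds at 3% injection.

## Known limitations

- **Finite window resolution.**  A 2-min rolling window convolves the true
  alpha-1 trajectory.  Where the decline is short relative to the window —
  steep ramps, or thresholds close to the floor of the profile — the
  measured trace is stretched, and the fitted-line crossing at 0.5 lands
  systematically late by an amount that grows with ramp slope.  HRVT1, near
  the decline midpoint, is much less affected than HRVT2.  The package's
  own cohort recovery test computes this directly: ICCs across slopes stay
  excellent, but HRVT2 times can exceed a ±30 s recovery band and paired
  tests on bias-free synthetic cohorts are powerful enough to detect the
  slope-dependent component that biological noise would mask in real data.
  This is a property of the windowed method itself, not of this
  implementation.
- The automatic segment rule replaces expert visual selection; traces with
  long plateaus hovering near 1.0, or that never reach 0.5, depend on the
  stated tie-break rules.  The `segment` override exists for exactly these
  cases.
- The artifact classifier reproduces the published decision structure but
  not any proprietary tuning; constants are exposed and auditable.
- GET and RCP are accepted as externally supplied values only; the package
  never determines them from gas-exchange curves.
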