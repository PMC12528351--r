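---
title: "Methods: individualised TRIMP weightings from lactate and DFA-alpha1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualised TRIMP weightings from lactate and DFA-alpha1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphatrimp)
```

## The problem and the model

A training session's *internal* exposure — the homeostatic disturbance
it causes — differs between athletes doing the same external work,
because the physiological cost of a given relative heart rate is
fitness-dependent. Training-impulse (TRIMP) methods summarise a session
as accumulated weighted intensity, where the weighting maps the
fractional elevation of heart rate,
$\Delta HR = (HR - HR_{rest})/(HR_{max} - HR_{rest})$,
to an individually calibrated physiological response.

Two calibrations are implemented.

**Lactate (iTRIMP).** During a step incremental test (3-min stages,
+1 km/h per stage, blood sampled at each stage, stage HR taken as the
last-30-s average), blood lactate grows approximately exponentially in
$\Delta HR$:
$\mathrm{BLa} = a_i e^{b_i \Delta HR}$. The intercept $a_i$ (mmol/L) is
the resting lactate concentration; $b_i$ is the growth rate. Both are
estimated by Levenberg-Marquardt nonlinear least squares, initialised
from the log-linear regression of $\log \mathrm{BLa}$ on $\Delta HR$.

**DFA-alpha1 (alphaTRIMP).** The short-scale scaling exponent of RR
intervals (detrended fluctuation analysis over 4-16-beat boxes) sits
above 1 at rest and falls towards and below 0.5 with intensity, in a
reverse-sigmoidal, athlete-specific way. Because the absolute level and
span of the exponent vary between athletes, the trace is first
normalised to $[0,1]$ between the athlete's own anchors:
$\alpha_{norm}(t) = (DFA_{rest} - DFA_t)/(DFA_{rest} - DFA_{maximal})$,
with $DFA_{rest}$ the highest value at rest and $DFA_{maximal}$ the
lowest at maximal intensity. A one-parameter exponential
$\alpha_{norm} = p\, e^{q_i \Delta HR}$ is then fitted with the
intercept fixed at the cohort constant $p = 0.06$; grid rows with
$\alpha_{norm} = 0$ are dropped before fitting, since the exponential
never attains zero. The per-athlete free intercepts $p_i$ (from the
two-parameter fit) can be re-averaged via `standardise_intercept()` if a
new cohort constant is wanted; fixing $p$ reflects that the normalised
scale is bounded, so individuality is carried by the slope $q_i$ alone.

Both weightings differentiate to themselves scaled by the slope
coefficient ($b_i y$ and $q_i w$), which the tests verify to machine
precision — useful because the *slope* of the weighting at a given
intensity is how fast perceived physiological cost is changing there.

**Session scoring.** The session integral over $\Delta HR$ samples is
exposed in two conventions, because the notation of a "pseudo-integral
over all $\Delta HR$ data points" is genuinely ambiguous against the
established individualised-TRIMP accumulation it descends from:

* `manzi` (default): $\sum_t \Delta t \cdot \Delta HR_t \cdot w(\Delta HR_t)$ —
  duration × fractional elevation × weighting, the classical form;
* `literal`: $\sum_t \Delta t \cdot w(\Delta HR_t)$ — the weighting alone
  integrated over time.

The choice is recorded in every `trimp_result`; scores are comparable
only within a stated convention. Missing HR samples contribute zero and
are counted, so a dropped strap second cannot silently inflate or
deflate a score.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| artifact `rel_threshold` | 0.20 | fraction | standard HRV practice: a beat deviating >20% from the local median of accepted beats is implausible physiologically |
| artifact `window_beats` | 11 | beats | local median wide enough to be robust to runs of 2-3 artifacts |
| exclusion bound | 0.03 | fraction | recordings with more than 3% artifacts are excluded from weighting generation (strictly above; 3.0% exactly is kept) |
| DFA `window_s` / `step_s` | 120 / 5 | s | the short-scale exercise DFA lineage: 2-min windows recomputed on a 5-s grid |
| DFA `scales` | 4-16 | beats | the short-scale (alpha1) regime |
| DFA `min_beats` | 64 | beats | 4 × the largest box; fewer beats cannot support the log-log slope |
| `detrend_order` | 3 | — | see *Numerical choices* |
| fixed intercept `p` | 0.06 | — | cohort constant of the normalised-DFA exponential |
| LT2 `delta` | 1.5 | mmol/L | rise above the lactate baseline (lowest stage value) estimating maximal lactate steady state |
| LT1 grid | 0.05 | km/h | breakpoint candidate spacing; speeds reported to 0.01 km/h |
| age-predicted HRmax | 220 − age | bpm | conventional formula; configurable, as only the 95% criterion itself is fixed |
| CV folds | 10 | — | tenfold cross-validation, seeded; fold sizes differ by at most one |

## What the synthetic generator emulates — and what it does not

`make_cohort()` draws a latent fitness score $z \sim N(0,1)$ per
athlete. The six fitness variables are affine in $z$ with Gaussian noise
scaled so PC1 of the standardised panel captures a configurable share
(default 0.89); the means and spreads describe recreationally active
adults (VO2max 48 ± 8 mL/kg/min, threshold speeds around 10-13 km/h).
Coefficients are log-linear in $z$ with negative fitness slopes — lower
fitness gives a steeper weighting curve, which is the construct the
validation machinery is meant to detect — plus athlete-level log-normal
noise. `effect_size` scales the coupling; 0 severs it, giving the null
cohort against which the regression machinery is checked for
false-positive signal.

`simulate_ramp_rr()` synthesises the ramp recording: 300 s seated rest,
then a 720-s ramp during which $\Delta HR$ rises linearly to 0.97 with
first-order onset kinetics ($\tau$ = 30 s — heart rate does not step at
exercise onset, and a step would put a spurious trend into every DFA
window spanning it). The target exponent trajectory is the athlete's
inverted weighting curve, and the RR series is built block-wise (64
beats, 50% overlap, power-complementary sine-window cross-fade) from
spectrally synthesised $1/f^\beta$ noise with $\beta = 2\alpha^*(t)-1$;
mean RR tracks $60000/HR(t)$ and the variability amplitude shrinks from
~48 ms at rest to a few ms near maximum. There is no canonical generator
for time-varying fractal processes; the cross-faded block construction
is judged by whether the analysis chain recovers known exponents, which
is exactly what the recovery tests measure.

What it does *not* emulate: respiratory sinus arrhythmia and its
frequency structure, ectopic-beat morphology, thermoregulatory drift,
cadence lock-in, or day-to-day biological variation. Passing recovery
tests therefore shows the chain is correct for signals with the assumed
fractal structure — not that field recordings are that clean.

Step tests are generated directly from the lactate exponential with
truncated Gaussian noise (floor 0.3 mmol/L, a physiological minimum)
and stages appended until the termination rule (BLa strictly above
4 mmol/L *and* RPE ≥ 18, each possibly reached at a different stage) is
satisfied. One consequence is worth stating plainly: a pure exponential
has no baseline plateau, so the log-log first-lactate-threshold method —
which locates the end of a shallow baseline segment — is poorly
identified on such profiles. `lt1_loglog()` flags this (`uncertain`
attribute) when the below-breakpoint log-log slope is at least half the
above-breakpoint slope or the RSS basin is wide; the LT1-before-LT2
ordering property is accordingly tested on flat-baseline-then-rise
profiles, the shape real step tests produce and the log-log method
presumes.

## Numerical choices

* **DFA**: profile integration of mean-centred intervals; per-box
  least-squares line removal, boxes taken forward *and* backward so all
  beats are used; natural log; equally weighted scales in the slope
  regression. Estimates at scales 4-16 carry the well-known small-box
  upward bias for weakly correlated signals (white noise reads ≈ 0.58,
  not 0.50); this is a property of the standard estimator, shared by the
  tooling this field uses, and the recovery tolerances account for it.
* **Window detrending**: before DFA, each 120-s window's intervals have
  a cubic polynomial trend removed. During a ramp the mean RR falls
  steadily; left in place, that deterministic drift masquerades as
  long-range correlation and inflates the exponent. This mirrors the
  slow-trend (smoothness-priors style) removal customary before
  short-scale DFA in exercise settings.
* **Anchors**: estimated from the 3-row-median-smoothed valid trace —
  the highest smoothed value in the rest segment and the lowest anywhere
  in the test — so a single noisy window cannot define an anchor. Raw
  extremes are available (`smooth = FALSE`). A flat trace (anchors
  coinciding) is an error: no profile can be built from it.
* **Estimand note**: the anchors, and hence $q_i$, are defined on the
  *windowed* trace. A 120-s window can only average over the final
  stretch of a ramp, so the observed minimum sits above the
  instantaneous physiological floor, and for athletes whose exponent
  never plateaus within the test the normalisation compresses the fitted
  $q_i$ towards $\ln(1/p)/\Delta HR_{end}$. This is a property of the
  method itself, not an implementation artifact; recovery tests compare
  against generating values and absorb it within their stated
  tolerances.
* **Fits**: `nlsLM` with `ftol = ptol = 1e-12`; a flat lactate response
  (log-linear slope ≈ 0) short-circuits to a flagged profile rather than
  a spurious converged fit; fitted non-positive slopes are flagged, as
  the profile invariants require $b_i, q_i > 0$.
* **Artifact correction**: monotone piecewise-cubic (PCHIP)
  interpolation over unflagged beats — shape-preserving, so no
  overshoot next to flagged runs; more than 50% flagged refuses to
  correct. Edge artifacts take the nearest accepted value.
* **LT1 breakpoint**: continuous hinge in log-log space, exhaustive
  0.05 km/h candidate scan, ties to the lower RSS then the lower speed —
  deterministic and directly checkable against a brute-force oracle.
* **PCA**: correlation-matrix PCA via `prcomp(scale. = TRUE)` (the
  variables are on different units, and the merge is defined on the
  standardised panel); PC1 sign oriented so `CRF_m` correlates
  positively with VO2max, making "higher = fitter" stable across
  platforms. Component retention is not automated — PC1 is always
  extracted and the eigen-structure returned for inspection.
* **Cross-validated R²**: out-of-sample $1 - SSE/SST$ per held-out fold
  (SST about the held-out mean), so pure-noise responses go negative
  rather than being flattered — the `cor(obs, pred)²` alternative is
  badly behaved on 3-observation folds. The second-order model uses a
  centred square to limit collinearity between the linear and quadratic
  terms. Band labels use the < 0.3 / 0.3–0.5 / 0.5–0.7 / > 0.7
  cut-points with boundaries assigned to the lower band.
* **Problem sizes**: the test suite uses 2^12–2^14-beat series with
  10–50 replicates for the DFA oracles, 500 replicates for the
  lactate-fit noise study, 20 seeds for the end-to-end ramp recovery and
  31-athlete cohorts for the construct checks — sizes at which the
  Monte-Carlo means are stable to well inside the asserted tolerances.

## Known limitations

* Ventilatory thresholds are accepted as externally supplied panel
  variables; determining them from raw gas exchange involves a partly
  visual multi-method procedure that is out of scope.
* The artifact detector is a statistical outlier rule; it does not
  classify ectopy by morphology, and vendor "automatic correction"
  pipelines may differ in detail.
* The alphaTRIMP weighting inherits every caveat of windowed DFA-alpha1:
  estimates lag intensity changes by up to a window, and the exponent's
  mapping to intensity saturates once the trace reaches its floor.
* How rest is instrumented before a ramp (duration, posture) affects
  $DFA_{rest}$; the profile functions expose `rest_end_s` but cannot
  verify the athlete actually rested.
* A trace that never attains the 0.5 threshold passes the multi-crossing
  QC but is flagged `"incomplete range"` — the exclusion rule speaks
  only to multiple crossings, and a hard exclusion here would discard
  genuinely submaximal-variance athletes; downstream users should treat
  the flag as a prompt to inspect the recording.
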