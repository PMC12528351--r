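# alphatrimp

Individualised internal-training-exposure quantification from heart rate
and heart-rate variability, for exercise physiologists and sport
scientists who profile athletes with incremental treadmill tests and
score their training sessions afterwards.

Fixed-percentage heart-rate methods assume everyone experiences the same
physiological stress at the same relative HR. They do not: the
fractional HR elevation at which lactate and ventilatory thresholds
occur varies widely between individuals. Individualised training-impulse
(TRIMP) methods therefore weight each moment of a session by a curve
fitted to the athlete's own physiological response during an incremental
test. This package implements two such weightings end to end:

* **iTRIMP** — the weighting is the athlete's blood-lactate exponential,
  fitted to a step incremental test;
* **alphaTRIMP** — the weighting is a fixed-intercept exponential fitted
  to the athlete's *normalised short-scale DFA exponent* (DFA-alpha1) of
  RR intervals during a ramp test. DFA-alpha1 falls from above 1 at rest
  towards 0.5 and below at high intensity, and needs only a chest-strap
  ECG sensor — no blood sampling.

## The model

With resting and maximal heart rate `HR_rest`, `HR_max`, the fractional
elevation of heart rate is

    dHR = (HR_exercise - HR_rest) / (HR_max - HR_rest).

The iTRIMP weighting is the fitted individual lactate curve

    BLa = a_i * exp(b_i * dHR),

where `a_i` (mmol/L) is the resting lactate concentration (dHR = 0) and
`b_i` its exponential growth rate. For alphaTRIMP the DFA-alpha1 trace
of the ramp test (2-min windows recomputed every 5 s, box scales 4-16
beats) is first normalised between the athlete's resting maximum and
exercise minimum,

    alpha_norm(t) = (DFA_rest - DFA_t) / (DFA_rest - DFA_maximal),

and a one-parameter exponential with fixed cohort intercept `p = 0.06`
is fitted (zero values excluded, as an exponential never attains 0):

    alpha_norm = p * exp(q_i * dHR).

A session score accumulates the weighted intensity over the recording,

    TRIMP = sum_t  dt * dHR_t * w(dHR_t)        ("manzi" convention)
    TRIMP = sum_t  dt * w(dHR_t)                ("literal" convention)

with `dt` in minutes and `w` the chosen weighting. The rate of change of
either weighting is proportional to itself: `dw/d(dHR) = b_i * y` and
`= q_i * w`. Construct validation merges six cardiorespiratory fitness
variables (VO2max, vVO2max, vLT1, vLT2, vVT1, vVT2) into a single PC1
score `CRF_m` and regresses coefficients (first order) and weightings at
fixed dHR (second order) on it, with tenfold cross-validated R².

Everything upstream is included: RR artifact detection/correction and
the 3% exclusion rule, sliding-window DFA-alpha1, log-log and
baseline+1.5 mmol/L lactate thresholds, VO2max attainment checks, and a
synthetic-physiology generator (fitness-coupled cohorts, step tests,
fractal-noise ramp RR recordings) so that every stage of the chain has a
ground-truth recovery test.

## Worked example

```r
library(alphatrimp)

co  <- make_cohort(5, seed = 42)          # synthetic cohort with known truth
ath <- co$athletes[1, ]

# profile the athlete from a (simulated) step incremental test
st  <- simulate_step_test(ath, seed = 7)
res <- profile_from_step(st, id = ath$id)
res$profile
#> <athlete_profile> ath01  HR 56.7168/187.429
#>   iTRIMP:     a = 0.9412, b = 1.584
c(res$v_lt1, res$v_lt2)
#> [1]  7.00 10.43

# and from a (simulated) ramp-test RR recording
sim  <- simulate_ramp_rr(ath, seed = 7)
ramp <- profile_from_ramp(sim$rr, ath$hr_rest, ath$hr_max, rest_end_s = 300)
ramp$profile
#> <athlete_profile> athlete  HR 56.7168/187.429
#>   alphaTRIMP: p = 0.06, q = 3.256
#>   DFA anchors: rest 1.539, maximal 0.900

# score a one-hour session with both methods
hr   <- hr_series(seq(0, 3599), 120 + 25 * sin(seq(0, 3599) / 300))
prof <- ramp$profile; prof$itrimp <- res$profile$itrimp
session_trimp(hr, prof, method = "itrimp")
#> <trimp_result> itrimp (manzi): 64.53 AU over 60.0 min (mean dHR 0.49)
session_trimp(hr, prof, method = "atrimp")
#> <trimp_result> atrimp (manzi): 10.54 AU over 60.0 min (mean dHR 0.49)
```

The iTRIMP weighting is an absolute lactate concentration (so its score
carries mmol/L-scaled units), while the alphaTRIMP weighting lives on
the normalised 0-1 scale; scores are comparable within a method and
convention, not across them. Fitted coefficients recover the generating
values: the lactate fit returns `a = 0.941, b = 1.584` against true
`(0.960, 1.588)`.

A command-line front end wrapping the same functions ships at
`inst/cli/alphatrimp.R` (subcommands `profile-step`, `profile-ramp`,
`score`, `simulate`, `validate`).

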