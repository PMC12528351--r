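# Shared fixtures: all built in code, no stored data.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A mid-fitness reference athlete with round-number physiology.
ref_athlete <- function() {
  list(id = "ref", z = 0, a = 1.2, b = 2.2, q = 2.9, p_i = 0.06,
       hr_rest = 60, hr_max = 190, dfa_rest = 1.35, dfa_maximal = 0.30)
}

# Well-formed step test: exponential lactate, 7 stages.
ref_step_test <- function(a = 1.2, b = 2.2, hr_rest = 60, hr_max = 190) {
  dhr <- seq(0.35, 0.95, by = 0.10)
  step_test(
    data.frame(stage = seq_along(dhr), speed = 8 + seq_along(dhr) - 1,
               hr_last30 = hr_rest + dhr * (hr_max - hr_rest),
               bla = a * exp(b * dhr),
               rpe = pmin(20, round(6 + 14 * dhr^1.5))),
    hr_rest = hr_rest, hr_max = hr_max
  )
}

# dfa_grid with a prescribed alpha1 trace (rows with NA alpha1 invalid).
grid_from_alpha <- function(alpha1, hr = NULL, step_s = 5, valid = NULL) {
  n <- length(alpha1)
  if (is.null(hr)) hr <- seq(70, 180, length.out = n)
  if (is.null(valid)) valid <- is.finite(alpha1)
  dfa_grid(time = seq(120, by = step_s, length.out = n), hr = hr,
           alpha1 = alpha1, n_beats = rep(100L, n), valid = valid,
           window_s = 120, step_s = step_s)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
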