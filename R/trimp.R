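#' Estimate DFA-alpha1 normalisation anchors from a ramp grid
#'
#' `dfa_rest` is the highest 3-row-median-smoothed valid alpha1 in the
#' pre-exercise segment (rows at or before `rest_end_s`; the whole grid
#' when unspecified), `dfa_maximal` the lowest smoothed valid alpha1
#' anywhere in the test. Median smoothing stops a single noisy window
#' from defining an anchor; set `smooth = FALSE` for raw extremes.
#'
#' @param grid a [dfa_grid()].
#' @param rest_end_s end of the resting segment in seconds, or `NULL`.
#' @param smooth apply the 3-row running median (default `TRUE`).
#' @return list with `dfa_rest` and `dfa_maximal`.
#' @export
estimate_dfa_anchors <- function(grid, rest_end_s = NULL, smooth = TRUE) {
  stopifnot(inherits(grid, "dfa_grid"))
  a <- grid$alpha1
  if (smooth && sum(grid$valid) >= 3L) {
    av <- a[grid$valid]
    a[grid$valid] <- stats::runmed(av, 3, endrule = "median")
  }
  rest_sel <- grid$valid
  if (!is.null(rest_end_s)) rest_sel <- rest_sel & grid$time <= rest_end_s
  if (!any(rest_sel)) stopf("no valid rows in the resting segment")
  dfa_rest <- max(a[rest_sel])
  dfa_maximal <- min(a[grid$valid])
  if (dfa_rest <= dfa_maximal) stopf("flat DFA trace: anchors coincide")
  list(dfa_rest = dfa_rest, dfa_maximal = dfa_maximal)
}

#' Normalise a DFA-alpha1 trace to the 0-1 exercise scale
#'
#' `alpha_norm(t) = (DFA_rest - DFA_t) / (DFA_rest - DFA_maximal)`: 0 at
#' the athlete's highest resting alpha1, 1 at the lowest alpha1 reached
#' at maximal intensity. Values outside `[0, 1]` are clipped with a
#' warning. Invalid grid rows propagate as `NA`.
#'
#' @param grid a [dfa_grid()].
#' @param anchors list with `dfa_rest` and `dfa_maximal`
#'   (`dfa_rest > dfa_maximal`); estimated via [estimate_dfa_anchors()]
#'   when `NULL`.
#' @param rest_end_s passed to the anchor estimator.
#' @return data.frame with `time`, `hr`, `alpha_norm` (`NA` where the
#'   grid row is invalid) and the anchors as attributes.
#' @export
normalise_dfa <- function(grid, anchors = NULL, rest_end_s = NULL) {
  stopifnot(inherits(grid, "dfa_grid"))
  if (is.null(anchors)) anchors <- estimate_dfa_anchors(grid, rest_end_s)
  r <- anchors$dfa_rest
  m <- anchors$dfa_maximal
  if (!is_number(r) || !is_number(m) || r == m) stopf("anchors must differ")
  if (r < m) stopf("dfa_rest must exceed dfa_maximal")
  an <- rep(NA_real_, nrow(grid))
  an[grid$valid] <- clip_warn((r - grid$alpha1[grid$valid]) / (r - m), 0, 1,
                              "alpha_norm")
  out <- data.frame(time = grid$time, hr = grid$hr, alpha_norm = an)
  attr(out, "dfa_rest") <- r
  attr(out, "dfa_maximal") <- m
  out
}

# Shared Levenberg-Marquardt driver for the exponential weighting fits.
.fit_exp_lm <- function(formula, data, start) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-12, ptol = 1e-12, maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    e <- simpleError(sprintf("exponential fit did not converge: %s",
                             conditionMessage(fit)))
    e$fallback <- start
    stop(e)
  }
  fit
}

#' Fit the individual blood-lactate exponential
#'
#' Nonlinear least squares of `BLa = a * exp(b * dHR)`, the individual
#' lactate response whose interpolated values are the iTRIMP weighting
#' factors. `a` is the resting BLa concentration (dHR = 0), `b` the rate
#' of BLa growth with fractional HR elevation. Initialised from the
#' log-linear regression of `log(BLa)` on dHR; refined by
#' Levenberg-Marquardt to an RSS tolerance of 1e-12.
#'
#' @param dhr fractional HR elevation per stage, in `[0, 1]`.
#' @param bla blood lactate per stage, mmol/L, all > 0.
#' @return list with `a`, `b`, `rss`, `n` and `flagged` (`TRUE` when the
#'   fitted slope is not positive, e.g. flat lactate).
#' @export
fit_bla_exponential <- function(dhr, bla) {
  if (length(dhr) != length(bla)) stopf("dhr and bla differ in length")
  if (length(dhr) < 4L) stopf("need >= 4 points")
  if (any(bla <= 0)) stopf("BLa must be > 0")
  init <- stats::coef(stats::lm(log(bla) ~ dhr))
  start <- list(a = exp(unname(init[1L])), b = unname(init[2L]))
  if (abs(start$b) < 1e-8) {
    # flat response: degenerate slope, report without NLS refinement
    return(list(a = mean(bla), b = start$b, rss = sum((bla - mean(bla))^2),
                n = length(bla), flagged = TRUE))
  }
  fit <- .fit_exp_lm(bla ~ a * exp(b * dhr), data.frame(dhr = dhr, bla = bla),
                     start)
  cf <- stats::coef(fit)
  list(a = unname(cf["a"]), b = unname(cf["b"]),
       rss = sum(stats::resid(fit)^2), n = length(bla),
       flagged = unname(cf["b"]) <= 0)
}

#' Fit the fixed-intercept normalised-DFA exponential
#'
#' One-parameter nonlinear least squares of
#' `alpha_norm = p * exp(q * dHR)` with the intercept `p` held fixed
#' (cohort constant, default 0.06). Zero alpha_norm values are dropped
#' before fitting, since the exponential never attains 0. Initial `q`
#' from the through-origin regression of `log(alpha_norm / p)` on dHR.
#'
#' @param dhr fractional HR elevation per grid row.
#' @param alpha_norm normalised DFA-alpha1 per row (`NA` rows dropped).
#' @param p fixed intercept, default 0.06.
#' @param min_points minimum usable points after dropping zeros, default
#'   10.
#' @return list with `p`, `q`, `rss`, `n` (points used) and `flagged`
#'   (`TRUE` when fitted `q <= 0`).
#' @export
fit_alpha_exponential <- function(dhr, alpha_norm, p = 0.06, min_points = 10L) {
  if (length(dhr) != length(alpha_norm)) stopf("dhr and alpha_norm differ in length")
  keep <- is.finite(dhr) & is.finite(alpha_norm)
  dhr <- dhr[keep]
  alpha_norm <- alpha_norm[keep]
  nz <- alpha_norm > 0
  if (!any(nz)) stopf("all alpha_norm values are zero")
  dhr <- dhr[nz]
  alpha_norm <- alpha_norm[nz]
  if (length(dhr) < min_points) stopf("need >= %d nonzero points", min_points)
  q0 <- sum(dhr * log(alpha_norm / p)) / sum(dhr * dhr)
  fit <- .fit_exp_lm(alpha_norm ~ p * exp(q * dhr),
                     data.frame(dhr = dhr, alpha_norm = alpha_norm),
                     list(q = q0))
  q <- unname(stats::coef(fit)["q"])
  list(p = p, q = q, rss = sum(stats::resid(fit)^2), n = length(dhr),
       flagged = q <= 0)
}

#' Free two-parameter normalised-DFA exponential fit
#'
#' Fits `alpha_norm = p_i * exp(q_i * dHR)` with both coefficients free,
#' used to derive each athlete's own intercept `p_i` before it is
#' standardised across the cohort.
#'
#' @inheritParams fit_alpha_exponential
#' @return list with `p`, `q`, `rss`, `n`.
#' @export
fit_alpha_exponential_free <- function(dhr, alpha_norm, min_points = 10L) {
  if (length(dhr) != length(alpha_norm)) stopf("dhr and alpha_norm differ in length")
  keep <- is.finite(dhr) & is.finite(alpha_norm) & alpha_norm > 0
  dhr <- dhr[keep]
  alpha_norm <- alpha_norm[keep]
  if (length(dhr) < min_points) stopf("need >= %d nonzero points", min_points)
  init <- stats::coef(stats::lm(log(alpha_norm) ~ dhr))
  fit <- .fit_exp_lm(alpha_norm ~ p * exp(q * dhr),
                     data.frame(dhr = dhr, alpha_norm = alpha_norm),
                     list(p = exp(unname(init[1L])), q = unname(init[2L])))
  cf <- stats::coef(fit)
  list(p = unname(cf["p"]), q = unname(cf["q"]),
       rss = sum(stats::resid(fit)^2), n = length(dhr))
}

#' Standardise the DFA-exponential intercept across a cohort
#'
#' The cohort constant `p` is the arithmetic mean of the individually
#' fitted intercepts `p_i` (the normalised scale is bounded, so the
#' between-athlete intercept is fixed and individuality carried by `q_i`
#' alone).
#'
#' @param p_values numeric vector of per-athlete intercepts `p_i`.
#' @return the cohort constant `p`.
#' @export
standardise_intercept <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0L || anyNA(p_values)) stopf("need per-athlete p values")
  mean(p_values)
}

#' Individualised weighting factor at a given intensity
#'
#' `a_i * exp(b_i * dHR)` (iTRIMP: interpolated BLa, mmol/L) or
#' `p * exp(q_i * dHR)` (alphaTRIMP: interpolated alpha_norm).
#'
#' @param profile an [athlete_profile()] with the relevant fit.
#' @param dhr fractional HR elevation, in `[0, 1]`.
#' @param method `"itrimp"` or `"atrimp"`.
#' @return weighting factor(s), same length as `dhr`.
#' @export
weighting <- function(profile, dhr, method = c("itrimp", "atrimp")) {
  stopifnot(inherits(profile, "athlete_profile"))
  method <- match.arg(method)
  if (method == "itrimp") {
    if (is.null(profile$itrimp)) stopf("profile has no iTRIMP coefficients")
    profile$itrimp$a * exp(profile$itrimp$b * dhr)
  } else {
    if (is.null(profile$atrimp)) stopf("profile has no alphaTRIMP coefficients")
    profile$atrimp$p * exp(profile$atrimp$q * dhr)
  }
}

#' Rate of change of the weighting factor with intensity
#'
#' The derivative of the exponential weighting with respect to dHR:
#' `b_i * y(dHR)` for iTRIMP, `q_i * w(dHR)` for alphaTRIMP — the slope
#' is always the slope coefficient times the weighting itself.
#'
#' @inheritParams weighting
#' @return derivative of the weighting at `dhr`.
#' @export
weighting_slope <- function(profile, dhr, method = c("itrimp", "atrimp")) {
  method <- match.arg(method)
  slope_coef <- if (method == "itrimp") profile$itrimp$b else profile$atrimp$q
  if (is.null(slope_coef)) stopf("profile has no %s coefficients", method)
  slope_coef * weighting(profile, dhr, method)
}

#' Session training impulse from a heart-rate recording
#'
#' Accumulates the weighted intensity over a session. Two conventions for
#' the pseudo-integral over the dHR samples are exposed:
#'
#' * `"manzi"` (default): `sum(dt_min * dHR_t * weight(dHR_t))` — the
#'   established individualised-TRIMP accumulation (duration x fractional
#'   elevation x weighting);
#' * `"literal"`: `sum(dt_min * weight(dHR_t))` — the weighting alone
#'   integrated over time.
#'
#' Missing HR samples contribute 0 and are counted in `n_missing`.
#'
#' @param hr an [hr_series()] of the session (uniform grid).
#' @param profile an [athlete_profile()] with the relevant coefficients.
#' @param method `"itrimp"` or `"atrimp"`.
#' @param convention `"manzi"` or `"literal"`.
#' @return a [trimp_result()].
#' @export
session_trimp <- function(hr, profile, method = c("itrimp", "atrimp"),
                          convention = c("manzi", "literal")) {
  stopifnot(inherits(hr, "hr_series"), inherits(profile, "athlete_profile"))
  method <- match.arg(method)
  convention <- match.arg(convention)
  if (method == "itrimp" && is.null(profile$itrimp)) {
    stopf("profile has no iTRIMP coefficients")
  }
  if (method == "atrimp" && is.null(profile$atrimp)) {
    stopf("profile has no alphaTRIMP coefficients")
  }
  dt_min <- hr$sample_interval / 60
  present <- !is.na(hr$hr)
  if (!any(present)) stopf("empty HR series")
  dhr <- rep(NA_real_, length(hr$hr))
  dhr[present] <- delta_hr(hr$hr[present], profile$hr_rest, profile$hr_max)
  w <- weighting(profile, dhr[present], method)
  contrib <- numeric(length(hr$hr))
  contrib[present] <- if (convention == "manzi") {
    dt_min * dhr[present] * w
  } else {
    dt_min * w
  }
  trimp_result(method, convention, contrib,
               duration_min = length(hr$hr) * dt_min,
               mean_delta_hr = mean(dhr[present]),
               n_missing = sum(!present))
}

#' Multi-crossing QC of the DFA-alpha1 versus HR trace
#'
#' Recordings whose alpha1 trace attains the 0.75 and 0.5 intensity
#' thresholds multiple times within one continuous incremental test are
#' excluded from weighting generation (a monotone-intensity test should
#' cross each once). Counts downward crossings of each threshold on the
#' 3-row-median-smoothed valid trace; fails when either count exceeds 1.
#' A trace that never reaches 0.5 passes but is flagged as covering an
#' incomplete intensity range.
#'
#' @param grid a [dfa_grid()].
#' @param thresholds the two alpha1 thresholds, default `c(0.75, 0.5)`.
#' @return list with `pass`, per-threshold downward-crossing `counts`,
#'   and `note` (`"incomplete range"` when 0.5 is never attained).
#' @export
qc_multi_crossing <- function(grid, thresholds = c(0.75, 0.5)) {
  stopifnot(inherits(grid, "dfa_grid"))
  a <- grid$alpha1[grid$valid]
  if (length(a) < 3L) stopf("too few valid rows for QC")
  s <- stats::runmed(a, 3, endrule = "median")
  counts <- vapply(thresholds, function(th) {
    sum(s[-length(s)] >= th & s[-1L] < th)
  }, numeric(1))
  names(counts) <- paste0("th", thresholds)
  note <- if (min(s) > min(thresholds)) "incomplete range" else NA_character_
  list(pass = all(counts <= 1), counts = counts, note = note)
}
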