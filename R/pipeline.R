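#' Build an athlete profile from a step incremental test
#'
#' Computes the fractional HR elevation of each stage from the last-30-s
#' stage HR, fits the individual lactate exponential, and determines
#' both lactate thresholds.
#'
#' @param test a [step_test()].
#' @param id athlete identifier.
#' @return list with `profile` (an [athlete_profile()] carrying the
#'   iTRIMP coefficients), `v_lt1`, `v_lt2` (km/h) and `fit` (the raw
#'   fit diagnostics).
#' @export
profile_from_step <- function(test, id = "athlete") {
  stopifnot(inherits(test, "step_test"))
  hr_rest <- attr(test, "hr_rest")
  hr_max <- attr(test, "hr_max")
  dhr <- delta_hr(test$hr_last30, hr_rest, hr_max)
  fit <- fit_bla_exponential(dhr, test$bla)
  if (isTRUE(fit$flagged)) stopf("degenerate lactate response: fitted b <= 0")
  prof <- athlete_profile(id = id, hr_rest = hr_rest, hr_max = hr_max,
                          itrimp = list(a = fit$a, b = fit$b,
                                        rss = fit$rss, n = fit$n))
  v_lt1 <- tryCatch(as.numeric(lt1_loglog(test)), error = function(e) NA_real_)
  v_lt2 <- tryCatch(lt2_baseline_delta(test), error = function(e) NA_real_)
  list(profile = prof, v_lt1 = v_lt1, v_lt2 = v_lt2, fit = fit)
}

#' Build an athlete profile from a ramp-test RR recording
#'
#' The full alphaTRIMP chain: artifact detection and correction,
#' recording-level artifact exclusion, sliding-window DFA-alpha1,
#' multi-crossing QC, anchor estimation, normalisation, and the
#' fixed-intercept exponential fit of alpha_norm against the fractional
#' HR elevation of each window.
#'
#' @param rr a raw [rr_series()].
#' @param hr_rest,hr_max the athlete's resting and maximal HR, bpm.
#' @param id athlete identifier.
#' @param rest_end_s end of the pre-exercise rest segment, seconds
#'   (anchors the DFA_rest estimate).
#' @param p fixed weighting intercept, default 0.06.
#' @param window_s,step_s DFA window and step, seconds.
#' @param max_artifact_fraction recording-level exclusion bound, default
#'   0.03.
#' @return list with `profile`, `grid` (the [dfa_grid()]), `qc`
#'   (multi-crossing result), `artifact_fraction`, `exclusion`
#'   (`"include"`/`"exclude"`) and `fit`. An excluded recording still
#'   returns its QC numbers but `profile` is `NULL`.
#' @export
profile_from_ramp <- function(rr, hr_rest, hr_max, id = "athlete",
                              rest_end_s = NULL, p = 0.06,
                              window_s = 120, step_s = 5,
                              max_artifact_fraction = 0.03) {
  stopifnot(inherits(rr, "rr_series"))
  rr <- detect_artifacts(rr)
  frac <- artifact_fraction(rr)
  excl <- exclusion_check(frac, max_artifact_fraction)
  if (excl == "exclude") {
    return(list(profile = NULL, grid = NULL, qc = NULL,
                artifact_fraction = frac, exclusion = excl, fit = NULL))
  }
  rr <- correct_artifacts(rr)
  grid <- windowed_dfa(rr, window_s = window_s, step_s = step_s)
  qc <- qc_multi_crossing(grid)
  an <- normalise_dfa(grid, rest_end_s = rest_end_s)
  dhr <- delta_hr(an$hr, hr_rest, hr_max)
  fit <- fit_alpha_exponential(dhr, an$alpha_norm, p = p)
  prof <- athlete_profile(id = id, hr_rest = hr_rest, hr_max = hr_max,
                          atrimp = list(p = fit$p, q = fit$q,
                                        rss = fit$rss, n = fit$n),
                          dfa_rest = attr(an, "dfa_rest"),
                          dfa_maximal = attr(an, "dfa_maximal"))
  list(profile = prof, grid = grid, qc = qc, artifact_fraction = frac,
       exclusion = excl, fit = fit)
}
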