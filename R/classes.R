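#' Beat-to-beat RR interval series
#'
#' Container for a chest-strap RR recording: one interval per beat in
#' milliseconds, cumulative beat times in seconds from recording start, a
#' per-beat artifact flag, and a marker recording whether artifact
#' correction has been applied.
#'
#' @param intervals numeric vector of RR intervals in milliseconds, all > 0.
#' @param beat_times optional numeric vector of beat times in seconds; when
#'   omitted it is the cumulative sum of `intervals` / 1000.
#' @param artifact_flags logical vector, one flag per beat; default all
#'   `FALSE`.
#' @param corrected logical scalar; `TRUE` once [correct_artifacts()] has
#'   replaced flagged beats.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(intervals, beat_times = NULL,
                      artifact_flags = NULL, corrected = FALSE) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stopf("no intervals")
  if (anyNA(intervals) || any(intervals <= 0)) {
    stopf("RR intervals must all be positive and non-missing")
  }
  if (is.null(beat_times)) beat_times <- cumsum(intervals) / 1000
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) != length(intervals)) {
    stopf("beat_times and intervals differ in length")
  }
  if (any(diff(beat_times) <= 0)) stopf("beat_times must be strictly increasing")
  if (is.null(artifact_flags)) artifact_flags <- rep(FALSE, length(intervals))
  artifact_flags <- as.logical(artifact_flags)
  if (length(artifact_flags) != length(intervals)) {
    stopf("artifact_flags and intervals differ in length")
  }
  structure(
    list(beat_times = beat_times, intervals = intervals,
         artifact_flags = artifact_flags, corrected = isTRUE(corrected)),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, %.1f s, %.2f%% flagged%s\n",
              length(x$intervals), max(x$beat_times) - x$beat_times[1L] +
                x$intervals[1L] / 1000,
              100 * mean(x$artifact_flags),
              if (x$corrected) ", corrected" else ""))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Uniformly sampled heart-rate series
#'
#' @param times numeric vector, seconds from recording start (uniform grid).
#' @param hr numeric vector, beats per minute; `NA` marks dropped samples.
#' @param sample_interval grid spacing in seconds; inferred from `times`
#'   when omitted.
#' @return An object of class `hr_series`.
#' @export
hr_series <- function(times, hr, sample_interval = NULL) {
  times <- as.numeric(times)
  hr <- as.numeric(hr)
  if (length(times) != length(hr)) stopf("times and hr differ in length")
  if (length(times) == 0L) stopf("empty HR series")
  if (is.null(sample_interval)) {
    sample_interval <- if (length(times) > 1L) stats::median(diff(times)) else 1
  }
  if (length(times) > 1L &&
      any(abs(diff(times) - sample_interval) > sample_interval + 1e-9)) {
    stopf("times not uniform to within one sample_interval")
  }
  bad <- !is.na(hr) & (hr <= 20 | hr >= 250)
  if (any(bad)) stopf("%d HR value(s) outside physiological range (20, 250)", sum(bad))
  structure(list(times = times, hr = hr, sample_interval = sample_interval),
            class = "hr_series")
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> %d samples @ %.3g s, HR %.0f-%.0f bpm\n",
              length(x$times), x$sample_interval,
              min(x$hr, na.rm = TRUE), max(x$hr, na.rm = TRUE)))
  invisible(x)
}

#' Step incremental test record
#'
#' Per-stage speed, last-30-s heart rate, blood lactate and RPE from a step
#' incremental treadmill test, plus the resting/maximal HR needed for
#' fractional HR elevation. The lactate baseline is the lowest measurement
#' across all stages.
#'
#' @param stages data.frame with columns `stage`, `speed` (km/h, strictly
#'   increasing by a constant increment), `hr_last30` (bpm), `bla`
#'   (mmol/L, >= 0), `rpe` (Borg 6-20).
#' @param hr_rest,hr_max resting and maximal heart rate in bpm.
#' @return An object of class `step_test` (a data.frame with attributes
#'   `hr_rest`, `hr_max`, `bla_baseline`).
#' @export
step_test <- function(stages, hr_rest, hr_max) {
  need <- c("stage", "speed", "hr_last30", "bla", "rpe")
  if (!all(need %in% names(stages))) {
    stopf("stages must have columns: %s", paste(need, collapse = ", "))
  }
  stages <- as.data.frame(stages)[need]
  if (nrow(stages) == 0L) stopf("no stages")
  if (any(diff(stages$speed) <= 0)) stopf("speeds not increasing")
  if (nrow(stages) > 2L) {
    incr <- diff(stages$speed)
    if (any(abs(incr - incr[1L]) > 1e-6)) {
      stopf("speed increments not constant")
    }
  }
  if (any(stages$bla < 0)) stopf("BLa must be >= 0")
  if (any(stages$rpe < 6 | stages$rpe > 20)) stopf("RPE outside Borg 6-20 scale")
  if (!is_number(hr_rest) || !is_number(hr_max)) stopf("missing hr_rest/hr_max")
  if (!(hr_max > hr_rest && hr_rest > 0)) stopf("need hr_max > hr_rest > 0")
  structure(stages, class = c("step_test", "data.frame"),
            hr_rest = as.numeric(hr_rest), hr_max = as.numeric(hr_max),
            bla_baseline = min(stages$bla))
}

#' @export
print.step_test <- function(x, ...) {
  cat(sprintf("<step_test> %d stages, %.1f-%.1f km/h, HR rest/max %g/%g, BLa baseline %.2f\n",
              nrow(x), min(x$speed), max(x$speed),
              attr(x, "hr_rest"), attr(x, "hr_max"), attr(x, "bla_baseline")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Gas-exchange summary of a ramp test
#'
#' 30-s time-averaged metabolic cart output used for VO2max attainment.
#'
#' @param time numeric, seconds on a 30-s grid.
#' @param vo2 oxygen uptake, L/min, > 0.
#' @param rer respiratory exchange ratio.
#' @param hr heart rate, bpm.
#' @param age athlete age in years (for age-predicted HRmax).
#' @param speed optional treadmill speed per row (km/h); derived from the
#'   ramp protocol (4 km/h + 0.5 per 30 s) when omitted.
#' @return An object of class `ramp_gas`.
#' @export
ramp_gas <- function(time, vo2, rer, hr, age, speed = NULL) {
  n <- length(time)
  if (n == 0L) stopf("empty gas-exchange record")
  if (length(vo2) != n || length(rer) != n || length(hr) != n) {
    stopf("time, vo2, rer, hr differ in length")
  }
  if (n > 1L && any(abs(diff(time) - 30) > 1e-6)) stopf("grid spacing must be 30 s")
  if (any(vo2 <= 0)) stopf("vo2 must be > 0")
  if (!is_number(age) || age <= 0) stopf("age required")
  if (is.null(speed)) speed <- 4 + 0.5 * floor(time / 30)
  structure(data.frame(time = time, vo2 = vo2, rer = rer, hr = hr, speed = speed),
            class = c("ramp_gas", "data.frame"), age = as.numeric(age))
}

#' 5-s grid of heart rate and DFA-alpha1
#'
#' Product of [windowed_dfa()]: one row per 5-s step with the window-mean
#' heart rate, the short-scale DFA exponent, the number of beats in the
#' window and a validity flag.
#'
#' @param time grid times in seconds (constant spacing).
#' @param hr window-mean heart rate, bpm.
#' @param alpha1 DFA-alpha1 estimate; `NA` where invalid.
#' @param n_beats beats in the trailing window.
#' @param valid logical; `FALSE` when the window held fewer than the
#'   minimum beat count.
#' @param window_s,step_s window length and recompute step in seconds.
#' @return An object of class `dfa_grid`.
#' @export
dfa_grid <- function(time, hr, alpha1, n_beats, valid,
                     window_s = 120, step_s = 5) {
  n <- length(time)
  if (!all(lengths(list(hr, alpha1, n_beats, valid)) == n)) {
    stopf("dfa_grid columns differ in length")
  }
  if (n > 1L) {
    sp <- diff(time)
    if (any(abs(sp - sp[1L]) > 1e-9)) stopf("grid spacing not constant")
  }
  if (any(valid & !is.finite(alpha1))) stopf("alpha1 must be finite where valid")
  structure(data.frame(time = time, hr = hr, alpha1 = alpha1,
                       n_beats = n_beats, valid = valid),
            class = c("dfa_grid", "data.frame"),
            window_s = window_s, step_s = step_s)
}

#' @export
print.dfa_grid <- function(x, ...) {
  cat(sprintf("<dfa_grid> %d rows (%d valid), window %gs / step %gs\n",
              nrow(x), sum(x$valid), attr(x, "window_s"), attr(x, "step_s")))
  invisible(x)
}

#' Athlete profile of individualised TRIMP coefficients
#'
#' Everything needed to score a future session for one athlete: the HR
#' anchors for fractional elevation, the lactate exponential coefficients
#' (a_i, b_i) for iTRIMP, the fixed-intercept DFA exponential (p, q_i) for
#' alphaTRIMP, and the DFA-alpha1 normalisation anchors.
#'
#' @param id athlete identifier (character).
#' @param hr_rest,hr_max resting/maximal HR, bpm.
#' @param itrimp `NULL` or list with `a`, `b` (> 0) and optionally `rss`,
#'   `n` fit diagnostics.
#' @param atrimp `NULL` or list with `p` (in (0,1), default 0.06), `q`
#'   (> 0) and optionally `rss`, `n`.
#' @param dfa_rest,dfa_maximal DFA-alpha1 normalisation anchors
#'   (`dfa_rest > dfa_maximal`); may be `NA` when only iTRIMP is used.
#' @return An object of class `athlete_profile`.
#' @export
athlete_profile <- function(id = "athlete", hr_rest, hr_max,
                            itrimp = NULL, atrimp = NULL,
                            dfa_rest = NA_real_, dfa_maximal = NA_real_) {
  if (!(is_number(hr_rest) && is_number(hr_max) && hr_max > hr_rest && hr_rest > 0)) {
    stopf("need hr_max > hr_rest > 0")
  }
  if (!is.null(itrimp)) {
    if (!is_number(itrimp$a) || itrimp$a <= 0) stopf("iTRIMP coefficient a must be > 0")
    if (!is_number(itrimp$b) || itrimp$b <= 0) stopf("iTRIMP coefficient b must be > 0")
  }
  if (!is.null(atrimp)) {
    if (!is_number(atrimp$p) || atrimp$p <= 0 || atrimp$p >= 1) {
      stopf("alphaTRIMP intercept p must be in (0, 1)")
    }
    if (!is_number(atrimp$q) || atrimp$q <= 0) stopf("alphaTRIMP coefficient q must be > 0")
  }
  if (is.finite(dfa_rest) && is.finite(dfa_maximal) && dfa_rest <= dfa_maximal) {
    stopf("dfa_rest must exceed dfa_maximal")
  }
  structure(list(id = as.character(id), hr_rest = as.numeric(hr_rest),
                 hr_max = as.numeric(hr_max), itrimp = itrimp, atrimp = atrimp,
                 dfa_rest = as.numeric(dfa_rest),
                 dfa_maximal = as.numeric(dfa_maximal)),
            class = "athlete_profile")
}

#' @export
print.athlete_profile <- function(x, ...) {
  cat(sprintf("<athlete_profile> %s  HR %g/%g\n", x$id, x$hr_rest, x$hr_max))
  if (!is.null(x$itrimp)) {
    cat(sprintf("  iTRIMP:     a = %.4g, b = %.4g\n", x$itrimp$a, x$itrimp$b))
  }
  if (!is.null(x$atrimp)) {
    cat(sprintf("  alphaTRIMP: p = %.4g, q = %.4g\n", x$atrimp$p, x$atrimp$q))
  }
  if (is.finite(x$dfa_rest)) {
    cat(sprintf("  DFA anchors: rest %.3f, maximal %.3f\n",
                x$dfa_rest, x$dfa_maximal))
  }
  invisible(x)
}

#' Session TRIMP score
#'
#' @param method `"itrimp"` or `"atrimp"`.
#' @param convention `"manzi"` (duration x dHR x weighting) or `"literal"`
#'   (duration x weighting).
#' @param contributions per-sample score contributions (already in minutes
#'   x weighting units); missing samples contribute 0.
#' @param duration_min session duration in minutes.
#' @param mean_delta_hr mean fractional HR elevation over present samples.
#' @param n_missing number of missing HR samples.
#' @return An object of class `trimp_result`; `total` is the sum of
#'   contributions.
#' @export
trimp_result <- function(method, convention, contributions, duration_min,
                         mean_delta_hr, n_missing = 0L) {
  method <- match.arg(method, c("itrimp", "atrimp"))
  convention <- match.arg(convention, c("manzi", "literal"))
  total <- sum(contributions)
  if (total < 0) stopf("TRIMP total must be non-negative")
  structure(list(method = method, convention = convention, total = total,
                 contributions = contributions,
                 duration_min = duration_min, mean_delta_hr = mean_delta_hr,
                 n_missing = as.integer(n_missing)),
            class = "trimp_result")
}

#' @export
print.trimp_result <- function(x, ...) {
  cat(sprintf("<trimp_result> %s (%s): %.2f AU over %.1f min (mean dHR %.2f)\n",
              x$method, x$convention, x$total, x$duration_min, x$mean_delta_hr))
  invisible(x)
}

#' Cohort panel of cardiorespiratory fitness variables
#'
#' Six fitness variables per athlete: VO2max (mL/kg/min) and the speeds
#' (km/h) at VO2max, at the two lactate thresholds and at the two
#' ventilatory thresholds.
#'
#' @param df data.frame with columns `id`, `vo2max`, `v_vo2max`, `v_lt1`,
#'   `v_lt2`, `v_vt1`, `v_vt2`.
#' @return An object of class `crf_panel`.
#' @export
crf_panel <- function(df) {
  need <- c("id", "vo2max", "v_vo2max", "v_lt1", "v_lt2", "v_vt1", "v_vt2")
  if (!all(need %in% names(df))) {
    stopf("crf_panel needs columns: %s", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  num <- df[-1L]
  if (any(!is.finite(as.matrix(num)))) stopf("CRF panel has missing values")
  if (any(as.matrix(num) <= 0)) stopf("CRF variables must be > 0")
  bad <- df$v_lt1 >= df$v_lt2
  if (any(bad)) stopf("v_lt1 must be below v_lt2 (%d row(s) violate)", sum(bad))
  structure(df, class = c("crf_panel", "data.frame"))
}

#' Matrix of the six CRF variables from a panel
#' @param panel a [crf_panel()].
#' @return numeric matrix, athletes x 6 variables.
#' @export
crf_matrix <- function(panel) {
  m <- as.matrix(as.data.frame(panel)[-1L])
  rownames(m) <- panel$id
  m
}
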