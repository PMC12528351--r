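#' Flag RR artifacts by deviation from a running median
#'
#' A beat is flagged when its interval deviates from the median of its
#' nearest `window_beats` unflagged neighbours by more than
#' `rel_threshold` (relative to that median). Beats are visited in order;
#' already-flagged beats are excluded from later neighbourhoods, so a
#' missed-beat spike does not drag the local median. Intervals are left
#' untouched; only the flags change.
#'
#' @param rr an [rr_series()].
#' @param rel_threshold relative deviation above which a beat is flagged;
#'   default 0.20 (20%), standard practice for chest-strap HRV cleaning.
#' @param window_beats neighbourhood size for the running median (default
#'   11 beats).
#' @return The series with updated `artifact_flags`.
#' @export
detect_artifacts <- function(rr, rel_threshold = 0.20, window_beats = 11L) {
  stopifnot(inherits(rr, "rr_series"))
  n <- length(rr$intervals)
  if (n < window_beats) stopf("series shorter than the %d-beat window", window_beats)
  x <- rr$intervals
  flags <- rep(FALSE, n)
  for (i in seq_len(n)) {
    # nearest unflagged neighbours by index distance, excluding beat i
    ord <- order(abs(seq_len(n) - i))
    cand <- ord[ord != i & !flags[ord]]
    nb <- cand[seq_len(min(window_beats, length(cand)))]
    if (length(nb) == 0L) next
    m <- stats::median(x[nb])
    if (abs(x[i] - m) > rel_threshold * m) flags[i] <- TRUE
  }
  rr$artifact_flags <- flags
  rr
}

#' Replace flagged RR intervals by shape-preserving cubic interpolation
#'
#' Flagged intervals are replaced by monotone piecewise-cubic (PCHIP)
#' interpolation of interval versus beat index over the unflagged beats;
#' beat times are recomputed from the corrected intervals. Refuses to
#' correct when more than `max_fraction` of beats are flagged.
#'
#' @param rr an [rr_series()] with flags computed.
#' @param max_fraction largest correctable flagged fraction (default 0.5).
#' @return Corrected series (`corrected = TRUE`); identical to the input
#'   when nothing is flagged.
#' @export
correct_artifacts <- function(rr, max_fraction = 0.5) {
  stopifnot(inherits(rr, "rr_series"))
  frac <- mean(rr$artifact_flags)
  if (frac > max_fraction) {
    stopf("%.0f%% of beats flagged exceeds correctable maximum (%.0f%%)",
          100 * frac, 100 * max_fraction)
  }
  if (!any(rr$artifact_flags)) {
    rr$corrected <- TRUE
    return(rr)
  }
  idx <- seq_along(rr$intervals)
  good <- !rr$artifact_flags
  if (sum(good) < 2L) stopf("too few unflagged beats to interpolate")
  y <- rr$intervals
  bad_i <- idx[!good]
  # pchip needs query points inside the support; extrapolate edges flat
  lo <- min(idx[good]); hi <- max(idx[good])
  inner <- bad_i[bad_i > lo & bad_i < hi]
  if (length(inner) > 0L) {
    y[inner] <- pracma::pchip(idx[good], rr$intervals[good], inner)
  }
  y[bad_i[bad_i <= lo]] <- rr$intervals[good][1L]
  y[bad_i[bad_i >= hi]] <- rr$intervals[good][sum(good)]
  rr_series(y, artifact_flags = rr$artifact_flags, corrected = TRUE)
}

#' Fraction of beats flagged as artifacts
#'
#' Exact integer ratio flagged / total.
#'
#' @param rr an [rr_series()].
#' @return fraction in `[0, 1]`.
#' @export
artifact_fraction <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  sum(rr$artifact_flags) / length(rr$artifact_flags)
}

#' Recording-level artifact exclusion rule
#'
#' Recordings whose artifact percentage exceeds the cutoff (default 3%)
#' are excluded from weighting-factor generation; the boundary itself is
#' included ("exceeded" is strict).
#'
#' @param fraction artifact fraction in `[0, 1]`.
#' @param max_fraction exclusion cutoff, default 0.03.
#' @return `"include"` or `"exclude"`.
#' @export
exclusion_check <- function(fraction, max_fraction = 0.03) {
  stopifnot(is_number(fraction), fraction >= 0, fraction <= 1)
  if (fraction > max_fraction) "exclude" else "include"
}

#' Fractional elevation of heart rate
#'
#' `(HR_exercise - HR_rest) / (HR_max - HR_rest)`, the normalised HR scale
#' every TRIMP weighting is expressed on. Raw values outside `[0, 1]`
#' (field HR can exceed test HRmax) are clipped with a warning.
#'
#' @param hr_exercise exercise heart rate(s), bpm (> 0; `NA` passes
#'   through).
#' @param hr_rest,hr_max the athlete's resting and maximal HR.
#' @return fractional elevation in `[0, 1]`, same length as `hr_exercise`.
#' @export
delta_hr <- function(hr_exercise, hr_rest, hr_max) {
  if (!(is_number(hr_rest) && is_number(hr_max) && hr_max > hr_rest && hr_rest > 0)) {
    stopf("need hr_max > hr_rest > 0")
  }
  if (any(hr_exercise <= 0, na.rm = TRUE)) stopf("hr_exercise must be > 0")
  raw <- (hr_exercise - hr_rest) / (hr_max - hr_rest)
  clip_warn(raw, 0, 1, "delta_hr")
}

#' Last-30-s average heart rate per stage
#'
#' Arithmetic mean of the HR samples in the final half-open 30-s window
#' `[end - 30, end)` of each stage, the per-stage HR entering the lactate
#' exponential fit.
#'
#' @param hr an [hr_series()].
#' @param stage_windows data.frame/list with `start` and `end` times
#'   (seconds) per stage, from the protocol timing.
#' @param tail_s length of the averaged tail, default 30 s.
#' @return numeric vector of per-stage bpm.
#' @export
stage_average_hr <- function(hr, stage_windows, tail_s = 30) {
  stopifnot(inherits(hr, "hr_series"))
  starts <- stage_windows$start
  ends <- stage_windows$end
  if (any(ends - starts < tail_s)) stopf("stage shorter than %g s", tail_s)
  vapply(seq_along(starts), function(i) {
    sel <- hr$times >= (ends[i] - tail_s) & hr$times < ends[i]
    if (!any(sel)) stopf("no HR samples in final %g s of stage %d", tail_s, i)
    mean(hr$hr[sel], na.rm = TRUE)
  }, numeric(1))
}

#' Average a beat-level series onto a uniform 5-s grid
#'
#' One row per half-open bin `[t, t + bin_s)`; the value is the mean over
#' beats falling in the bin. Empty bins carry `NA`, never an interpolated
#' value.
#'
#' @param times beat times in seconds.
#' @param values value per beat.
#' @param bin_s bin width in seconds, default 5.
#' @return data.frame with `time` (bin start) and `value`.
#' @export
grid_5s <- function(times, values, bin_s = 5) {
  if (length(times) != length(values)) stopf("times and values differ in length")
  if (length(times) == 0L) stopf("empty series")
  bin <- floor(times / bin_s) + 1L
  n_bins <- max(bin)
  out <- rep(NA_real_, n_bins)
  agg <- tapply(values, bin, mean)
  out[as.integer(names(agg))] <- agg
  data.frame(time = (seq_len(n_bins) - 1L) * bin_s, value = out)
}
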