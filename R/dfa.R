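#' Short-scale detrended fluctuation analysis exponent (DFA-alpha1)
#'
#' Estimates the scaling exponent of an RR interval series over beat
#' scales 4-16, the short-scale exponent used to track autonomic
#' correlation properties during exercise. The algorithm is classical DFA
#' with linear detrending:
#'
#' 1. integrate the mean-centred intervals into a profile;
#' 2. for each scale `n`, split the profile into non-overlapping boxes of
#'    `n` beats, both from the start and from the end (so every beat is
#'    used), remove a least-squares line per box and take the RMS residual
#'    `F(n)`;
#' 3. alpha1 is the slope of `log F(n)` against `log n` over the scale
#'    set, equally weighted.
#'
#' White (uncorrelated) noise gives alpha1 near 0.5, 1/f noise near 1.0,
#' integrated white noise near 1.5.
#'
#' @param intervals RR intervals (ms) or any numeric series.
#' @param scales integer box sizes in beats; default `4:16`.
#' @return alpha1 estimate (dimensionless).
#' @export
dfa_alpha1 <- function(intervals, scales = 4:16) {
  x <- as.numeric(intervals)
  n_x <- length(x)
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 2L)) stopf("scales must be >= 2 beats")
  if (n_x < max(scales)) stopf("fewer beats (%d) than largest scale (%d)", n_x, max(scales))
  if (stats::var(x) == 0) stopf("zero-variance input")
  prof <- cumsum(x - mean(x))
  log_f <- vapply(scales, function(s) log(.dfa_fluct(prof, s)), numeric(1))
  if (any(!is.finite(log_f))) stopf("degenerate fluctuation function")
  unname(stats::coef(stats::lm(log_f ~ log(scales)))[2L])
}

# RMS residual around a per-box least-squares line at one scale,
# forward and backward boxes pooled. Vectorised: the residual-maker for
# the design [1, 1:s] is applied to all boxes at once.
.dfa_fluct <- function(prof, s) {
  n <- length(prof)
  k <- n %/% s
  t <- seq_len(s)
  X <- cbind(1, t)
  M <- diag(s) - X %*% solve(crossprod(X), t(X))
  fwd <- matrix(prof[seq_len(k * s)], nrow = s)
  bwd <- matrix(prof[(n - k * s + 1L):n], nrow = s)
  r1 <- M %*% fwd
  r2 <- M %*% bwd
  sqrt(mean(c(colMeans(r1 * r1), colMeans(r2 * r2))))
}

#' Sliding-window DFA-alpha1 over an RR recording
#'
#' Recomputes DFA-alpha1 every `step_s` seconds over the trailing
#' `window_s`-second window `(t - window_s, t]`, together with the
#' window-mean heart rate (60000 / mean RR). A row is valid only when the
#' window holds at least `min_beats` beats; the first full window defines
#' the first potentially valid row.
#'
#' Before the DFA step, a low-order polynomial trend (default cubic) is
#' removed from the window's intervals: during a ramp the mean RR
#' declines steadily, and that deterministic drift would otherwise
#' masquerade as long-range correlation and inflate alpha1. This mirrors
#' the slow-trend removal the short-scale DFA exercise literature applies
#' before computing the exponent. Set `detrend_order = 0` for raw
#' windows.
#'
#' @param rr a corrected [rr_series()].
#' @param window_s window length in seconds (default 120).
#' @param step_s recompute step (default 5 s).
#' @param scales DFA box sizes (default `4:16`).
#' @param min_beats minimum beats for a valid window (default 64, i.e.
#'   4 x the largest scale).
#' @param detrend_order polynomial order of the within-window trend
#'   removed before DFA; default 3, 0 disables.
#' @return A [dfa_grid()].
#' @export
windowed_dfa <- function(rr, window_s = 120, step_s = 5, scales = 4:16,
                         min_beats = 64L, detrend_order = 3L) {
  stopifnot(inherits(rr, "rr_series"))
  t_end <- rr$beat_times[length(rr$beat_times)]
  if (t_end < window_s) {
    stopf("recording (%.0f s) shorter than one %g-s window", t_end, window_s)
  }
  grid_t <- seq(window_s, t_end, by = step_s)
  res <- lapply(grid_t, function(t0) {
    sel <- rr$beat_times > (t0 - window_s) & rr$beat_times <= t0
    nb <- sum(sel)
    hr <- if (nb > 0L) 60000 / mean(rr$intervals[sel]) else NA_real_
    a1 <- NA_real_
    ok <- nb >= min_beats
    if (ok) {
      x <- rr$intervals[sel]
      if (detrend_order > 0L) {
        x <- stats::resid(stats::lm(x ~ stats::poly(seq_along(x), detrend_order)))
      }
      a1 <- tryCatch(dfa_alpha1(x, scales), error = function(e) NA_real_)
      ok <- is.finite(a1)
    }
    c(hr = hr, alpha1 = a1, n_beats = nb, valid = as.numeric(ok))
  })
  res <- do.call(rbind, res)
  dfa_grid(time = grid_t, hr = res[, "hr"], alpha1 = res[, "alpha1"],
           n_beats = as.integer(res[, "n_beats"]), valid = res[, "valid"] > 0,
           window_s = window_s, step_s = step_s)
}
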