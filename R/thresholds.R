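#' First lactate threshold by the log-log breakpoint method
#'
#' Fits a continuous two-segment linear regression of log(BLa) on
#' log(speed), scanning breakpoint candidates on a dense 0.05 km/h grid
#' between the second and penultimate stage speeds and minimising the
#' total residual sum of squares. Ties go to the lower RSS, then to the
#' lower speed. When the RSS profile is nearly flat across candidates the
#' breakpoint is poorly identified and the result carries an `uncertain`
#' attribute.
#'
#' @param test a [step_test()] with at least 4 stages of positive BLa.
#' @param grid_step candidate spacing in km/h, default 0.05.
#' @return breakpoint speed in km/h. Attribute `uncertain` is `TRUE` when
#'   the breakpoint is poorly identified: either the below-breakpoint
#'   log-log slope is at least half the above-breakpoint slope (no
#'   distinct baseline segment — e.g. a purely exponential lactate
#'   curve), or the candidates within 5% of the minimum RSS span more
#'   than a quarter of the search range.
#' @export
lt1_loglog <- function(test, grid_step = 0.05) {
  stopifnot(inherits(test, "step_test"))
  sp <- test$speed
  bla <- test$bla
  if (sum(bla > 0) < 4L || nrow(test) < 4L) stopf("need >= 4 stages with BLa > 0")
  if (any(bla <= 0)) stopf("BLa must be > 0 for the log-log fit")
  if (all(diff(bla) <= 0)) stopf("no inflection: BLa never rises")
  lx <- log(sp)
  ly <- log(bla)
  cand <- seq(sp[2L], sp[length(sp) - 1L], by = grid_step)
  fit_at <- function(cc) {
    z <- pmax(lx - log(cc), 0)  # hinge: continuous at the breakpoint
    stats::lm(ly ~ lx + z)
  }
  rss <- vapply(cand, function(cc) sum(stats::resid(fit_at(cc))^2), numeric(1))
  best <- which(rss == min(rss))[1L]  # ties -> lower speed (cand is sorted)
  out <- round(cand[best], 2)
  near <- cand[rss <= min(rss) * 1.05 + 1e-12]
  flat <- (max(near) - min(near)) > 0.25 * (max(cand) - min(cand))
  cf <- stats::coef(fit_at(cand[best]))
  slope1 <- unname(cf["lx"])
  slope2 <- slope1 + unname(cf["z"])
  no_baseline <- !is.finite(slope2) || slope2 <= 0 || slope1 >= 0.5 * slope2
  attr(out, "uncertain") <- flat || no_baseline
  out
}

#' Second lactate threshold: baseline + fixed BLa delta
#'
#' Speed at which BLa first rises `delta` mmol/L above the baseline (the
#' lowest measurement across all stages), linearly interpolated between
#' the bracketing stages. A valid estimate of maximal lactate steady
#' state for 3-min step protocols.
#'
#' @param test a [step_test()].
#' @param delta rise above baseline in mmol/L, default 1.5.
#' @return speed in km/h (reported to 0.01 km/h).
#' @export
lt2_baseline_delta <- function(test, delta = 1.5) {
  stopifnot(inherits(test, "step_test"), delta > 0)
  target <- attr(test, "bla_baseline") + delta
  bla <- test$bla
  sp <- test$speed
  hit <- which(bla >= target)
  if (length(hit) == 0L) stopf("target not attained: max BLa %.2f below %.2f",
                               max(bla), target)
  j <- hit[1L]
  if (bla[j] == target || j == 1L) return(round(sp[j], 2))
  frac <- (target - bla[j - 1L]) / (bla[j] - bla[j - 1L])
  round(sp[j - 1L] + frac * (sp[j] - sp[j - 1L]), 2)
}

#' VO2max attainment from 30-s-averaged gas exchange
#'
#' Attained when at least two of three criteria hold: a VO2 plateau
#' (change < `plateau_l` L/min across at least three consecutive 30-s
#' stages despite increasing speed), RER strictly above `rer_min`, or HR
#' reaching `hr_frac` of age-predicted HRmax (`220 - age` by default).
#'
#' @param gas a [ramp_gas()].
#' @param plateau_l plateau band in L/min, default 0.2.
#' @param plateau_stages consecutive 30-s stages required, default 3.
#' @param rer_min RER criterion (strict >), default 1.1.
#' @param hr_frac fraction of age-predicted HRmax, default 0.95.
#' @param hr_max_formula function of age giving predicted HRmax.
#' @return list with `attained`, `criteria_met` (character subset of
#'   `plateau`, `rer`, `hr`), `vo2max` (highest 30-s value, L/min) and
#'   `v_vo2max` (lowest speed first eliciting it, km/h).
#' @export
vo2max_attained <- function(gas, plateau_l = 0.2, plateau_stages = 3L,
                            rer_min = 1.1, hr_frac = 0.95,
                            hr_max_formula = function(age) 220 - age) {
  stopifnot(inherits(gas, "ramp_gas"))
  vo2 <- gas$vo2
  n <- length(vo2)
  plateau <- FALSE
  if (n >= plateau_stages) {
    for (i in seq_len(n - plateau_stages + 1L)) {
      w <- vo2[i:(i + plateau_stages - 1L)]
      sw <- gas$speed[i:(i + plateau_stages - 1L)]
      if ((max(w) - min(w)) < plateau_l && all(diff(sw) > 0)) {
        plateau <- TRUE
        break
      }
    }
  }
  rer_ok <- max(gas$rer) > rer_min
  hr_pred <- hr_max_formula(attr(gas, "age"))
  hr_ok <- max(gas$hr) >= hr_frac * hr_pred
  met <- c("plateau", "rer", "hr")[c(plateau, rer_ok, hr_ok)]
  vo2max <- max(vo2)
  first <- which(vo2 == vo2max)[1L]
  list(attained = length(met) >= 2L, criteria_met = met,
       vo2max = vo2max, v_vo2max = gas$speed[first])
}

#' Step-test termination status per stage
#'
#' The step protocol terminates after the first stage at which both
#' criteria have (cumulatively) been met: BLa strictly above `bla_min`
#' mmol/L and RPE at or above `rpe_min`. Each criterion may first be met
#' at a different stage; progression continues until the second one is
#' also achieved.
#'
#' @param test a [step_test()].
#' @param bla_min BLa criterion (strict >), default 4 mmol/L.
#' @param rpe_min RPE criterion (>=), default 18.
#' @return logical vector, `TRUE` from the stage at which the test may
#'   terminate.
#' @export
step_termination_check <- function(test, bla_min = 4, rpe_min = 18) {
  stopifnot(inherits(test, "step_test"))
  (cummax(test$bla > bla_min) > 0) & (cummax(test$rpe >= rpe_min) > 0)
}
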