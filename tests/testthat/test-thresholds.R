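# Independent log-log breakpoint oracle: hand-rolled normal equations over
# the same candidate grid, no lm().
oracle_lt1 <- function(speed, bla, grid_step = 0.05) {
  lx <- log(speed); ly <- log(bla)
  cand <- seq(speed[2], speed[length(speed) - 1], by = grid_step)
  rss <- vapply(cand, function(cc) {
    X <- cbind(1, lx, pmax(lx - log(cc), 0))
    beta <- qr.solve(crossprod(X), crossprod(X, ly))
    sum((ly - X %*% beta)^2)
  }, numeric(1))
  cand[which.min(rss)]
}

test_that("log-log LT1 finds the inflection and matches the exhaustive oracle", {
  # flat baseline through 10 km/h, then doubling per stage
  speed <- 6:13
  bla <- c(1, 1, 1, 1, 1, 2, 4, 8)
  st <- step_test(data.frame(stage = 1:8, speed = speed,
                             hr_last30 = seq(110, 180, by = 10),
                             bla = bla, rpe = pmin(20, 6 + 2 * (1:8))),
                  hr_rest = 60, hr_max = 190)
  est <- lt1_loglog(st)
  expect_lt(abs(est - 10), 0.5)
  expect_equal(as.numeric(est), oracle_lt1(speed, bla), tolerance = 0.026)

  # random convex lactate curves agree with the oracle exactly
  set.seed(5)
  for (i in 1:5) {
    bla_i <- 1 + c(0, 0.05, 0.1, 0.3, 0.9, 2.1, 4.2) * runif(1, 0.5, 2)
    st_i <- step_test(data.frame(stage = 1:7, speed = 7:13,
                                 hr_last30 = seq(115, 175, by = 10),
                                 bla = bla_i, rpe = pmin(20, 6 + 2 * (1:7))),
                      hr_rest = 60, hr_max = 190)
    expect_equal(as.numeric(lt1_loglog(st_i)), oracle_lt1(7:13, bla_i),
                 tolerance = 1e-9)
  }
})

test_that("LT1 degenerate inputs: too few stages, no rise, flat RSS flag", {
  st3 <- step_test(data.frame(stage = 1:3, speed = 8:10,
                              hr_last30 = c(120, 140, 160),
                              bla = c(1, 2, 4), rpe = c(8, 11, 14)),
                   hr_rest = 60, hr_max = 190)
  expect_error(lt1_loglog(st3), ">= 4 stages")

  dec <- step_test(data.frame(stage = 1:5, speed = 8:12,
                              hr_last30 = seq(120, 170, length.out = 5),
                              bla = c(3, 2.5, 2, 1.5, 1), rpe = c(8, 10, 12, 14, 16)),
                   hr_rest = 60, hr_max = 190)
  expect_error(lt1_loglog(dec), "no inflection")

  # perfectly exponential BLa: breakpoint poorly identified
  dhr <- seq(0.3, 0.9, 0.1)
  exp_st <- step_test(data.frame(stage = 1:7, speed = 8:14,
                                 hr_last30 = 60 + dhr * 130,
                                 bla = exp(2.5 * dhr), rpe = pmin(20, 6 + 2 * (1:7))),
                      hr_rest = 60, hr_max = 190)
  expect_true(isTRUE(attr(lt1_loglog(exp_st), "uncertain")))
})

test_that("LT1 is invariant to rescaling all BLa values", {
  st <- ref_step_test()
  st2 <- step_test(data.frame(stage = st$stage, speed = st$speed,
                              hr_last30 = st$hr_last30, bla = st$bla * 3.1,
                              rpe = st$rpe),
                   hr_rest = attr(st, "hr_rest"), hr_max = attr(st, "hr_max"))
  expect_equal(as.numeric(lt1_loglog(st)), as.numeric(lt1_loglog(st2)))
})

test_that("LT2 interpolates the baseline + delta crossing", {
  st <- step_test(data.frame(stage = 1:4, speed = 8:11,
                             hr_last30 = c(120, 140, 160, 175),
                             bla = c(1.0, 1.2, 2.0, 3.4), rpe = c(8, 11, 14, 17)),
                  hr_rest = 60, hr_max = 190)
  expect_equal(lt2_baseline_delta(st), round(10 + 0.5 / 1.4, 2))

  exact <- step_test(data.frame(stage = 1:4, speed = 8:11,
                                hr_last30 = c(120, 140, 160, 175),
                                bla = c(1.0, 1.5, 2.5, 4.0), rpe = c(8, 11, 14, 17)),
                     hr_rest = 60, hr_max = 190)
  expect_equal(lt2_baseline_delta(exact), 10)  # hits 2.5 exactly at stage 3

  low <- step_test(data.frame(stage = 1:4, speed = 8:11,
                              hr_last30 = c(120, 140, 160, 175),
                              bla = c(1.0, 1.2, 1.6, 2.0), rpe = c(8, 11, 14, 17)),
                   hr_rest = 60, hr_max = 190)
  expect_error(lt2_baseline_delta(low), "not attained")
})

test_that("LT2 speed is monotone non-decreasing in delta and below LT max", {
  st <- ref_step_test()
  deltas <- seq(0.5, 3, by = 0.25)
  sp <- vapply(deltas, function(d) lt2_baseline_delta(st, delta = d), numeric(1))
  expect_true(all(diff(sp) >= 0))
})

test_that("flat-baseline-then-rise lactate profiles place LT1 below LT2", {
  # the log-log method presumes a shallow baseline segment before the rise;
  # random such profiles must order the thresholds essentially always
  set.seed(88)
  ok <- 0L
  n_eval <- 0L
  for (i in 1:60) {
    base <- runif(1, 0.8, 1.6)
    a <- runif(1, 0.2, 0.5)
    b <- runif(1, 2.2, 3.5)
    dhr <- seq(0.2, 0.95, length.out = 8)
    bla <- pmax(pmax(base, a * exp(b / 0.95 * dhr)) + rnorm(8, 0, 0.15), 0.3)
    st <- step_test(data.frame(stage = 1:8, speed = 6:13,
                               hr_last30 = 60 + dhr * 130,
                               bla = bla, rpe = pmin(20, 6 + 2 * (1:8))),
                    hr_rest = 60, hr_max = 190)
    v1 <- tryCatch({
      est <- lt1_loglog(st)
      if (isTRUE(attr(est, "uncertain"))) NA_real_ else as.numeric(est)
    }, error = function(e) NA_real_)
    v2 <- tryCatch(lt2_baseline_delta(st), error = function(e) NA_real_)
    if (is.na(v1) || is.na(v2)) next
    n_eval <- n_eval + 1L
    if (v1 < v2) ok <- ok + 1L
  }
  expect_gt(n_eval, 30L)
  expect_gte(ok / n_eval, 0.99)
})

test_that("VO2max attainment applies the two-of-three rule with strict RER", {
  mk <- function(vo2, rer, hr, age = 30) {
    ramp_gas(time = seq(0, by = 30, length.out = length(vo2)),
             vo2 = vo2, rer = rer, hr = hr, age = age)
  }
  # plateau + RER, HR below 95% of 190
  g <- mk(c(2.0, 2.5, 3.0, 3.05, 3.1), rep(1.15, 5), rep(160, 5))
  res <- vo2max_attained(g)
  expect_true(res$attained)
  expect_setequal(res$criteria_met, c("plateau", "rer"))
  expect_equal(res$vo2max, 3.1)

  # only RER
  g2 <- mk(c(2.0, 2.5, 3.0, 3.5, 4.0), rep(1.15, 5), rep(150, 5))
  expect_false(vo2max_attained(g2)$attained)

  # RER exactly 1.1 does not count
  g3 <- mk(c(2.0, 2.5, 3.0, 3.05, 3.1), rep(1.1, 5), rep(150, 5))
  expect_false("rer" %in% vo2max_attained(g3)$criteria_met)

  # HR criterion with 220 - age
  g4 <- mk(c(2.0, 2.5, 3.0, 3.5, 4.0), rep(1.0, 5), c(150, 160, 170, 178, 181))
  expect_true("hr" %in% vo2max_attained(g4)$criteria_met)  # 181 >= 0.95*190
})

test_that("step termination requires both criteria cumulatively", {
  mk_st <- function(bla, rpe) {
    step_test(data.frame(stage = seq_along(bla), speed = 7 + seq_along(bla),
                         hr_last30 = seq(120, by = 8, length.out = length(bla)),
                         bla = bla, rpe = rpe),
              hr_rest = 60, hr_max = 195)
  }
  # BLa criterion at stage 6, RPE at stage 7 -> terminate after 7
  t1 <- step_termination_check(mk_st(c(1, 1.5, 2, 3, 3.8, 4.2, 5.1),
                                     c(8, 10, 12, 14, 16, 17, 18)))
  expect_equal(which(t1)[1], 7L)
  # BLa exactly 4 is not enough
  t2 <- step_termination_check(mk_st(c(1, 2, 3, 4.0), c(9, 13, 17, 19)))
  expect_false(any(t2))
  # both at stage 5
  t3 <- step_termination_check(mk_st(c(1, 1.5, 2.5, 3.5, 4.5),
                                     c(9, 11, 14, 16, 18)))
  expect_equal(which(t3)[1], 5L)
})
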