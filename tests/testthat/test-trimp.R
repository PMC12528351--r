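test_that("DFA normalisation maps rest to 0 and maximal to 1, clipping outside", {
  g <- grid_from_alpha(c(1.5, 1.2, 0.9, 0.6, 0.3))
  an <- normalise_dfa(g, anchors = list(dfa_rest = 1.5, dfa_maximal = 0.3))
  expect_equal(an$alpha_norm, c(0, 0.25, 0.5, 0.75, 1))

  expect_warning(
    an2 <- normalise_dfa(g, anchors = list(dfa_rest = 1.4, dfa_maximal = 0.4)),
    "clipped"
  )
  expect_equal(range(an2$alpha_norm), c(0, 1))

  expect_error(normalise_dfa(g, anchors = list(dfa_rest = 1, dfa_maximal = 1)),
               "differ")
  expect_error(normalise_dfa(g, anchors = list(dfa_rest = 0.3, dfa_maximal = 1.5)),
               "exceed")
})

test_that("anchor estimation uses smoothed extremes and rejects flat traces", {
  set.seed(2)
  a <- c(rep(1.3, 20) + rnorm(20, 0, 0.02), seq(1.3, 0.35, length.out = 60))
  g <- grid_from_alpha(a)
  an <- estimate_dfa_anchors(g, rest_end_s = 120 + 19 * 5)
  expect_lt(abs(an$dfa_rest - 1.3), 0.06)
  expect_lt(abs(an$dfa_maximal - 0.35), 0.03)
  # single outlier window cannot define an anchor when smoothing is on
  a_out <- a
  a_out[40] <- 3.0
  expect_equal(estimate_dfa_anchors(grid_from_alpha(a_out))$dfa_rest,
               an$dfa_rest, tolerance = 0.05)
  expect_error(estimate_dfa_anchors(grid_from_alpha(rep(1, 30))), "flat")
})

test_that("lactate exponential fit is exact on noiseless data", {
  dhr <- seq(0.3, 0.9, by = 0.1)
  fit <- fit_bla_exponential(dhr, 1.2 * exp(3.0 * dhr))
  expect_rel_equal(fit$a, 1.2, 1e-6)
  expect_rel_equal(fit$b, 3.0, 1e-6)
  expect_lt(fit$rss, 1e-12)

  expect_error(fit_bla_exponential(dhr[1:3], rep(1, 3)), ">= 4")
  expect_error(fit_bla_exponential(dhr, c(1, 2, 3, 0, 1, 2, 3)), "> 0")
  flat <- fit_bla_exponential(dhr, rep(2, 7))
  expect_true(flat$flagged)
})

test_that("lactate slope recovery under stage noise: median relative error < 10%", {
  set.seed(202)
  dhr <- pmin(0.35 + 0.1 * (0:7), 0.98)
  rel_err <- replicate(500, {
    bla <- pmax(1.2 * exp(2.2 * dhr) + rnorm(8, 0, 0.3), 0.3)
    abs(fit_bla_exponential(dhr, bla)$b - 2.2) / 2.2
  })
  expect_lt(median(rel_err), 0.10)
})

test_that("fixed-intercept alpha fit: closed-form recovery, zero handling", {
  q_true <- log(0.5 / 0.06) / 0.75
  dhr <- seq(0.05, 0.95, length.out = 30)
  fit <- fit_alpha_exponential(dhr, 0.06 * exp(q_true * dhr))
  expect_rel_equal(fit$q, q_true, 1e-6)
  prof <- athlete_profile(hr_rest = 60, hr_max = 190,
                          atrimp = list(p = 0.06, q = fit$q))
  expect_equal(weighting(prof, 0.75, "atrimp"), 0.5, tolerance = 1e-6)

  expect_error(fit_alpha_exponential(dhr, rep(0, 30)), "zero")
  # zeros are dropped, not fitted
  an <- c(rep(0, 5), 0.06 * exp(q_true * dhr))
  fit2 <- fit_alpha_exponential(c(runif(5), dhr), an)
  expect_equal(fit2$n, 30L)
  expect_rel_equal(fit2$q, q_true, 1e-6)
  expect_error(fit_alpha_exponential(dhr[1:5], 0.06 * exp(dhr[1:5])), ">= 10")
})

test_that("free alpha fit recovers both coefficients; cohort p is the mean", {
  dhr <- seq(0.05, 0.95, length.out = 25)
  fit <- fit_alpha_exponential_free(dhr, 0.045 * exp(3.2 * dhr))
  expect_rel_equal(fit$p, 0.045, 1e-6)
  expect_rel_equal(fit$q, 3.2, 1e-6)
  expect_equal(standardise_intercept(c(0.04, 0.06, 0.08)), 0.06)
  expect_equal(standardise_intercept(0.07), 0.07)
})

test_that("weighting identities at the intercept and the slope relation", {
  prof <- athlete_profile(hr_rest = 60, hr_max = 190,
                          itrimp = list(a = 1.4, b = 2.6),
                          atrimp = list(p = 0.06, q = 2.9))
  expect_equal(weighting(prof, 0, "itrimp"), 1.4)   # a_i = resting BLa
  expect_equal(weighting(prof, 0, "atrimp"), 0.06)  # fixed intercept p
  grid <- seq(0, 1, length.out = 100)
  expect_equal(weighting_slope(prof, grid, "itrimp") / weighting(prof, grid, "itrimp"),
               rep(2.6, 100))
  expect_equal(weighting_slope(prof, 0, "atrimp"), 2.9 * 0.06)
  # finite differences agree at O(h^2)
  h <- 1e-5
  fd <- (weighting(prof, grid[2:99] + h, "atrimp") -
           weighting(prof, grid[2:99] - h, "atrimp")) / (2 * h)
  expect_equal(fd, weighting_slope(prof, grid[2:99], "atrimp"), tolerance = 1e-7)
})

test_that("session TRIMP closed forms, conventions, missing samples", {
  prof <- athlete_profile(hr_rest = 60, hr_max = 180,
                          itrimp = list(a = 1, b = 2))
  hr <- hr_series(seq(0, 599), rep(120, 600))  # dHR = 0.5 for 10 min
  manzi <- session_trimp(hr, prof)
  literal <- session_trimp(hr, prof, convention = "literal")
  expect_equal(manzi$total, 10 * 0.5 * exp(1), tolerance = 1e-9)
  expect_equal(literal$total, 10 * exp(1), tolerance = 1e-9)
  expect_equal(manzi$total, sum(manzi$contributions))
  expect_equal(manzi$mean_delta_hr, 0.5)

  gaps <- hr_series(seq(0, 599), c(rep(120, 300), rep(NA, 60), rep(120, 240)))
  res <- session_trimp(gaps, prof)
  expect_equal(res$n_missing, 60L)
  expect_equal(res$total, 9 * 0.5 * exp(1), tolerance = 1e-9)

  expect_error(session_trimp(hr_series(0:9, rep(NA_real_, 10)), prof), "empty")
  noat <- athlete_profile(hr_rest = 60, hr_max = 180, itrimp = list(a = 1, b = 2))
  expect_error(session_trimp(hr, noat, method = "atrimp"), "no alphaTRIMP")
})

test_that("TRIMP is additive over concatenated sessions and monotone in dHR", {
  prof <- athlete_profile(hr_rest = 60, hr_max = 190,
                          itrimp = list(a = 1.3, b = 2.4),
                          atrimp = list(p = 0.06, q = 2.8))
  set.seed(8)
  hr_a <- 80 + 60 * runif(300)
  hr_b <- 80 + 60 * runif(200)
  for (m in c("itrimp", "atrimp")) {
    for (cv in c("manzi", "literal")) {
      ta <- session_trimp(hr_series(seq_along(hr_a) - 1, hr_a), prof, m, cv)$total
      tb <- session_trimp(hr_series(seq_along(hr_b) - 1, hr_b), prof, m, cv)$total
      tab <- session_trimp(hr_series(seq_len(500) - 1, c(hr_a, hr_b)), prof, m, cv)$total
      expect_equal(tab, ta + tb, tolerance = 1e-12)
    }
  }
  lower <- session_trimp(hr_series(0:299, hr_a), prof)$total
  higher <- session_trimp(hr_series(0:299, pmin(hr_a + 15, 190)), prof)$total
  expect_gte(higher, lower)
})

test_that("multi-crossing QC fails double dips and flags incomplete range", {
  mono <- grid_from_alpha(seq(1.2, 0.3, length.out = 60))
  expect_true(qc_multi_crossing(mono)$pass)

  dip <- grid_from_alpha(c(seq(1.2, 0.65, length.out = 20),
                           seq(0.65, 0.95, length.out = 15),
                           seq(0.95, 0.3, length.out = 25)))
  res <- qc_multi_crossing(dip)
  expect_false(res$pass)
  expect_gt(res$counts[["th0.75"]], 1)

  shallow <- grid_from_alpha(seq(1.2, 0.6, length.out = 40))
  res2 <- qc_multi_crossing(shallow)
  expect_true(res2$pass)
  expect_equal(res2$note, "incomplete range")
})

test_that("fitted weightings at fixed dHR rank-inversely with latent fitness", {
  co <- make_cohort(30, seed = 41)
  w75 <- vapply(seq_len(30), function(i) {
    ath <- co$athletes[i, ]
    st <- simulate_step_test(ath, seed = 900 + i)
    prof <- profile_from_step(st)$profile
    weighting(prof, 0.75, "itrimp")
  }, numeric(1))
  expect_lt(cor(w75, co$athletes$z, method = "spearman"), -0.8)
})
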