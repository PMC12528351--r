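#' Gaussian 1/f^beta noise by spectral synthesis
#'
#' Generates a zero-mean, unit-variance series whose power spectrum
#' follows `f^-beta` with `beta = 2 * alpha - 1`, so its DFA exponent is
#' `alpha` in expectation: white noise at `alpha = 0.5`, pink (1/f) at
#' `alpha = 1`, Brownian-like at `alpha = 1.5`. Random Fourier phases,
#' Hermitian-symmetric spectrum, inverse FFT. Draws from the current RNG
#' stream.
#'
#' @param n series length.
#' @param alpha target DFA scaling exponent.
#' @return numeric vector of length `n`.
#' @export
fractal_noise <- function(n, alpha) {
  stopifnot(n >= 8, is_number(alpha))
  beta <- 2 * alpha - 1
  k <- seq_len(n - 1)
  fk <- pmin(k, n - k) / n          # symmetric frequency magnitudes
  amp <- fk^(-beta / 2)
  half <- seq_len(floor((n - 1) / 2))
  ph <- numeric(n - 1)
  ph[half] <- stats::runif(length(half), 0, 2 * pi)
  ph[n - half] <- -ph[half]         # Hermitian symmetry -> real signal
  if (n %% 2 == 0) ph[n / 2] <- 0   # Nyquist bin must be real
  spec <- complex(modulus = c(0, amp), argument = c(0, ph))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Generate a synthetic athlete cohort with fitness-coupled coefficients
#'
#' Each athlete has a latent fitness score `z ~ N(0, 1)`. The six CRF
#' panel variables are affine in `z` with Gaussian noise scaled so the
#' first principal component captures a configurable fraction of the
#' variance; panel means and spreads follow typical recreationally
#' active adults (VO2max 48 +/- 8 mL/kg/min, threshold speeds 10-13
#' km/h). The TRIMP coefficients are log-linear in `z` with negative
#' fitness slopes — lower fitness gives steeper weighting curves, the
#' construct under test — plus log-normal athlete-level noise.
#' `effect_size` scales the fitness slopes (0 decouples coefficients
#' from fitness entirely).
#'
#' @param n cohort size.
#' @param seed integer seed; same seed reproduces the cohort exactly.
#' @param effect_size multiplier on the fitness dependence of the
#'   coefficients; default 1 (moderate coupling).
#' @param pc1_target target PC1 explained-variance fraction of the panel,
#'   default 0.89; 1 gives a noiseless rank-1 panel.
#' @return list with `athletes` (data.frame of latent scores and true
#'   coefficients: `z`, `a`, `b`, `q`, `p_i`, `hr_rest`, `hr_max`,
#'   `dfa_rest`, `dfa_maximal`) and `panel` (a [crf_panel()]).
#' @export
make_cohort <- function(n, seed = 1L, effect_size = 1, pc1_target = 0.89) {
  stopifnot(n >= 3L, pc1_target > 1 / 6, pc1_target <= 1)
  with_seed(seed, {
    z <- stats::rnorm(n)
    lambda <- sqrt((6 * pc1_target - 1) / 5)
    panel_mu <- c(vo2max = 48.32, v_vo2max = 15.87, v_lt1 = 9.83,
                  v_lt2 = 11.71, v_vt1 = 10.07, v_vt2 = 13.28)
    panel_sd <- c(7.95, 2.24, 2.21, 2.29, 2.11, 2.01)
    noise_sd <- sqrt(max(0, 1 - lambda^2))
    raw <- vapply(seq_along(panel_mu), function(j) {
      panel_mu[j] + panel_sd[j] * (lambda * z + noise_sd * stats::rnorm(n))
    }, numeric(n))
    colnames(raw) <- names(panel_mu)
    raw <- pmax(raw, 3)  # physiological floor
    # keep the per-athlete lactate-threshold ordering the panel requires
    bad <- raw[, "v_lt2"] <= raw[, "v_lt1"]
    if (any(bad)) {
      mid <- (raw[bad, "v_lt1"] + raw[bad, "v_lt2"]) / 2
      raw[bad, "v_lt1"] <- mid - 0.25
      raw[bad, "v_lt2"] <- mid + 0.25
    }
    es <- effect_size
    ath <- data.frame(
      id = sprintf("ath%02d", seq_len(n)),
      z = z,
      a = 1.2 * exp(-es * 0.10 * z + stats::rnorm(n, 0, 0.05)),
      b = 2.2 * exp(-es * 0.25 * z + stats::rnorm(n, 0, 0.08)),
      q = 2.9 * exp(-es * 0.18 * z + stats::rnorm(n, 0, 0.06)),
      p_i = 0.06 * exp(-es * 0.05 * z + stats::rnorm(n, 0, 0.04)),
      hr_rest = pmin(pmax(60 - 3 * z + stats::rnorm(n, 0, 3), 40), 80),
      hr_max = pmin(pmax(190 + stats::rnorm(n, 0, 7), 170), 210),
      dfa_rest = pmin(pmax(1.35 + stats::rnorm(n, 0, 0.08), 1.05), 1.60),
      dfa_maximal = pmin(pmax(0.30 + stats::rnorm(n, 0, 0.04), 0.18), 0.45)
    )
    list(athletes = ath,
         panel = crf_panel(cbind(data.frame(id = ath$id), as.data.frame(raw))))
  })
}

#' Simulate a step incremental test for one athlete
#'
#' Speeds increase by 1 km/h per 3-min stage from the starting speed;
#' the fractional HR elevation rises linearly across stages toward its
#' cap, and BLa follows the athlete's true exponential
#' `a * exp(b * dHR)` plus truncated Gaussian noise (floored at the
#' physiological minimum of 0.3 mmol/L). RPE grows with dHR on the Borg
#' 6-20 scale. Stages are appended until the termination rule (BLa
#' strictly above 4 mmol/L and RPE at least 18, each possibly at a
#' different stage) has been satisfied.
#'
#' @param athlete one row of `make_cohort()$athletes` (or any list with
#'   `a`, `b`, `hr_rest`, `hr_max`).
#' @param bla_noise_sd BLa noise standard deviation in mmol/L, default
#'   0.3; 0 gives noiseless measurements.
#' @param seed integer seed.
#' @param start_speed first-stage speed, km/h (default 6).
#' @param dhr_start,dhr_step,dhr_cap dHR at stage 1, per-stage rise, and
#'   ceiling (defaults 0.35, 0.10, 0.98).
#' @param max_stages hard stop, default 12.
#' @return a [step_test()].
#' @export
simulate_step_test <- function(athlete, bla_noise_sd = 0.3, seed = 1L,
                               start_speed = 6, dhr_start = 0.35,
                               dhr_step = 0.10, dhr_cap = 0.98,
                               max_stages = 12L) {
  with_seed(seed, {
    stages <- list()
    k <- 0L
    repeat {
      k <- k + 1L
      dhr <- min(dhr_start + (k - 1L) * dhr_step, dhr_cap)
      hr <- athlete$hr_rest + dhr * (athlete$hr_max - athlete$hr_rest)
      bla <- athlete$a * exp(athlete$b * dhr)
      if (bla_noise_sd > 0) bla <- max(bla + stats::rnorm(1, 0, bla_noise_sd), 0.3)
      rpe <- min(20, max(6, round(6 + 14 * dhr^1.5)))
      stages[[k]] <- data.frame(stage = k, speed = start_speed + (k - 1L),
                                hr_last30 = hr, bla = bla, rpe = rpe)
      df <- do.call(rbind, stages)
      done <- any(df$bla > 4) && any(df$rpe >= 18)
      if ((done && k >= 4L) || k >= max_stages) break
    }
    step_test(do.call(rbind, stages), hr_rest = athlete$hr_rest,
              hr_max = athlete$hr_max)
  })
}

#' Simulate a ramp-test RR recording with a known DFA-alpha1 trajectory
#'
#' Emulates the chest-strap recording of a continuous ramp test: a
#' seated rest segment followed by a ramp during which the fractional HR
#' elevation rises linearly to near-maximal. The target alpha1
#' trajectory is the athlete's inverted weighting curve,
#' `alpha*(t) = dfa_rest - (dfa_rest - dfa_maximal) * min(p_i *
#' exp(q * dHR(t)), 1)`, so the full analysis chain has a known ground
#' truth. The RR series is synthesised block-wise (64 beats, 50%
#' overlap, raised-cosine cross-fade) from spectrally shaped fractal
#' noise whose local exponent follows `alpha*(t)`; the mean RR tracks
#' `60000 / HR(t)` and the variability amplitude shrinks with intensity
#' (roughly 48 ms at rest to a few ms near maximum).
#'
#' @param athlete list/row with `p_i`, `q`, `hr_rest`, `hr_max`,
#'   `dfa_rest`, `dfa_maximal`.
#' @param seed integer seed.
#' @param rest_s resting-segment duration, s (default 300).
#' @param ramp_s ramp duration, s (default 720, i.e. 4 km/h + 0.5 per
#'   30 s up to ~16 km/h).
#' @param dhr_start,dhr_end dHR at ramp start/end (defaults 0.10, 0.97).
#' @param tau_on HR onset time constant in seconds (default 30): the
#'   fractional elevation approaches the ramp target with first-order
#'   kinetics, as HR does at exercise onset, rather than stepping.
#' @return list with `rr` (an [rr_series()]) and `truth` (data.frame of
#'   beat `time`, true `dhr` and `alpha_target`).
#' @export
simulate_ramp_rr <- function(athlete, seed = 1L, rest_s = 300, ramp_s = 720,
                             dhr_start = 0.10, dhr_end = 0.97, tau_on = 30) {
  if (rest_s + ramp_s < 120) stopf("duration shorter than one DFA window")
  with_seed(seed, {
    total_s <- rest_s + ramp_s
    dhr_at <- function(t) {
      target <- dhr_start + (dhr_end - dhr_start) * pmin((t - rest_s) / ramp_s, 1)
      onset <- 1 - exp(-pmax(t - rest_s, 0) / tau_on)
      ifelse(t < rest_s, 0, target * onset)
    }
    hr_at <- function(t) athlete$hr_rest + dhr_at(t) * (athlete$hr_max - athlete$hr_rest)
    alpha_at <- function(t) {
      w <- pmin(pmax(athlete$p_i * exp(athlete$q * dhr_at(t)), 0), 1)
      athlete$dfa_rest - (athlete$dfa_rest - athlete$dfa_maximal) * w
    }
    # deterministic beat->time map from the mean RR trajectory
    t_map <- numeric(0)
    t <- 0
    while (t < total_s) {
      t_map <- c(t_map, t)
      t <- t + 60 / hr_at(t)
    }
    n_beats <- length(t_map)
    # block-wise fractal noise, 64 beats per block, hop 32, cross-faded
    block <- 64L
    hop <- 32L
    n_blocks <- ceiling((n_beats - block) / hop) + 1L
    z <- numeric(n_beats + block)
    wsq <- numeric(n_beats + block)
    # power-complementary sine window: overlapping squares sum to 1
    fade <- sin(pi * (seq_len(block) - 0.5) / block)
    for (m in seq_len(n_blocks)) {
      i0 <- (m - 1L) * hop
      centre_t <- t_map[min(i0 + block %/% 2L, n_beats)]
      zb <- fractal_noise(block, alpha_at(centre_t))
      idx <- i0 + seq_len(block)
      z[idx] <- z[idx] + fade * zb
      wsq[idx] <- wsq[idx] + fade^2
    }
    z <- (z / sqrt(pmax(wsq, 1e-12)))[seq_len(n_beats)]
    sd_rr <- 45 * exp(-2.2 * dhr_at(t_map)) + 3
    rr_ms <- pmax(60000 / hr_at(t_map) + sd_rr * z, 250)
    list(rr = rr_series(rr_ms),
         truth = data.frame(time = t_map, dhr = dhr_at(t_map),
                            alpha_target = alpha_at(t_map)))
  })
}

#' Inject missed- and extra-beat artifacts into an RR series
#'
#' Randomly selected beats are replaced by a doubled (missed detection)
#' or halved (spurious extra detection) interval, each with probability
#' 1/2, emulating chest-strap artifact contamination at a controlled
#' rate. Flags are reset — detection is the job of
#' [detect_artifacts()].
#'
#' @param rr an [rr_series()].
#' @param rate fraction of beats corrupted, in `[0, 1)`.
#' @param seed integer seed.
#' @return corrupted [rr_series()] with attribute `injected` giving the
#'   corrupted beat indices.
#' @export
inject_artifacts <- function(rr, rate, seed = 1L) {
  stopifnot(inherits(rr, "rr_series"), rate >= 0, rate < 1)
  if (rate == 0) return(rr)
  with_seed(seed, {
    n <- length(rr$intervals)
    k <- round(rate * n)
    if (k == 0L) return(rr)
    idx <- sort(sample.int(n, k))
    mult <- sample(c(2, 0.5), k, replace = TRUE)
    x <- rr$intervals
    x[idx] <- x[idx] * mult
    out <- rr_series(x)
    attr(out, "injected") <- idx
    out
  })
}
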