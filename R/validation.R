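#' Variance inflation factors of a variable panel
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing variable
#' `j` on all the others; the standard multicollinearity screen applied
#' before merging the fitness variables by PCA. Perfectly collinear
#' columns are reported at the 1e6 cap.
#'
#' @param x numeric matrix or data.frame, athletes x variables.
#' @return named vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) stopf("need >= 2 variables")
  out <- vapply(seq_len(p), function(j) {
    # perfect-fit warnings are expected for collinear columns
    r2 <- suppressWarnings(
      summary(stats::lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-6) 1e6 else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO from the squared zero-order correlations against the
#' squared anti-image partial correlations; values at or above 0.5
#' conventionally indicate suitability for PCA.
#'
#' @param x numeric matrix or data.frame, observations x variables.
#' @return KMO value in `[0, 1]`.
#' @export
kmo <- function(x) {
  r <- stats::cor(as.matrix(x))
  ri <- solve(r)
  d <- 1 / sqrt(diag(ri))
  partial <- -ri * outer(d, d)
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(partial[off]^2))
}

#' Bartlett test of sphericity
#'
#' Chi-square test that the correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2p + 5) / 6) * log(det(R))` with
#' `p (p - 1) / 2` degrees of freedom.
#'
#' @param x numeric matrix or data.frame, observations x variables.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  r <- stats::cor(x)
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(det(r))
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Merge the CRF panel into a single fitness score by PCA
#'
#' Mean-centres and standardises the six fitness variables, performs PCA
#' on the correlation structure (via [stats::prcomp()]), and returns the
#' first-component scores as the merged fitness measure CRF_m. Loadings
#' are oriented so that CRF_m correlates positively with VO2max. KMO and
#' Bartlett diagnostics are attached.
#'
#' @param panel a [crf_panel()] (or a plain numeric matrix of fitness
#'   variables; orientation then uses the first column).
#' @return list of class `pca_result`: `eigenvalues`, `explained`
#'   (fractions summing to 1), `loadings`, `scores`, `crf_m` (PC1
#'   scores), `kmo`, `bartlett`.
#' @export
pca_crfm <- function(panel) {
  x <- if (inherits(panel, "crf_panel")) crf_matrix(panel) else as.matrix(panel)
  if (nrow(x) < 3L) stopf("need >= 3 athletes")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  anchor <- if ("vo2max" %in% colnames(x)) x[, "vo2max"] else x[, 1L]
  flip <- sign(stats::cor(pc$x[, 1L], anchor))
  if (flip < 0) {
    pc$rotation <- -pc$rotation
    pc$x <- -pc$x
  }
  structure(list(eigenvalues = ev, explained = ev / sum(ev),
                 loadings = pc$rotation, scores = pc$x,
                 crf_m = unname(pc$x[, 1L]),
                 # singular correlation matrices (e.g. rank-1 panels) have no
                 # defined sampling adequacy
                 kmo = tryCatch(kmo(x), error = function(e) NA_real_),
                 bartlett = bartlett_sphericity(x)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> PC1 %.1f%% of variance, KMO %.2f, Bartlett p %.2g\n",
              100 * x$explained[1L], x$kmo, x$bartlett$p_value))
  invisible(x)
}

#' Effect-size band for a coefficient of determination
#'
#' `< 0.3` very weak, `0.3-0.5` low, `0.5-0.7` moderate, `> 0.7` strong;
#' boundary values fall in the lower band.
#'
#' @param r2 R-squared value(s).
#' @param breaks band boundaries, default `c(0.3, 0.5, 0.7)`.
#' @return character band label(s).
#' @export
r2_band <- function(r2, breaks = c(0.3, 0.5, 0.7)) {
  labs <- c("very weak", "low", "moderate", "strong")
  labs[findInterval(r2, breaks, left.open = TRUE) + 1L]
}

#' Tenfold cross-validated R-squared of a polynomial regression
#'
#' Seeded random partition into `k` folds (sizes differing by at most 1,
#' every observation in exactly one test fold); per fold, the model is
#' refitted on the training folds and the out-of-sample
#' `R2 = 1 - SSE / SST` evaluated on the held-out fold (SST about the
#' held-out mean; negative values possible and informative).
#'
#' @param x predictor (CRF_m scores).
#' @param y response.
#' @param order 1 (linear) or 2 (adds the centred square of `x`).
#' @param k number of folds, default 10.
#' @param seed integer seed for the fold assignment.
#' @return list with `mean`, `sd`, `fold_r2`, `band` (label of the mean).
#' @export
kfold_cv_r2 <- function(x, y, order = 1L, k = 10L, seed = 1L) {
  n <- length(y)
  if (length(x) != n) stopf("x and y differ in length")
  if (k < 2L || k > n) stopf("k must be in [2, n]")
  xc <- x - mean(x)
  design <- if (order == 2L) cbind(x, xc^2) else cbind(x)
  # seeded fold assignment without disturbing the caller's RNG stream
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  fold_r2 <- vapply(seq_len(k), function(f) {
    te <- folds == f
    fit <- stats::lm.fit(cbind(1, design[!te, , drop = FALSE]), y[!te])
    pred <- cbind(1, design[te, , drop = FALSE]) %*% fit$coefficients
    sse <- sum((y[te] - pred)^2)
    sst <- sum((y[te] - mean(y[te]))^2)
    if (sst == 0) return(NA_real_)
    1 - sse / sst
  }, numeric(1))
  m <- mean(fold_r2, na.rm = TRUE)
  list(mean = m, sd = stats::sd(fold_r2, na.rm = TRUE),
       fold_r2 = fold_r2, band = r2_band(m))
}

#' Principal-component regression of a TRIMP quantity on CRF_m
#'
#' Ordinary least squares of a coefficient or weighting on the merged
#' fitness score: first order (`y ~ CRF_m`) for the individual
#' coefficients, second order (`y ~ CRF_m + centred CRF_m^2`) for the
#' weightings at fixed dHR. Model fit is summarised by the in-sample R2
#' and the tenfold cross-validated R2 with its effect-size band.
#'
#' @param crf_m merged fitness scores (PC1).
#' @param response per-athlete response (coefficient or weighting).
#' @param order 1 or 2.
#' @param k folds for cross-validation, default 10.
#' @param seed fold-assignment seed.
#' @return list of class `pcr_model`: `order`, `coefficients`
#'   (intercept, beta_pc1, optionally beta_pc1_sq), `r2`, `cv_r2_mean`,
#'   `cv_r2_sd`, `band`.
#' @export
pcr_fit <- function(crf_m, response, order = 1L, k = 10L, seed = 1L) {
  if (!order %in% c(1L, 2L)) stopf("order must be 1 or 2")
  if (length(crf_m) != length(response)) stopf("lengths differ")
  df <- data.frame(y = response, x = crf_m, x2 = (crf_m - mean(crf_m))^2)
  fit <- if (order == 2L) stats::lm(y ~ x + x2, df) else stats::lm(y ~ x, df)
  cf <- stats::coef(fit)
  names(cf) <- c("intercept", "beta_pc1", if (order == 2L) "beta_pc1_sq")
  r2 <- if (stats::var(response) == 0) 0 else
    suppressWarnings(summary(fit)$r.squared)
  cv <- kfold_cv_r2(crf_m, response, order = order, k = k, seed = seed)
  structure(list(order = order, coefficients = cf,
                 r2 = r2,
                 cv_r2_mean = cv$mean, cv_r2_sd = cv$sd, band = cv$band,
                 fit = fit),
            class = "pcr_model")
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("<pcr_model> order %d: R2 %.3f, cv R2 %.3f +/- %.3f (%s)\n",
              x$order, x$r2, x$cv_r2_mean, x$cv_r2_sd, x$band))
  invisible(x)
}

#' Run the full construct-validation table for a cohort
#'
#' Merges the CRF panel into CRF_m and regresses each supplied response
#' on it: first-order models for intercept/slope coefficients, second-
#' order models for the weightings at fixed dHR.
#'
#' @param panel a [crf_panel()].
#' @param responses named list of numeric vectors (one value per
#'   athlete); names starting with `"w_"` are treated as weightings and
#'   fitted second order, everything else first order.
#' @param seed fold seed for cross-validation.
#' @param k folds for cross-validation (default 10, clamped to the cohort
#'   size).
#' @return data.frame with one row per response: order, betas, R2,
#'   cv mean/sd, band; the `pca_result` is attached as an attribute.
#' @export
validate_cohort <- function(panel, responses, seed = 1L, k = 10L) {
  pca <- pca_crfm(panel)
  k <- min(k, length(pca$crf_m))
  rows <- lapply(names(responses), function(nm) {
    ord <- if (startsWith(nm, "w_")) 2L else 1L
    m <- pcr_fit(pca$crf_m, responses[[nm]], order = ord, k = k, seed = seed)
    data.frame(response = nm, order = ord,
               beta_pc1 = unname(m$coefficients["beta_pc1"]),
               beta_pc1_sq = if (ord == 2L) unname(m$coefficients["beta_pc1_sq"]) else NA_real_,
               r2 = m$r2, cv_r2_mean = m$cv_r2_mean, cv_r2_sd = m$cv_r2_sd,
               band = m$band)
  })
  out <- do.call(rbind, rows)
  attr(out, "pca") <- pca
  out
}
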