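# Independent least-squares oracle: normal equations via pseudo-inverse.
ols_oracle <- function(X, y) as.numeric(MASS::ginv(crossprod(X)) %*%
                                          crossprod(X, y))

test_that("fit_ols matches the pseudo-inverse oracle on random instances", {
  set.seed(71)
  for (rep in 1:10) {
    n <- 50
    k <- sample(2:6, 1)
    X <- cbind(1, matrix(rnorm(n * (k - 1)), n))
    colnames(X) <- paste0("t", seq_len(k))
    y <- X %*% rnorm(k) + rnorm(n)
    f <- fit_ols(X, y)
    expect_equal(unname(coef(f)), ols_oracle(X, y), tolerance = 1e-8)
  }
})

test_that("noise-free and orthogonal limits behave exactly", {
  x <- seq(0, 10, length.out = 30)
  f <- fit_ols(cbind(alpha = 1, slope = x), 3 + 0.5 * x)
  expect_equal(unname(coef(f)), c(3, 0.5), tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  # exactly-zero RSS trips the AIC guard
  expect_warning(
    fz <- fit_ols(matrix(1, 10, 1, dimnames = list(NULL, "alpha")),
                  rep(0, 10)),
    "-Inf")
  expect_identical(fz$aic, -Inf)
  # response orthogonal to the (centered) predictor: slope 0, r2 0
  set.seed(72)
  x2 <- rnorm(100)
  y2 <- rnorm(100)
  y2 <- residuals(lm(y2 ~ x2))  # enforce orthogonality
  f2 <- fit_ols(cbind(alpha = 1, slope = x2 - mean(x2)), y2)
  expect_equal(unname(coef(f2))[2], 0, tolerance = 1e-10)
  expect_equal(f2$r2, 0, tolerance = 1e-10)
})

test_that("rank deficiency errors name the collinear terms", {
  x <- rnorm(20)
  X <- cbind(a = 1, b = x, c = 2 * x)
  expect_error(fit_ols(X, rnorm(20)), "collinear.*c")
  expect_error(fit_ols(X[1:3, ], rnorm(3)), "at least")
})

test_that("design matrices have the spec'd shape per model", {
  land <- small_landscape(n_pix = 12, n_years = 8, seed = 51)
  anom <- compute_anomalies(land$panel)
  clim <- compute_climatology(land$panel)
  d1 <- build_design(anom, clim, legacy_model("eq1"))
  expect_identical(colnames(d1$X), c("alpha", "sigma"))
  d2 <- build_design(anom, clim, legacy_model("eq2"))
  expect_identical(colnames(d2$X), c("alpha", "sigma", "tau"))
  # first-year rows (no lag) excluded from lag designs only
  expect_equal(nrow(d2$X), nrow(d1$X) - length(unique(anom$pixel_id)))
  # per-ecoregion cell-means coding: one intercept + slope per ecoregion
  d5 <- build_design(anom, clim, legacy_model("eq5"))
  expect_equal(ncol(d5$X), 4 * 5)
  expect_equal(sum(startsWith(colnames(d5$X), "delta:")), 5L)
  d3 <- build_design(anom, clim, legacy_model("eq3"))
  expect_equal(ncol(d3$X), 5 * 5)
  expect_true(all(c("omega:cold_deserts", "theta:hot_deserts") %in%
                    colnames(d3$X)))
  # eq3/eq4 need climatologies
  expect_error(build_design(anom, NULL, legacy_model("eq3")),
               "climatolog")
})

test_that("residuals are orthogonal to every design column", {
  land <- small_landscape(n_pix = 20, n_years = 12, seed = 52)
  anom <- compute_anomalies(land$panel)
  clim <- compute_climatology(land$panel)
  for (m in c("eq1", "eq2", "eq5")) {
    d <- build_design(anom, clim, legacy_model(m))
    f <- fit_ols(d, spec_name = m)
    Xu <- scale(d$X, center = FALSE,
                scale = sqrt(colSums(d$X^2)))  # unit-scaled columns
    expect_lt(max(abs(crossprod(Xu, residuals(f)))), 1e-6)
  }
})

test_that("nesting monotonicity: adding the lag never lowers R2", {
  land <- small_landscape(n_pix = 25, n_years = 15, seed = 53)
  anom <- compute_anomalies(land$panel)
  clim <- compute_climatology(land$panel)
  lagged <- anom[complete.cases(anom["lag_npp_dev"]), ]
  f1 <- fit_legacy(lagged, clim, "eq1")
  f2 <- fit_legacy(lagged, clim, "eq2")
  expect_gte(f2$r2, f1$r2)
  cmp <- compare_models(f1, f2)
  expect_equal(cmp$delta[cmp$metric == "r2"], f2$r2 - f1$r2)
})

test_that("AIC follows the documented Gaussian convention", {
  # construct nested fits on identical rows where the larger model
  # halves the RSS with exactly one extra term
  set.seed(54)
  n <- 100
  x1 <- rnorm(n)
  Q <- qr.Q(qr(cbind(1, x1, rnorm(n), rnorm(n))))
  u1 <- Q[, 3]; u2 <- Q[, 4]        # orthonormal, orthogonal to {1, x1}
  y <- 3 * x1 + u1 + u2             # RSS under {1, x1} is exactly 2
  fa <- fit_ols(cbind(a = 1, b = x1), y)
  fb <- fit_ols(cbind(a = 1, b = x1, c = u1), y)  # removes |u1|^2 = 1
  expect_equal(fa$rss, 2, tolerance = 1e-10)
  expect_equal(fb$rss, 1, tolerance = 1e-10)
  expect_equal(fa$aic, n * log(2 / n) + 2 * 3, tolerance = 1e-8)
  # one extra term halving RSS: delta AIC = n log(1/2) + 2
  expect_equal(fb$aic - fa$aic, n * log(0.5) + 2, tolerance = 1e-8)
  # identical RSS with one extra term would add exactly +2 by the formula
  same <- compare_models(fa, fa)
  expect_true(all(same$delta == 0))
})

test_that("model comparison refuses mismatched row sets", {
  land <- small_landscape(n_pix = 10, n_years = 8, seed = 55)
  anom <- compute_anomalies(land$panel)
  clim <- compute_climatology(land$panel)
  f1 <- fit_legacy(anom, clim, "eq1")           # keeps first years
  f2 <- fit_legacy(anom, clim, "eq2")           # drops them
  expect_error(compare_models(f1, f2), "different row sets")
})

test_that("Durbin-Watson matches hand arithmetic and the single-series oracle", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3.0)
  # single series vs lmtest::dwtest on the same residuals
  set.seed(56)
  x <- rnorm(60)
  y <- 1 + 0.5 * x + rnorm(60)
  m <- lm(y ~ x)
  dw_ref <- unname(lmtest::dwtest(m)$statistic)
  expect_equal(durbin_watson(residuals(m)), dw_ref, tolerance = 1e-10)
  # within-pixel differencing only: two groups, no cross-boundary term
  e <- c(1, 2, 4, 10, 11, 13)
  g <- c(1, 1, 1, 2, 2, 2)
  manual <- (sum(diff(e[1:3])^2) + sum(diff(e[4:6])^2)) / sum(e^2)
  expect_equal(durbin_watson(e, g), manual)
  expect_error(durbin_watson(1, 1), "2\\+ residuals")
})

test_that("predict, simulate and accessors are coherent", {
  land <- small_landscape(n_pix = 10, n_years = 10, seed = 57)
  anom <- compute_anomalies(land$panel)
  clim <- compute_climatology(land$panel)
  f <- fit_legacy(anom, clim, "eq2")
  expect_equal(predict(f), fitted(f))
  expect_equal(unname(predict(f, anom, clim)), unname(fitted(f)))
  expect_equal(nobs(f), f$n_obs)
  expect_equal(AIC(f), f$aic)
  sim <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(f$n_obs, 2L))
  expect_output(print(summary(f)), "block bootstrap")
})

test_that("lagged NPP outpredicts lagged weather as the legacy proxy", {
  land <- small_landscape(n_pix = 60, n_years = 36, seed = 58)
  anom <- compute_anomalies(land$panel)
  clim <- compute_climatology(land$panel)
  need <- c("lag_npp_dev", "lag_ppt_dev", "lag_temp_dev")
  common <- anom[complete.cases(anom[need]), ]
  f_npp <- fit_legacy(common, clim, "eq2")
  f_ppt <- fit_legacy(common, clim, "lag_ppt")
  f_tmp <- fit_legacy(common, clim, "lag_temp")
  expect_gt(f_npp$r2, f_ppt$r2)
  expect_gt(f_npp$r2, f_tmp$r2)
  expect_lt(f_npp$aic, f_ppt$aic)
  # under the generator the weather-lag coefficients carry no signal
  expect_lt(abs(coef(f_tmp)[["tau"]]), 0.5)
})
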