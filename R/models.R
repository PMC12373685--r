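# Lag-regression model family: design construction, OLS fitting,
# R2 / AIC / Durbin-Watson diagnostics, model comparison.

.legacy_model_names <- c("eq1", "eq2", "eq3", "eq4", "eq5",
                         "lag_ppt", "lag_temp")

#' Specify a legacy-effect model structure
#'
#' The model family, in increasing structure (all on anomaly series):
#' \describe{
#'   \item{eq1}{`npp_dev ~ alpha + sigma * ppt_dev` — current-year PPT
#'     sensitivity only.}
#'   \item{eq2}{adds `tau * lag_npp_dev` — the pooled lag-1 NPP legacy
#'     model.}
#'   \item{eq3}{per-ecoregion intercepts (beta), PPT slopes (gamma), MAP
#'     main effects (omega), lag slopes (theta) and lag x MAP
#'     interactions (delta) — how the legacy coefficient varies with
#'     mean annual precipitation.}
#'   \item{eq4}{as eq3 with the herbaceous NPP fraction in place of
#'     MAP.}
#'   \item{eq5}{per-ecoregion intercepts, PPT slopes, lag slopes and
#'     lag x current-PPT interactions — how legacy effects modify PPT
#'     sensitivity.}
#'   \item{lag_ppt, lag_temp}{eq2 with the lagged PPT (or temperature)
#'     anomaly as the legacy proxy instead of lagged NPP.}
#' }
#' Per-ecoregion models use cell-means coding: the ecoregion indicator
#' columns are the intercepts and every ecoregion carries its own slope
#' for each interaction term, so each coefficient is directly that
#' ecoregion's effect (no shared baseline). Covariates are uncentered by
#' default so interaction coefficients are on per-mm and per-fraction
#' scales; `center = TRUE` centers MAP/HERB at their panel means.
#'
#' @param name One of `"eq1"`, `"eq2"`, `"eq3"`, `"eq4"`, `"eq5"`,
#'   `"lag_ppt"`, `"lag_temp"`.
#' @param standardize Fit on per-pixel SD-standardized anomalies.
#' @param center Center MAP / herbaceous-fraction covariates.
#' @return An object of class `legacy_spec`.
#' @export
#' @examples
#' legacy_model("eq2")
legacy_model <- function(name, standardize = FALSE, center = FALSE) {
  name <- match.arg(name, .legacy_model_names)
  structure(list(name = name, standardize = standardize, center = center),
            class = "legacy_spec")
}

#' @export
print.legacy_spec <- function(x, ...) {
  cat("legacy model spec '", x$name, "'",
      if (x$standardize) " (standardized anomalies)",
      if (x$center) " (centered covariates)", "\n", sep = "")
  invisible(x)
}

# Columns each spec needs in the anomaly records (beyond npp_dev).
.spec_predictors <- function(name) {
  switch(name,
    eq1 = "ppt_dev",
    eq2 = c("ppt_dev", "lag_npp_dev"),
    lag_ppt = c("ppt_dev", "lag_ppt_dev"),
    lag_temp = c("ppt_dev", "lag_temp_dev"),
    eq3 = c("ppt_dev", "lag_npp_dev", "map_mm"),
    eq4 = c("ppt_dev", "lag_npp_dev", "herb_frac"),
    eq5 = c("ppt_dev", "lag_npp_dev"))
}

#' Build the response and design matrix for a model spec
#'
#' Joins pixel covariates (MAP, herbaceous fraction) onto the anomaly
#' records where the spec needs them, drops rows with any missing
#' predictor (first years lack lags) and assembles the design matrix.
#' Coefficients are named by their role: `alpha` (intercept), `sigma`
#' (current-PPT slope), `tau` (lag slope) for the pooled models;
#' `beta:<eco>`, `gamma:<eco>`, `omega:<eco>`, `theta:<eco>`,
#' `delta:<eco>` for the per-ecoregion models.
#'
#' @param records Anomaly records from [compute_anomalies()].
#' @param climatologies Per-pixel climatology (needed for eq3/eq4 and
#'   for standardization bookkeeping); may be `NULL` for eq1/eq2/eq5.
#' @param spec A [legacy_model()] spec.
#' @return List with `y` (response), `X` (design matrix), `rows`
#'   (data.frame of `pixel_id`, `water_year` for the retained rows, in
#'   order) and `n_dropped`.
#' @export
build_design <- function(records, climatologies = NULL, spec) {
  stopifnot(inherits(spec, "legacy_spec"))
  if (spec$standardize) records <- standardize_anomalies(records)
  need <- .spec_predictors(spec$name)

  pixel_covs <- intersect(c("map_mm", "herb_frac"), need)
  if (length(pixel_covs)) {
    if (is.null(climatologies))
      stop("spec '", spec$name, "' needs per-pixel climatologies")
    i <- match(records$pixel_id, climatologies$pixel_id)
    if (anyNA(i)) stop("climatology does not cover every pixel")
    for (v in pixel_covs) {
      records[[v]] <- climatologies[[v]][i]
      if (spec$center)
        records[[v]] <- records[[v]] - mean(climatologies[[v]], na.rm = TRUE)
    }
  }

  keep <- stats::complete.cases(records[c("npp_dev", need)])
  n_dropped <- sum(!keep)
  rec <- records[keep, , drop = FALSE]
  if (!nrow(rec)) stop("no usable rows after dropping missing predictors")

  per_eco <- spec$name %in% c("eq3", "eq4", "eq5")
  if (!per_eco) {
    lagcol <- switch(spec$name, eq2 = "lag_npp_dev",
                     lag_ppt = "lag_ppt_dev", lag_temp = "lag_temp_dev",
                     NULL)
    X <- cbind(alpha = rep(1, nrow(rec)), sigma = rec$ppt_dev)
    if (!is.null(lagcol)) X <- cbind(X, tau = rec[[lagcol]])
  } else {
    eco <- factor(rec$ecoregion)
    levs <- levels(eco)
    counts <- table(eco)
    # cell-means coding: one indicator and one slope set per ecoregion
    D <- sapply(levs, function(l) as.numeric(eco == l))
    colnames(D) <- paste0("beta:", levs)
    G <- D * rec$ppt_dev
    colnames(G) <- paste0("gamma:", levs)
    Th <- D * rec$lag_npp_dev
    colnames(Th) <- paste0("theta:", levs)
    X <- switch(spec$name,
      eq3 = {
        Om <- D * rec$map_mm
        colnames(Om) <- paste0("omega:", levs)
        De <- D * rec$lag_npp_dev * rec$map_mm
        colnames(De) <- paste0("delta:", levs)
        cbind(D, G, Om, Th, De)
      },
      eq4 = {
        Om <- D * rec$herb_frac
        colnames(Om) <- paste0("omega:", levs)
        De <- D * rec$lag_npp_dev * rec$herb_frac
        colnames(De) <- paste0("delta:", levs)
        cbind(D, G, Om, Th, De)
      },
      eq5 = {
        De <- D * rec$lag_npp_dev * rec$ppt_dev
        colnames(De) <- paste0("delta:", levs)
        cbind(D, G, Th, De)
      })
    short <- counts[counts < ncol(X) / length(levs)]
    if (length(short))
      stop("ecoregion(s) with fewer rows than per-ecoregion terms: ",
           paste(names(short), collapse = ", "))
  }
  list(y = rec$npp_dev, X = X,
       rows = data.frame(pixel_id = rec$pixel_id,
                         water_year = rec$water_year),
       n_dropped = n_dropped)
}

#' Ordinary least squares with legacy-model bookkeeping
#'
#' Fits `y = X b + e` by QR least squares and returns a `legacy_fit`
#' carrying coefficients, R-squared (about the response mean), the
#' Gaussian AIC under the documented convention, residuals in input row
#' order and, when `rows` identify pixels and years, the panel
#' Durbin-Watson statistic.
#'
#' @param design Design list from [build_design()], or a plain numeric
#'   matrix (then `response` is required).
#' @param response Response vector when `design` is a matrix.
#' @param spec_name Optional label stored on the fit.
#' @return Object of class `legacy_fit`.
#' @details AIC is computed as `n * log(RSS / n) + 2 * (k + 1)` with `k`
#'   regression coefficients plus one variance parameter. Only AIC
#'   differences between models fit to the same rows are meaningful;
#'   percentage changes in AIC depend on this additive convention and
#'   are labelled as such by [compare_models()]. A zero-RSS fit gets
#'   `aic = -Inf` with a warning.
#' @export
#' @examples
#' x <- 1:20
#' f <- fit_ols(cbind(alpha = 1, slope = x), 3 + 0.5 * x)
#' coef(f)
fit_ols <- function(design, response = NULL, spec_name = NULL) {
  if (is.matrix(design)) {
    if (is.null(response)) stop("response required with a matrix design")
    design <- list(y = response, X = design, rows = NULL, n_dropped = 0L)
  }
  X <- design$X; y <- design$y
  n <- length(y); k <- ncol(X)
  if (n < k + 1L)
    stop("need at least ", k + 1L, " rows to fit ", k, " coefficients")
  fit <- lm.fit(X, y)
  if (fit$rank < k) {
    aliased <- colnames(X)[fit$qr$pivot[(fit$rank + 1L):k]]
    stop("rank-deficient design; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  res <- as.numeric(fit$residuals)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  aic <- if (rss > 0) n * log(rss / n) + 2 * (k + 1) else {
    warning("zero residual sum of squares; AIC set to -Inf")
    -Inf
  }
  dw <- if (!is.null(design$rows))
    durbin_watson(res, design$rows$pixel_id, design$rows$water_year)
  else NA_real_
  structure(list(coefficients = setNames(as.numeric(fit$coefficients),
                                         colnames(X)),
                 r2 = r2, aic = aic, dw = dw, n_obs = n, k = k,
                 rss = rss, residuals = res,
                 fitted = as.numeric(fit$fitted.values),
                 rows = design$rows, n_dropped = design$n_dropped,
                 spec_name = spec_name),
            class = "legacy_fit")
}

#' Fit a legacy-effect model to anomaly records
#'
#' The central fitting function: builds the design for `spec` from the
#' anomaly records (and climatologies where the spec needs pixel
#' covariates) and fits it by OLS. Uncertainty for these models comes
#' from the spatial block bootstrap ([run_bootstrap()]), not from
#' model-based standard errors.
#'
#' @inheritParams build_design
#' @param spec A [legacy_model()] spec or a model name string.
#' @return A `legacy_fit`; see [fit_ols()].
#' @export
#' @examples
#' land <- generate_landscape(synthetic_config(
#'   n_pixels_per_ecoregion = 20, n_years = 12, seed = 42))
#' anom <- compute_anomalies(land$panel)
#' fit_legacy(anom, spec = "eq2")
fit_legacy <- function(records, climatologies = NULL, spec = "eq2") {
  if (is.character(spec)) spec <- legacy_model(spec)
  d <- build_design(records, climatologies, spec)
  fit_ols(d, spec_name = spec$name)
}

#' Panel Durbin-Watson statistic
#'
#' `DW = sum((e_t - e_(t-1))^2) / sum(e_t^2)` with first differences
#' taken only within pixels (each pixel's residuals ordered by year; no
#' differencing across pixel boundaries). Values near 2 indicate no
#' lag-1 autocorrelation of residuals; below 2, positive
#' autocorrelation.
#'
#' @param residuals Numeric residual vector.
#' @param pixel_id Grouping vector (same length); `NULL` treats the
#'   input as a single series.
#' @param water_year Ordering within groups; `NULL` keeps input order.
#' @return The statistic, in \[0, 4\].
#' @export
#' @examples
#' durbin_watson(c(1, -1, 1, -1))  # 3
durbin_watson <- function(residuals, pixel_id = NULL, water_year = NULL) {
  if (is.null(pixel_id)) pixel_id <- rep(1L, length(residuals))
  if (!is.null(water_year)) {
    ord <- order(pixel_id, water_year)
    residuals <- residuals[ord]; pixel_id <- pixel_id[ord]
  }
  groups <- split(residuals, pixel_id)
  if (all(lengths(groups) < 2L))
    stop("Durbin-Watson needs at least one group with 2+ residuals")
  num <- sum(vapply(groups, function(e)
    if (length(e) >= 2L) sum(diff(e)^2) else 0, numeric(1)))
  num / sum(residuals^2)
}

#' Compare two fits on identical rows
#'
#' Differences `b - a` in R-squared and AIC, plus percentage changes.
#' Refuses the comparison when the two fits did not use the same
#' (pixel, water-year) rows, since R2/AIC are only comparable on a
#' common response.
#'
#' @param fit_a,fit_b `legacy_fit` objects.
#' @return data.frame with `metric`, `a`, `b`, `delta`, `pct_change`.
#'   Percent change in AIC depends on the additive AIC convention and
#'   is reported for completeness only.
#' @export
compare_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "legacy_fit"), inherits(fit_b, "legacy_fit"))
  ra <- fit_a$rows; rb <- fit_b$rows
  if (is.null(ra) || is.null(rb))
    same <- fit_a$n_obs == fit_b$n_obs
  else {
    ka <- paste(ra$pixel_id, ra$water_year)
    kb <- paste(rb$pixel_id, rb$water_year)
    same <- length(ka) == length(kb) && setequal(ka, kb)
  }
  if (!same)
    stop("fits use different row sets; refit both on common rows ",
         "(drop first-year rows from every model in a comparison set)")
  data.frame(
    metric = c("r2", "aic"),
    a = c(fit_a$r2, fit_a$aic),
    b = c(fit_b$r2, fit_b$aic),
    delta = c(fit_b$r2 - fit_a$r2, fit_b$aic - fit_a$aic),
    pct_change = c(100 * (fit_b$r2 - fit_a$r2) / abs(fit_a$r2),
                   100 * (fit_b$aic - fit_a$aic) / abs(fit_a$aic))
  )
}

# ---- legacy_fit methods ----

#' @export
print.legacy_fit <- function(x, digits = 4, ...) {
  cat("Legacy-effect OLS fit",
      if (!is.null(x$spec_name)) paste0(" (", x$spec_name, ")"), "\n",
      sep = "")
  cat("  n = ", x$n_obs, ", terms = ", x$k,
      ", dropped rows = ", x$n_dropped, "\n", sep = "")
  cat("  R2 = ", signif(x$r2, digits), ", AIC = ", signif(x$aic, digits),
      if (!is.na(x$dw)) paste0(", DW = ", signif(x$dw, digits)), "\n",
      sep = "")
  cat("Coefficients:\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.legacy_fit <- function(object, ...) object$coefficients

#' @export
residuals.legacy_fit <- function(object, ...) object$residuals

#' @export
fitted.legacy_fit <- function(object, ...) object$fitted

#' @export
nobs.legacy_fit <- function(object, ...) object$n_obs

#' AIC of a legacy fit (documented convention)
#'
#' Returns `n * log(RSS/n) + 2 * (k + 1)`; see [fit_ols()]. This fixed
#' convention (Gaussian profile likelihood without the `n log(2 pi) + n`
#' constant) is used for every model comparison in the package, so AIC
#' differences match those of the standard definition exactly.
#'
#' @param object A `legacy_fit`.
#' @param ... Ignored.
#' @param k Ignored (signature compatibility).
#' @export
AIC.legacy_fit <- function(object, ..., k = 2) object$aic

#' @export
summary.legacy_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.legacy_fit")
}

#' @export
print.summary.legacy_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nResidual SD: ",
      signif(sqrt(f$rss / (f$n_obs - f$k)), digits),
      " (df = ", f$n_obs - f$k, ")\n", sep = "")
  cat("Note: coefficient uncertainty is assessed by the stratified\n",
      "spatial block bootstrap (run_bootstrap), not model-based SEs.\n",
      sep = "")
  invisible(x)
}

#' Predict from a legacy fit
#'
#' @param object A `legacy_fit` produced by [fit_legacy()].
#' @param newdata Anomaly records (plus climatologies via `climatologies`
#'   for eq3/eq4); omitted returns fitted values.
#' @param climatologies Climatology table for specs that need it.
#' @param ... Ignored.
#' @return Numeric predictions for the usable rows of `newdata`.
#' @export
predict.legacy_fit <- function(object, newdata = NULL,
                               climatologies = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.null(object$spec_name))
    stop("fit carries no spec; predict needs a fit from fit_legacy()")
  d <- build_design(newdata, climatologies, legacy_model(object$spec_name))
  as.numeric(d$X %*% object$coefficients)
}

#' Simulate responses from a fitted legacy model
#'
#' Parametric simulation: fitted values plus Gaussian noise with the
#' residual SD.
#'
#' @param object A `legacy_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Ignored.
#' @return data.frame with `nsim` columns.
#' @export
simulate.legacy_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(object$rss / (object$n_obs - object$k))
  out <- replicate(nsim, object$fitted + rnorm(object$n_obs, 0, s))
  as.data.frame(out)
}

#' Residual diagnostics plot
#'
#' Residuals against fitted values and a residual histogram.
#'
#' @param x A `legacy_fit`.
#' @param ... Passed to the scatter plot.
#' @export
plot.legacy_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot.default(x$fitted, x$residuals, xlab = "fitted",
               ylab = "residuals",
               main = paste("Residuals", x$spec_name %||% ""), ...)
  abline(h = 0, lty = 2)
  hist(x$residuals, main = "Residual distribution", xlab = "residual")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
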