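# Stratified spatial block bootstrap: resample whole pixels (all their
# years) within ecoregion x wet/dry-side-of-MAP strata, refit, and
# summarize metric distributions.

#' Stratify pixels for the spatial block bootstrap
#'
#' Each pixel is assigned to exactly one stratum keyed by its ecoregion
#' and by whether its MAP falls below or at-or-above the mean MAP of
#' that ecoregion's pixels. An ecoregion with fewer than two pixels
#' collapses to a single stratum with a warning.
#'
#' @param climatologies Per-pixel climatology from
#'   [compute_climatology()] (needs `pixel_id`, `ecoregion`, `map_mm`).
#' @return data.frame with `pixel_id`, `ecoregion`, `stratum`.
#' @export
stratify_pixels <- function(climatologies) {
  stopifnot(all(c("pixel_id", "ecoregion", "map_mm") %in%
                  names(climatologies)))
  eco <- climatologies$ecoregion
  eco_mean <- ave(climatologies$map_mm, eco, FUN = mean)
  n_eco <- ave(rep(1L, nrow(climatologies)), eco, FUN = sum)
  side <- ifelse(climatologies$map_mm >= eco_mean, "above", "below")
  if (any(n_eco < 2L)) {
    warning("ecoregion(s) with < 2 pixels fall back to a single stratum: ",
            paste(unique(eco[n_eco < 2L]), collapse = ", "))
    side[n_eco < 2L] <- "all"
  }
  data.frame(pixel_id = climatologies$pixel_id, ecoregion = eco,
             stratum = paste(eco, side, sep = "|"),
             stringsAsFactors = FALSE)
}

#' Draw one bootstrap iteration's pixel sample
#'
#' From each stratum, `round(fraction * stratum size)` pixels (never
#' fewer than 1) are drawn without replacement using the current RNG
#' state (set `replace = TRUE` for within-iteration replacement).
#' Iterations are independent redraws.
#'
#' @param strata Output of [stratify_pixels()].
#' @param fraction Sampling fraction in (0, 1\].
#' @param replace Sample with replacement within the iteration.
#' @return Vector of sampled pixel ids (with duplicates when
#'   `replace = TRUE`).
#' @export
sample_iteration <- function(strata, fraction = 0.001, replace = FALSE) {
  stopifnot(fraction > 0, fraction <= 1)
  groups <- split(strata$pixel_id, strata$stratum)
  if (any(lengths(groups) == 0L)) stop("empty stratum")
  unlist(lapply(groups, function(ids) {
    m <- max(1L, round(fraction * length(ids)))
    ids[sample.int(length(ids), m, replace = replace)]
  }), use.names = FALSE)
}

# Deterministic per-iteration seeds from one master seed, so iteration
# results do not depend on execution order.
.iteration_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the stratified spatial block bootstrap for one model spec
#'
#' Per iteration: draw the stratified pixel sample, pool those pixels'
#' full anomaly series, fit `spec`, and record R-squared, AIC and every
#' coefficient. Distributions are summarized by their mean and
#' percentile confidence interval; a metric is flagged significant when
#' its CI excludes zero. A master seed spawns one sub-seed per
#' iteration, so results are bit-reproducible and independent of
#' execution order. Iterations whose design is rank deficient (possible
#' in tiny samples) are redrawn and counted; more than 5% redraws
#' aborts.
#'
#' @param records Anomaly records ([compute_anomalies()]).
#' @param climatologies Per-pixel climatology (strata and eq3/eq4
#'   covariates).
#' @param spec A [legacy_model()] or model name.
#' @param n_iterations Bootstrap iterations (study default 1000).
#' @param fraction Stratum sampling fraction (study default 0.001).
#' @param ci_level Confidence level for percentile intervals (default
#'   0.99).
#' @param seed Master seed (required, for reproducibility).
#' @param replace Within-iteration sampling with replacement (default
#'   `FALSE`; at 0.1% sampling the two conventions are nearly
#'   identical).
#' @return Object of class `legacy_boot`: `draws` (one row per
#'   iteration), `summaries` (per metric: mean, ci_lo, ci_hi,
#'   significant), `spec_name`, `n_iterations`, `ci_level`, `seed`,
#'   `n_redrawn`.
#' @export
run_bootstrap <- function(records, climatologies, spec = "eq2",
                          n_iterations = 1000, fraction = 0.001,
                          ci_level = 0.99, seed, replace = FALSE) {
  if (is.character(spec)) spec <- legacy_model(spec)
  strata <- stratify_pixels(climatologies)
  seeds <- .iteration_seeds(seed, n_iterations)
  draws <- vector("list", n_iterations)
  n_redrawn <- 0L
  for (i in seq_len(n_iterations)) {
    set.seed(seeds[i])
    repeat {
      ids <- sample_iteration(strata, fraction, replace)
      rec <- records[records$pixel_id %in% ids, , drop = FALSE]
      fit <- tryCatch(fit_legacy(rec, climatologies, spec),
                      error = function(e) e)
      if (!inherits(fit, "error")) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 0.05 * n_iterations)
        stop("more than 5% of bootstrap iterations redrawn; last error: ",
             conditionMessage(fit))
    }
    draws[[i]] <- c(r2 = fit$r2, aic = fit$aic, fit$coefficients)
  }
  draws <- as.data.frame(do.call(rbind, draws))
  .finish_boot(draws, spec$name, n_iterations, ci_level, seed, n_redrawn)
}

.finish_boot <- function(draws, spec_name, n_iterations, ci_level, seed,
                         n_redrawn = 0L) {
  alpha <- (1 - ci_level) / 2
  summaries <- do.call(rbind, lapply(names(draws), function(m) {
    v <- draws[[m]]
    ci <- quantile(v, c(alpha, 1 - alpha), names = FALSE, type = 7)
    data.frame(metric = m, mean = mean(v), ci_lo = ci[1], ci_hi = ci[2],
               significant = ci[1] > 0 | ci[2] < 0,
               stringsAsFactors = FALSE)
  }))
  rownames(summaries) <- NULL
  structure(list(draws = draws, summaries = summaries,
                 spec_name = spec_name, n_iterations = n_iterations,
                 ci_level = ci_level, seed = seed, n_redrawn = n_redrawn),
            class = "legacy_boot")
}

#' Bootstrap distribution of differences between two nested specs
#'
#' Per iteration both specs are fit to the SAME sampled pixels and the
#' same rows: rows usable by both models (in particular, first-year
#' rows lacking a lag are dropped from both, including the smaller
#' model). The distributions of `delta_r2 = r2_b - r2_a` and
#' `delta_aic = aic_b - aic_a` are summarized as in [run_bootstrap()];
#' the model improvement is significant when the CI of the difference
#' excludes zero.
#'
#' @inheritParams run_bootstrap
#' @param spec_a,spec_b Model specs (or names); `b` is the larger model.
#' @return A `legacy_boot` whose draws are `delta_r2`, `delta_aic`,
#'   `r2_a`, `r2_b`, `aic_a`, `aic_b`.
#' @export
paired_model_deltas <- function(records, climatologies,
                                spec_a = "eq1", spec_b = "eq2",
                                n_iterations = 1000, fraction = 0.001,
                                ci_level = 0.99, seed, replace = FALSE) {
  if (is.character(spec_a)) spec_a <- legacy_model(spec_a)
  if (is.character(spec_b)) spec_b <- legacy_model(spec_b)
  strata <- stratify_pixels(climatologies)
  need <- unique(c("npp_dev", .spec_predictors(spec_a$name),
                   .spec_predictors(spec_b$name)))
  need <- setdiff(need, c("map_mm", "herb_frac"))  # joined, never missing
  seeds <- .iteration_seeds(seed, n_iterations)
  draws <- vector("list", n_iterations)
  n_redrawn <- 0L
  for (i in seq_len(n_iterations)) {
    set.seed(seeds[i])
    repeat {
      ids <- sample_iteration(strata, fraction, replace)
      rec <- records[records$pixel_id %in% ids, , drop = FALSE]
      rec <- rec[stats::complete.cases(rec[need]), , drop = FALSE]
      fits <- tryCatch(list(a = fit_legacy(rec, climatologies, spec_a),
                            b = fit_legacy(rec, climatologies, spec_b)),
                       error = function(e) e)
      if (!inherits(fits, "error")) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 0.05 * n_iterations)
        stop("more than 5% of bootstrap iterations redrawn; last error: ",
             conditionMessage(fits))
    }
    draws[[i]] <- c(delta_r2 = fits$b$r2 - fits$a$r2,
                    delta_aic = fits$b$aic - fits$a$aic,
                    r2_a = fits$a$r2, r2_b = fits$b$r2,
                    aic_a = fits$a$aic, aic_b = fits$b$aic)
  }
  draws <- as.data.frame(do.call(rbind, draws))
  .finish_boot(draws, paste(spec_b$name, "-", spec_a$name),
               n_iterations, ci_level, seed, n_redrawn)
}

#' @export
print.legacy_boot <- function(x, digits = 4, ...) {
  cat("Stratified spatial block bootstrap: ", x$spec_name, "\n", sep = "")
  cat("  iterations = ", x$n_iterations, ", CI level = ", x$ci_level,
      ", seed = ", x$seed,
      if (x$n_redrawn) paste0(", redrawn = ", x$n_redrawn), "\n", sep = "")
  s <- x$summaries
  s[c("mean", "ci_lo", "ci_hi")] <- lapply(s[c("mean", "ci_lo", "ci_hi")],
                                           signif, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
summary.legacy_boot <- function(object, ...) object$summaries

#' Density plot of bootstrap draws for one metric
#'
#' @param x A `legacy_boot`.
#' @param metric Column of `x$draws` to plot (default the first
#'   coefficient after r2/aic).
#' @param ... Passed to `plot`.
#' @export
plot.legacy_boot <- function(x, metric = NULL, ...) {
  if (is.null(metric))
    metric <- setdiff(names(x$draws), c("r2", "aic"))[1]
  d <- density(x$draws[[metric]])
  plot.default(d$x, d$y / max(d$y), type = "l", xlab = metric,
               ylab = "scaled density",
               main = paste("Bootstrap distribution:", metric), ...)
  abline(v = 0, lty = 2)
  invisible(x)
}
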