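# Pixel-specific lag regressions, percentile trimming, coefficient
# rasters (the legacy-coefficient map).

#' Fit the lag model independently to every pixel
#'
#' For each pixel, OLS of `npp_dev` on an intercept, `ppt_dev` and
#' `lag_npp_dev` over that pixel's own years (first year dropped for the
#' lag). Pixels with fewer than `min_years` usable years, a constant
#' predictor, or a rank-deficient design are skipped with a reason.
#'
#' @param records Anomaly records from [compute_anomalies()].
#' @param min_years Minimum usable years after lag exclusion (default 5;
#'   guards degenerate inputs — full 35-year series are far above it).
#' @return List with `estimates` (data.frame: `pixel_id`, `tau`,
#'   `sigma`, `alpha`, `r2`, `n_years_used`) and `skipped` (data.frame:
#'   `pixel_id`, `reason`).
#' @export
fit_pixel_lag <- function(records, min_years = 5) {
  pieces <- split(records, records$pixel_id)
  est <- vector("list", length(pieces))
  skip <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    p <- p[order(p$water_year), , drop = FALSE]
    use <- stats::complete.cases(p[c("npp_dev", "ppt_dev", "lag_npp_dev")])
    p <- p[use, , drop = FALSE]
    pid <- if (nrow(p)) p$pixel_id[1] else names(pieces)[i]
    if (nrow(p) < min_years) {
      skip[[i]] <- data.frame(pixel_id = pid, reason = "too_few_years")
      next
    }
    if (sd(p$ppt_dev) == 0 || sd(p$lag_npp_dev) == 0) {
      skip[[i]] <- data.frame(pixel_id = pid, reason = "constant_predictor")
      next
    }
    X <- cbind(alpha = 1, sigma = p$ppt_dev, tau = p$lag_npp_dev)
    f <- tryCatch(fit_ols(X, p$npp_dev), error = function(e) NULL)
    if (is.null(f)) {
      skip[[i]] <- data.frame(pixel_id = pid, reason = "rank_deficient")
      next
    }
    est[[i]] <- data.frame(pixel_id = pid, tau = f$coefficients[["tau"]],
                           sigma = f$coefficients[["sigma"]],
                           alpha = f$coefficients[["alpha"]],
                           r2 = f$r2, n_years_used = f$n_obs)
  }
  list(estimates = do.call(rbind, est[!vapply(est, is.null, logical(1))]),
       skipped = do.call(rbind, skip[!vapply(skip, is.null, logical(1))]))
}

#' Trim a distribution's tails by percentiles
#'
#' Masks values strictly below the `lo_pct` percentile or strictly
#' above the `hi_pct` percentile of the full input. Percentiles use the
#' `p (n + 1)` plotting-position convention with linear interpolation
#' between order statistics (`stats::quantile` type 6); under it the
#' values 1..100 trimmed at (2.5, 97.5) lose exactly {1, 2, 99, 100}.
#'
#' @param values Numeric vector (non-empty).
#' @param lo_pct,hi_pct Percentile bounds in percent (defaults 2.5 and
#'   97.5, the map-display trim).
#' @return List with `values` (retained values), `mask` (logical,
#'   `TRUE` = retained, aligned with the input) and `bounds`.
#' @export
#' @examples
#' trim_percentiles(1:100)$values  # 3..98
trim_percentiles <- function(values, lo_pct = 2.5, hi_pct = 97.5) {
  if (!length(values)) stop("empty input")
  if (lo_pct >= hi_pct) stop("lo_pct must be < hi_pct")
  b <- quantile(values, c(lo_pct, hi_pct) / 100, names = FALSE,
                type = 6, na.rm = TRUE)
  mask <- !is.na(values) & values >= b[1] & values <= b[2]
  list(values = values[mask], mask = mask,
       bounds = c(lo = b[1], hi = b[2]))
}

#' Rasterize per-pixel coefficients onto the panel grid
#'
#' Places per-pixel estimates (e.g. the lag coefficient tau from
#' [fit_pixel_lag()]) onto the regular grid defined by the pixel
#' coordinates. Skipped or trimmed pixels are masked. Optionally writes
#' the grid as an ESRI ASCII raster.
#'
#' @param records data.frame with `pixel_id` and the coefficient column.
#' @param coords data.frame with `pixel_id`, `x`, `y` (e.g. a
#'   climatology table or `landscape$truth` joined to coordinates).
#' @param value Name of the coefficient column (default `"tau"`).
#' @param path Optional output `.asc` path.
#' @return An [ascii_grid()] of the coefficient surface.
#' @export
rasterize_coefficients <- function(records, coords, value = "tau",
                                   path = NULL) {
  stopifnot(value %in% names(records),
            all(c("pixel_id", "x", "y") %in% names(coords)))
  i <- match(records$pixel_id, coords$pixel_id)
  if (anyNA(i)) stop("coordinates missing for some pixels")
  sub <- data.frame(x = coords$x[i], y = coords$y[i])
  sub[[value]] <- records[[value]]
  geo <- .panel_geometry(sub)
  g <- .panel_to_grid(sub, value, geo)
  if (!is.null(path)) write_ascii_grid(g, path)
  g
}
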