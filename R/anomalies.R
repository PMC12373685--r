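# Water-year aggregation, per-pixel climatologies, anomaly series.

#' Aggregate daily weather to water-year annual values
#'
#' The water year labelled Y runs from October 1 of Y-1 through
#' September 30 of Y. Precipitation is summed over the window; daily
#' mean temperature, `(tmin + tmax) / 2` (or a supplied `tmean`), is
#' averaged over it. Water years whose window is not fully covered by
#' the record (series edges) are dropped.
#'
#' @param daily data.frame with a `date` column (Date or parseable
#'   string) plus `ppt_mm` and either `tmean_c` or both `tmin_c` and
#'   `tmax_c`.
#' @return data.frame with `water_year`, `ppt_mm`, `tmean_c`, one row
#'   per complete water year.
#' @export
#' @examples
#' d <- data.frame(date = seq(as.Date("1986-10-01"),
#'                            as.Date("1987-09-30"), by = "day"),
#'                 ppt_mm = 1, tmin_c = 0, tmax_c = 10)
#' water_year_aggregate(d)  # 365 mm, 5 degrees C
water_year_aggregate <- function(daily) {
  stopifnot(is.data.frame(daily), "date" %in% names(daily),
            "ppt_mm" %in% names(daily))
  dates <- as.Date(daily$date)
  if (anyNA(dates)) stop("unparseable dates in daily records")
  if (anyDuplicated(dates)) stop("duplicate dates in daily records")
  if (is.unsorted(dates, strictly = FALSE) && is.unsorted(rev(dates)))
    stop("daily records must be in date order")
  ord <- order(dates)
  daily <- daily[ord, ]; dates <- dates[ord]

  tmean <- if ("tmean_c" %in% names(daily)) daily$tmean_c
           else if (all(c("tmin_c", "tmax_c") %in% names(daily)))
             (daily$tmin_c + daily$tmax_c) / 2
           else stop("need tmean_c or tmin_c + tmax_c")

  mon <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  wy <- ifelse(mon >= 10L, yr + 1L, yr)

  ppt <- tapply(daily$ppt_mm, wy, sum)
  tmn <- tapply(tmean, wy, mean)
  ndays <- tapply(dates, wy, length)
  wys <- as.integer(names(ppt))
  expected <- as.integer(as.Date(sprintf("%d-09-30", wys)) -
                           as.Date(sprintf("%d-10-01", wys - 1L))) + 1L
  complete <- ndays == expected
  data.frame(water_year = wys[complete],
             ppt_mm = as.numeric(ppt[complete]),
             tmean_c = as.numeric(tmn[complete]),
             row.names = NULL)
}

#' Per-pixel long-term climatology
#'
#' Long-term summaries over all available years of each pixel: mean
#' annual precipitation (MAP) and its SD, mean annual temperature, mean
#' and SD of total NPP, the coefficient of variation of NPP, and the
#' herbaceous NPP fraction. SDs use the sample (n-1) convention. The
#' herbaceous fraction is the mean over years of
#' (annual + perennial herbaceous NPP) / (total NPP), excluding years
#' with zero total NPP; the alternative ratio-of-means definition is
#' available via `herb_method = "ratio_of_means"`. A pixel whose NPP is
#' zero in every year gets `herb_frac = NA` with a warning.
#'
#' @param panel Panel data.frame (see [read_panel()]); a pixel needs at
#'   least 3 years.
#' @param herb_method `"mean_of_ratios"` (default) or
#'   `"ratio_of_means"`.
#' @return data.frame with one row per pixel: `pixel_id`, `ecoregion`,
#'   `x`, `y` (when present), `n_years`, `map_mm`, `sd_ppt_mm`,
#'   `mean_temp_c`, `mean_npp`, `sd_npp`, `cv_npp`, `herb_frac`.
#' @export
compute_climatology <- function(panel,
                                herb_method = c("mean_of_ratios",
                                                "ratio_of_means")) {
  herb_method <- match.arg(herb_method)
  .validate_panel_columns(panel)
  total <- panel$npp_annual_herb + panel$npp_perennial_herb +
    panel$npp_shrub + panel$npp_tree
  herb <- panel$npp_annual_herb + panel$npp_perennial_herb

  pid <- panel$pixel_id
  n_years <- tapply(panel$water_year, pid, length)
  if (any(n_years < 3L))
    stop("pixels with fewer than 3 years: ",
         paste(head(names(n_years)[n_years < 3L]), collapse = ", "))

  first <- panel[!duplicated(pid), , drop = FALSE]
  key <- as.character(first$pixel_id)  # tapply orders groups by name
  by_pix <- function(v, f, ...) as.numeric(tapply(v, pid, f, ...)[key])

  frac <- ifelse(total > 0, herb / total, NA_real_)
  herb_frac <- if (herb_method == "mean_of_ratios") {
    by_pix(frac, mean, na.rm = TRUE)
  } else {
    by_pix(herb, sum) / by_pix(total, sum)
  }
  if (anyNA(herb_frac) || any(is.nan(herb_frac))) {
    herb_frac[is.nan(herb_frac)] <- NA_real_
    warning("herbaceous fraction undefined for ",
            sum(is.na(herb_frac)), " all-zero-NPP pixel(s)")
  }

  clim <- data.frame(
    pixel_id = first$pixel_id,
    ecoregion = first$ecoregion,
    n_years = as.integer(n_years[key]),
    map_mm = by_pix(panel$ppt_mm, mean),
    sd_ppt_mm = by_pix(panel$ppt_mm, sd),
    mean_temp_c = by_pix(panel$tmean_c, mean),
    mean_npp = by_pix(total, mean),
    sd_npp = by_pix(total, sd),
    herb_frac = herb_frac,
    stringsAsFactors = FALSE
  )
  clim$cv_npp <- ifelse(clim$mean_npp > 0, clim$sd_npp / clim$mean_npp,
                        NA_real_)
  if (all(c("x", "y") %in% names(panel))) {
    clim$x <- first$x; clim$y <- first$y
  }
  rownames(clim) <- NULL
  clim
}

#' Anomaly (deviation) series with one-year lags
#'
#' Decomposes each pixel's series into deviations from its own
#' long-term mean: `npp_dev`, `ppt_dev` and `temp_dev` are the annual
#' value minus the pixel's climatological mean, so each pixel's
#' anomalies average zero by construction. One-year-lagged anomalies
#' (`lag_npp_dev`, `lag_ppt_dev`, `lag_temp_dev`) are populated by a
#' one-row shift within the pixel; the first year carries `NA` lags.
#'
#' @param panel Panel data.frame.
#' @param climatology Output of [compute_climatology()] on the same
#'   panel; computed on the fly when omitted.
#' @return data.frame with one row per pixel-year: identifiers,
#'   `water_year`, the three deviation columns and their lags.
#' @export
compute_anomalies <- function(panel, climatology = NULL) {
  .validate_panel_columns(panel)
  if (is.null(climatology)) climatology <- compute_climatology(panel)
  if (!all(panel$pixel_id %in% climatology$pixel_id))
    stop("climatology does not cover every pixel in the panel")

  ord <- order(panel$pixel_id, panel$water_year)
  panel <- panel[ord, , drop = FALSE]
  i <- match(panel$pixel_id, climatology$pixel_id)
  total <- panel$npp_annual_herb + panel$npp_perennial_herb +
    panel$npp_shrub + panel$npp_tree

  anom <- data.frame(
    pixel_id = panel$pixel_id,
    ecoregion = panel$ecoregion,
    water_year = panel$water_year,
    npp_dev = total - climatology$mean_npp[i],
    ppt_dev = panel$ppt_mm - climatology$map_mm[i],
    temp_dev = panel$tmean_c - climatology$mean_temp_c[i],
    stringsAsFactors = FALSE
  )
  lag1 <- function(v, g) ave(v, g, FUN = function(z) c(NA_real_,
                                                       z[-length(z)]))
  anom$lag_npp_dev <- lag1(anom$npp_dev, anom$pixel_id)
  anom$lag_ppt_dev <- lag1(anom$ppt_dev, anom$pixel_id)
  anom$lag_temp_dev <- lag1(anom$temp_dev, anom$pixel_id)
  rownames(anom) <- NULL
  anom
}

#' Standardize anomaly series to unit per-pixel SD
#'
#' Divides each pixel's deviation series by that pixel's sample SD of
#' the same variable, giving anomalies in SD units (mean 0, SD 1 per
#' pixel). Lagged columns are scaled by the SD of their parent variable
#' so that `lag_npp_dev` remains exactly the shifted `npp_dev`. Pixels
#' with a zero SD in any variable are excluded with a warning.
#'
#' @param anomalies Output of [compute_anomalies()].
#' @return Standardized anomaly data.frame of the same shape.
#' @export
standardize_anomalies <- function(anomalies) {
  pid <- anomalies$pixel_id
  key <- as.character(unique(pid))
  sds <- data.frame(
    pixel_id = unique(pid),
    s_npp = as.numeric(tapply(anomalies$npp_dev, pid, sd)[key]),
    s_ppt = as.numeric(tapply(anomalies$ppt_dev, pid, sd)[key]),
    s_temp = as.numeric(tapply(anomalies$temp_dev, pid, sd)[key])
  )
  zero <- sds$pixel_id[sds$s_npp == 0 | sds$s_ppt == 0 | sds$s_temp == 0 |
                         is.na(sds$s_npp) | is.na(sds$s_ppt) |
                         is.na(sds$s_temp)]
  if (length(zero)) {
    warning(length(zero), " pixel(s) with zero-SD series excluded from ",
            "standardization")
    anomalies <- anomalies[!(anomalies$pixel_id %in% zero), , drop = FALSE]
  }
  i <- match(anomalies$pixel_id, sds$pixel_id)
  anomalies$npp_dev <- anomalies$npp_dev / sds$s_npp[i]
  anomalies$lag_npp_dev <- anomalies$lag_npp_dev / sds$s_npp[i]
  anomalies$ppt_dev <- anomalies$ppt_dev / sds$s_ppt[i]
  anomalies$lag_ppt_dev <- anomalies$lag_ppt_dev / sds$s_ppt[i]
  anomalies$temp_dev <- anomalies$temp_dev / sds$s_temp[i]
  anomalies$lag_temp_dev <- anomalies$lag_temp_dev / sds$s_temp[i]
  rownames(anomalies) <- NULL
  anomalies
}
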