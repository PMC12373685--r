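# Extreme-to-normal year transitions: each pixel's wettest/driest,
# most/least productive (and hottest/coldest) years, the "normal
# following year" precipitation filter, and transition correlations.

.extreme_var_col <- c(ppt = "ppt_dev", npp = "npp_dev", temp = "temp_dev")

#' Find a pixel's extreme years for one variable
#'
#' Returns the years holding the single largest (`max`) and smallest
#' (`min`) anomaly of the chosen variable. The last year of the series
#' is excluded as a candidate because no following year exists to
#' evaluate; ties are broken by the earliest year (and noted).
#'
#' @param pixel_anomalies Anomaly records of ONE pixel.
#' @param variable `"ppt"`, `"npp"` or `"temp"`.
#' @return List with `max_year`, `min_year`, `max_anomaly`,
#'   `min_anomaly`, `ties` (logical).
#' @export
find_extreme_years <- function(pixel_anomalies,
                               variable = c("ppt", "npp", "temp")) {
  variable <- match.arg(variable)
  col <- .extreme_var_col[[variable]]
  p <- pixel_anomalies[order(pixel_anomalies$water_year), , drop = FALSE]
  if (nrow(p) < 3L) stop("series too short for extreme-year analysis")
  cand <- p[-nrow(p), , drop = FALSE]  # final year has no following year
  v <- cand[[col]]
  i_max <- which(v == max(v))[1]
  i_min <- which(v == min(v))[1]
  ties <- sum(v == max(v)) > 1L || sum(v == min(v)) > 1L
  list(max_year = cand$water_year[i_max], min_year = cand$water_year[i_min],
       max_anomaly = v[i_max], min_anomaly = v[i_min], ties = ties)
}

#' Build extreme-to-normal year transition records
#'
#' For every pixel and requested variable, identifies the max- and
#' min-anomaly years (excluding the final year), pairs each with the
#' following year's NPP anomaly, and applies the "normal following
#' year" filter: the record passes when the following year's PPT
#' anomaly is within `threshold_sd` pixel-specific PPT standard
#' deviations of zero (default 1; the stricter sensitivity setting is
#' 0.25).
#'
#' @param records Anomaly records ([compute_anomalies()]).
#' @param climatologies Per-pixel climatology (for `sd_ppt_mm`).
#' @param variables Subset of `c("ppt", "npp", "temp")`.
#' @param threshold_sd Normal-year filter width in SD units.
#' @return data.frame of transition records: `pixel_id`, `variable`,
#'   `direction` (`"max"`/`"min"`), `extreme_year`, `extreme_anomaly`,
#'   `next_year_npp_dev`, `next_year_ppt_sd_units`, `passed_filter`.
#' @export
extreme_transitions <- function(records, climatologies,
                                variables = c("ppt", "npp", "temp"),
                                threshold_sd = 1) {
  variables <- match.arg(variables, several.ok = TRUE)
  ord <- order(records$pixel_id, records$water_year)
  records <- records[ord, , drop = FALSE]
  sd_ppt <- climatologies$sd_ppt_mm[match(records$pixel_id,
                                          climatologies$pixel_id)]
  if (anyNA(sd_ppt)) stop("climatology does not cover every pixel")
  if (any(sd_ppt == 0)) stop("zero PPT SD for some pixel(s)")

  pieces <- split(seq_len(nrow(records)), records$pixel_id)
  out <- vector("list", length(pieces) * length(variables) * 2L)
  k <- 0L
  for (idx in pieces) {
    p <- records[idx, , drop = FALSE]
    if (nrow(p) < 3L) next
    s <- sd_ppt[idx[1]]
    for (v in variables) {
      ex <- find_extreme_years(p, v)
      for (dir in c("max", "min")) {
        ey <- if (dir == "max") ex$max_year else ex$min_year
        ea <- if (dir == "max") ex$max_anomaly else ex$min_anomaly
        nxt <- match(ey + 1L, p$water_year)
        if (is.na(nxt)) next  # gap in the series after the extreme
        ppt_sd_units <- p$ppt_dev[nxt] / s
        k <- k + 1L
        out[[k]] <- data.frame(
          pixel_id = p$pixel_id[1], variable = v, direction = dir,
          extreme_year = ey, extreme_anomaly = ea,
          next_year_npp_dev = p$npp_dev[nxt],
          next_year_ppt_sd_units = ppt_sd_units,
          passed_filter = abs(ppt_sd_units) <= threshold_sd,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Re-apply the normal-following-year filter at a new threshold
#'
#' Pure threshold rule on existing transition records: a record passes
#' iff the absolute following-year PPT anomaly is at most
#' `threshold_sd` pixel PPT standard deviations (boundary inclusive).
#' Tightening the threshold can only shrink the passing set.
#'
#' @param transitions Output of [extreme_transitions()].
#' @param threshold_sd New filter width in SD units (e.g. 0.25).
#' @return The records with `passed_filter` recomputed.
#' @export
filter_normal_following_year <- function(transitions, threshold_sd) {
  stopifnot(threshold_sd > 0)
  transitions$passed_filter <-
    abs(transitions$next_year_ppt_sd_units) <= threshold_sd
  transitions
}

#' Spearman correlation of extreme-year and following-year anomalies
#'
#' Rank correlation between the extreme-year anomaly and the following
#' "normal" year's NPP anomaly over passing records, pooled across the
#' max and min directions (the headline statistic) and, optionally,
#' per direction (wettest vs driest reported separately).
#'
#' @param transitions Transition records (one variable, or filter by
#'   `variable` first); only rows with `passed_filter` are used.
#' @param by_direction Also return per-direction correlations.
#' @return data.frame with `group`, `rho`, `p_value`, `n`.
#' @export
transition_correlation <- function(transitions, by_direction = FALSE) {
  rec <- transitions[transitions$passed_filter, , drop = FALSE]
  one <- function(d, label) {
    if (nrow(d) < 10L)
      stop("fewer than 10 passing records for group '", label, "'")
    if (length(unique(d$extreme_anomaly)) < 2L ||
        length(unique(d$next_year_npp_dev)) < 2L)
      stop("all-tied ranks in group '", label, "'")
    ct <- suppressWarnings(
      cor.test(d$extreme_anomaly, d$next_year_npp_dev,
               method = "spearman", alternative = "two.sided"))
    data.frame(group = label, rho = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(d),
               stringsAsFactors = FALSE)
  }
  res <- one(rec, "pooled")
  if (by_direction)
    res <- rbind(res,
                 one(rec[rec$direction == "max", , drop = FALSE], "max"),
                 one(rec[rec$direction == "min", , drop = FALSE], "min"))
  rownames(res) <- NULL
  res
}

#' Density summaries of following-year NPP anomalies by group
#'
#' For each variable x direction group of passing records, a kernel
#' density of the following-year NPP anomalies scaled to a maximum of 1
#' (for overlay plotting) plus the group median.
#'
#' @param transitions Transition records.
#' @return List with `densities` (data.frame: `variable`, `direction`,
#'   `x`, `density`) and `medians` (data.frame: `variable`, `direction`,
#'   `median_npp_dev`, `n`).
#' @export
transition_densities <- function(transitions) {
  rec <- transitions[transitions$passed_filter, , drop = FALSE]
  groups <- split(rec, list(rec$variable, rec$direction), drop = TRUE)
  dens <- vector("list", length(groups))
  meds <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (nrow(g) < 2L)
      stop("group ", names(groups)[i], " has fewer than 2 records")
    d <- density(g$next_year_npp_dev)
    dens[[i]] <- data.frame(variable = g$variable[1],
                            direction = g$direction[1],
                            x = d$x, density = d$y / max(d$y))
    meds[[i]] <- data.frame(variable = g$variable[1],
                            direction = g$direction[1],
                            median_npp_dev = median(g$next_year_npp_dev),
                            n = nrow(g))
  }
  list(densities = do.call(rbind, dens), medians = do.call(rbind, meds))
}
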