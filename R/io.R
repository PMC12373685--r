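# Panel ingestion and pixel-inclusion filtering.

#' Read a pixel-year panel
#'
#' Reads either the tabular dialect (one CSV row per pixel-year) or the
#' raster dialect (a directory of one-band-per-year ESRI ASCII grids, as
#' written by [write_fixture()]). Rows failing validation — negative
#' PPT, negative or non-finite NPP — are dropped with a warning giving
#' the count; duplicate (pixel, water-year) rows are dropped likewise.
#' Pixels whose year ranges differ from the panel mode are flagged with
#' a message but kept.
#'
#' @param path CSV file (tabular) or directory (raster).
#' @param format `"tabular"` or `"raster"`.
#' @return A panel data.frame ordered by pixel and water year, with
#'   columns `pixel_id`, `ecoregion`, `x`, `y` (when available),
#'   `water_year`, `ppt_mm`, `tmean_c` and the four partitioned NPP
#'   groups.
#' @export
read_panel <- function(path, format = c("tabular", "raster")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such path: ", path)
  panel <- if (format == "tabular") {
    p <- read.csv(path, stringsAsFactors = FALSE)
    .validate_panel_columns(p)
    p
  } else {
    .read_raster_panel(path)
  }
  .validate_panel_rows(panel)
}

.validate_panel_rows <- function(panel) {
  npp <- as.matrix(panel[.panel_value_cols[-(1:2)]])
  bad <- !is.finite(panel$ppt_mm) | panel$ppt_mm < 0 |
    !is.finite(panel$tmean_c) |
    apply(!is.finite(npp) | npp < 0, 1L, any)
  if (any(bad)) {
    warning(sum(bad), " pixel-year row(s) failed validation and were dropped")
    panel <- panel[!bad, , drop = FALSE]
  }
  ord <- order(panel$pixel_id, panel$water_year)
  panel <- panel[ord, , drop = FALSE]
  dup <- duplicated(panel[c("pixel_id", "water_year")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (pixel, water_year) row(s) dropped")
    panel <- panel[!dup, , drop = FALSE]
  }
  n_years <- table(panel$pixel_id)
  if (length(unique(n_years)) > 1L)
    message("mixed-length year ranges across pixels (",
            min(n_years), " to ", max(n_years), " years)")
  rownames(panel) <- NULL
  panel
}

.read_raster_panel <- function(path) {
  files <- list.files(path, pattern = "\\.asc$")
  meta <- regmatches(files, regexec("^(.*)_(\\d{4})\\.asc$", files))
  has_year <- lengths(meta) == 3L
  vars <- vapply(meta[has_year], `[`, character(1), 2L)
  yrs <- as.integer(vapply(meta[has_year], `[`, character(1), 3L))
  if (!length(vars)) stop("no <variable>_<year>.asc files under ", path)
  years <- sort(unique(yrs))

  eco_path <- file.path(path, "ecoregion.asc")
  legend_path <- file.path(path, "ecoregion_legend.csv")
  eco_grid <- if (file.exists(eco_path)) read_ascii_grid(eco_path) else NULL
  legend <- if (file.exists(legend_path)) read.csv(legend_path) else NULL

  ref <- read_ascii_grid(file.path(path, files[has_year][1]))
  nr <- nrow(ref$data); nc <- ncol(ref$data)
  cell_x <- ref$xll + (col(ref$data) - 0.5) * ref$cellsize
  cell_y <- ref$yll + (nr - row(ref$data) + 0.5) * ref$cellsize

  per_year <- lapply(years, function(yr) {
    layers <- lapply(.panel_value_cols, function(v) {
      f <- file.path(path, sprintf("%s_%d.asc", v, yr))
      if (!file.exists(f)) stop("missing raster band: ", f)
      read_ascii_grid(f)$data
    })
    names(layers) <- .panel_value_cols
    keep <- !is.na(layers$ppt_mm)
    df <- data.frame(
      pixel_id = which(keep),  # row-major cell index as stable id
      ecoregion = if (!is.null(eco_grid)) {
        code <- eco_grid$data[keep]
        if (!is.null(legend)) legend$ecoregion[match(code, legend$code)]
        else as.character(code)
      } else "unknown",
      x = cell_x[keep], y = cell_y[keep], water_year = yr,
      stringsAsFactors = FALSE
    )
    for (v in .panel_value_cols) df[[v]] <- layers[[v]][keep]
    df
  })
  do.call(rbind, per_year)
}

#' Apply pixel-inclusion filters
#'
#' Configurable form of the multi-step pixel screening used before
#' legacy-effect analysis: a land-cover allow-list, an optional
#' per-ecoregion NPP-outlier screen (pixels whose long-term mean total
#' NPP exceeds a quantile of their ecoregion are removed; off by
#' default), and a minimum number of complete years per pixel. Filters
#' act on whole pixels; the returned report counts pixels removed per
#' rule. Applying the same configuration twice is a no-op.
#'
#' @param panel Panel data.frame.
#' @param filter_config Named list with any of:
#'   \describe{
#'     \item{allowed_landcover}{Character vector of admissible labels,
#'       matched against the `landcover` column if present, else
#'       `ecoregion`. `NULL` disables the filter.}
#'     \item{npp_outlier_quantile}{Upper quantile (e.g. 0.99) of
#'       per-pixel mean total NPP within each ecoregion above which a
#'       pixel is removed. `NULL` (default) disables.}
#'     \item{min_years}{Minimum pixel-years per pixel. `NULL` disables.}
#'   }
#' @return List with `panel` (filtered) and `report` (data.frame of
#'   `rule`, `pixels_removed`).
#' @export
apply_inclusion_filters <- function(panel, filter_config = list()) {
  known <- c("allowed_landcover", "npp_outlier_quantile", "min_years")
  unknown <- setdiff(names(filter_config), known)
  if (length(unknown))
    stop("unknown filter key(s): ", paste(unknown, collapse = ", "))
  report <- data.frame(rule = character(0), pixels_removed = integer(0))
  add <- function(rule, n) rbind(report, data.frame(rule = rule,
                                                    pixels_removed = n))

  lc <- filter_config$allowed_landcover
  if (!is.null(lc)) {
    label <- if ("landcover" %in% names(panel)) panel$landcover
             else panel$ecoregion
    bad_pix <- unique(panel$pixel_id[!(label %in% lc)])
    report <- add("land_cover", length(bad_pix))
    panel <- panel[!(panel$pixel_id %in% bad_pix), , drop = FALSE]
  }
  q <- filter_config$npp_outlier_quantile
  if (!is.null(q)) {
    stopifnot(q > 0, q < 1)
    tot <- rowSums(panel[.panel_value_cols[-(1:2)]])
    mu <- tapply(tot, panel$pixel_id, mean)
    eco <- tapply(panel$ecoregion, panel$pixel_id, `[`, 1L)
    thr <- tapply(mu, eco, quantile, probs = q, type = 6)
    bad_pix <- names(mu)[mu > thr[eco]]
    report <- add("npp_outlier", length(bad_pix))
    panel <- panel[!(as.character(panel$pixel_id) %in% bad_pix), ,
                   drop = FALSE]
  }
  my <- filter_config$min_years
  if (!is.null(my)) {
    n_years <- table(panel$pixel_id)
    bad_pix <- names(n_years)[n_years < my]
    report <- add("min_years", length(bad_pix))
    panel <- panel[!(as.character(panel$pixel_id) %in% bad_pix), ,
                   drop = FALSE]
  }
  rownames(panel) <- NULL
  list(panel = panel, report = report)
}
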