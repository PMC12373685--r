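# Synthetic dryland landscape generator: multi-ecoregion pixel-year panels
# with a known lag-1 legacy data-generating process.

#' Describe one synthetic ecoregion
#'
#' Parameter block for a single ecoregion of the synthetic landscape:
#' the range of pixel mean annual precipitation (MAP), the range of the
#' herbaceous NPP fraction, the gamma shape of annual precipitation
#' totals (the per-pixel scale is set so the gamma mean equals the
#' pixel's MAP), the annual-temperature distribution and the ecoregion
#' mean total NPP.
#'
#' @param name Ecoregion label.
#' @param map_range Length-2 numeric, min and max pixel MAP in mm.
#' @param herb_range Length-2 numeric in \[0, 1\], min and max herbaceous
#'   NPP fraction.
#' @param ppt_shape Gamma shape parameter for annual PPT totals
#'   (dimensionless, > 0). The coefficient of variation of annual PPT is
#'   `1/sqrt(ppt_shape)`.
#' @param temp_mean,temp_sd Mean and SD of annual mean temperature (deg C).
#' @param mean_npp Ecoregion long-term mean total NPP (g C m^-2).
#' @return A list of class `ecoregion_block`.
#' @export
#' @examples
#' ecoregion_block("cold_deserts", c(150, 350), c(0.4, 0.8),
#'                 ppt_shape = 8, temp_mean = 8, temp_sd = 0.7,
#'                 mean_npp = 120)
ecoregion_block <- function(name, map_range, herb_range, ppt_shape,
                            temp_mean, temp_sd, mean_npp) {
  stopifnot(is.character(name), length(name) == 1L,
            length(map_range) == 2L, all(map_range > 0),
            map_range[1] <= map_range[2],
            length(herb_range) == 2L, all(herb_range >= 0),
            all(herb_range <= 1), herb_range[1] <= herb_range[2],
            ppt_shape > 0, temp_sd > 0, mean_npp > 0)
  structure(list(name = name, map_range = as.numeric(map_range),
                 herb_range = as.numeric(herb_range),
                 ppt_shape = as.numeric(ppt_shape),
                 temp_mean = as.numeric(temp_mean),
                 temp_sd = as.numeric(temp_sd),
                 mean_npp = as.numeric(mean_npp)),
            class = "ecoregion_block")
}

#' Default five-ecoregion parameter set
#'
#' A western-US-dryland-like set of five ecoregions spanning a gradient
#' of mean annual precipitation and herbaceous dominance: California
#' annual grasslands, northern mixed prairies, cold deserts, shortgrass
#' steppe and hot deserts. MAP ranges span roughly 100-600 mm; the
#' herbaceous fraction runs from shrub-dominated cold deserts (~0.4-0.8)
#' to nearly fully herbaceous prairies; annual PPT totals are gamma with
#' shape 8 (CV ~ 0.35, typical of dryland interannual variability); mean
#' NPP scales with MAP at roughly 0.4 g C m^-2 per mm.
#'
#' @return A list of five [ecoregion_block()] objects.
#' @export
default_ecoregions <- function() {
  list(
    ecoregion_block("california_annuals",      c(250, 600), c(0.80, 1.00),
                    ppt_shape = 8, temp_mean = 15, temp_sd = 0.7, mean_npp = 220),
    ecoregion_block("northern_mixed_prairies", c(300, 500), c(0.88, 1.00),
                    ppt_shape = 8, temp_mean = 7,  temp_sd = 0.8, mean_npp = 200),
    ecoregion_block("cold_deserts",            c(150, 350), c(0.40, 0.80),
                    ppt_shape = 8, temp_mean = 8,  temp_sd = 0.7, mean_npp = 120),
    ecoregion_block("shortgrass_steppe",       c(300, 450), c(0.85, 1.00),
                    ppt_shape = 8, temp_mean = 10, temp_sd = 0.8, mean_npp = 180),
    ecoregion_block("hot_deserts",             c(100, 350), c(0.55, 0.85),
                    ppt_shape = 8, temp_mean = 18, temp_sd = 0.7, mean_npp = 100)
  )
}

#' Configuration of the synthetic landscape generator
#'
#' Defines the data-generating process for a multi-ecoregion dryland
#' landscape. For each pixel x the generator draws a mean annual
#' precipitation `MAP_x` and a herbaceous fraction `HERB_x` uniformly
#' within the ecoregion's ranges, then simulates annual anomalies with
#' the lag-1 process
#' \deqn{NPPdev_{x,t} = \sigma PPTdev_{x,t} + \tau_x NPPdev_{x,t-1} +
#'   \epsilon_{x,t}}
#' where the pixel's true lag coefficient is
#' `tau_x = tau0_true + delta_map_true * MAP_x + delta_herb_true * HERB_x`.
#' Stationarity requires `|tau_x| < 1` for every pixel; generation stops
#' with an error otherwise.
#'
#' @param n_pixels_per_ecoregion Pixels simulated per ecoregion.
#' @param ecoregions List of [ecoregion_block()] parameter blocks.
#' @param n_years Years simulated per pixel (default 36).
#' @param sigma_true Sensitivity of NPP anomalies to same-year PPT
#'   anomalies (g C m^-2 per mm).
#' @param tau0_true Baseline lag-1 coefficient (unitless).
#' @param delta_map_true Change in the lag coefficient per mm of pixel MAP.
#' @param delta_herb_true Change in the lag coefficient per unit
#'   herbaceous fraction.
#' @param temp_effect_true Sensitivity of NPP anomalies to same-year
#'   temperature anomalies (g C m^-2 per deg C); default 0.
#' @param noise_sd Residual SD of the NPP process (g C m^-2).
#' @param cluster_rho Fraction of the residual variance shared by all
#'   pixels of a spatial cluster (in \[0, 1\]); gives the spatial block
#'   bootstrap dependence to absorb.
#' @param spatial_cluster_size Pixels per correlated square block.
#' @param first_year Calendar label of the first simulated water year.
#' @param init `"stationary"` (draw the initial anomaly from the
#'   stationary marginal; default) or `"burnin"` (start at zero and
#'   discard `burn_in` years).
#' @param burn_in Discarded spin-up years when `init = "burnin"`.
#' @param seed Integer seed; generation is bit-reproducible given a seed.
#' @return A list of class `synthetic_config`.
#' @seealso [generate_landscape()]
#' @export
synthetic_config <- function(n_pixels_per_ecoregion = 400,
                             ecoregions = default_ecoregions(),
                             n_years = 36,
                             sigma_true = 0.3,
                             tau0_true = 0.45,
                             delta_map_true = 0,
                             delta_herb_true = 0,
                             temp_effect_true = 0,
                             noise_sd = 45,
                             cluster_rho = 0.5,
                             spatial_cluster_size = 25,
                             first_year = 1986,
                             init = c("stationary", "burnin"),
                             burn_in = 10,
                             seed = NULL) {
  init <- match.arg(init)
  if (n_pixels_per_ecoregion < 1) stop("n_pixels_per_ecoregion must be >= 1")
  if (n_years < 3) stop("n_years must be >= 3")
  if (noise_sd <= 0) stop("noise_sd must be strictly positive")
  if (cluster_rho < 0 || cluster_rho > 1) stop("cluster_rho must be in [0, 1]")
  if (spatial_cluster_size < 1) stop("spatial_cluster_size must be >= 1")
  if (!length(ecoregions)) stop("at least one ecoregion block is required")
  ok <- vapply(ecoregions, inherits, logical(1), what = "ecoregion_block")
  if (!all(ok)) stop("ecoregions must be a list of ecoregion_block objects")
  structure(list(n_pixels_per_ecoregion = as.integer(n_pixels_per_ecoregion),
                 ecoregions = ecoregions, n_years = as.integer(n_years),
                 sigma_true = sigma_true, tau0_true = tau0_true,
                 delta_map_true = delta_map_true,
                 delta_herb_true = delta_herb_true,
                 temp_effect_true = temp_effect_true,
                 noise_sd = noise_sd, cluster_rho = cluster_rho,
                 spatial_cluster_size = as.integer(spatial_cluster_size),
                 first_year = as.integer(first_year), init = init,
                 burn_in = as.integer(burn_in), seed = seed),
            class = "synthetic_config")
}

# Pixel grid coordinates and square cluster ids for one ecoregion band.
# Pixels fill a near-square rectangle column-major; clusters are square
# blocks of side ceiling(sqrt(cluster_size)).
.pixel_layout <- function(n_pixels, cluster_size, cellsize = 1500,
                          x_offset = 0) {
  ncol_band <- ceiling(sqrt(n_pixels))
  nrow_band <- ceiling(n_pixels / ncol_band)
  idx <- seq_len(n_pixels) - 1L
  row <- idx %% nrow_band
  col <- idx %/% nrow_band
  side <- max(1L, ceiling(sqrt(cluster_size)))
  cluster <- (row %/% side) + (col %/% side) * 10000L
  list(x = x_offset + (col + 0.5) * cellsize,
       y = (row + 0.5) * cellsize,
       cluster = cluster,
       band_width = ncol_band * cellsize)
}

#' Generate a synthetic dryland landscape with known legacy structure
#'
#' Simulates the pixel-year panel described by a [synthetic_config()]:
#' gamma-distributed annual water-year PPT with per-pixel mean `MAP_x`,
#' Gaussian annual temperature, and an NPP anomaly process with a known
#' per-pixel lag-1 coefficient `tau_x`. Residual noise is the sum of a
#' cluster-shared and a pixel-specific Gaussian component so that pixels
#' within the same square spatial block are positively correlated.
#' Absolute NPP is the ecoregion mean plus the anomaly, floored at zero,
#' and is partitioned so that the herbaceous groups (annual plus
#' perennial forbs/grasses) sum to `HERB_x` of the total.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `legacy_landscape` with elements
#'   \describe{
#'     \item{panel}{data.frame, one row per pixel-year, with columns
#'       `pixel_id`, `ecoregion`, `x`, `y`, `water_year`, `ppt_mm`,
#'       `tmean_c`, `npp_annual_herb`, `npp_perennial_herb`, `npp_shrub`,
#'       `npp_tree`.}
#'     \item{truth}{data.frame, one row per pixel, with `pixel_id`,
#'       `ecoregion`, `map_mm`, `herb_frac`, `tau_true`, `sigma_true`
#'       and the generated anomaly bookkeeping column `cluster`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @details The initial anomaly is drawn from the stationary marginal
#'   N(0, (sigma^2 Var(PPT) + noise_sd^2) / (1 - tau_x^2)) unless
#'   `config$init == "burnin"`. Flooring of absolute NPP at zero can
#'   truncate extreme negative anomalies; with the default ecoregion
#'   means and `noise_sd` this is rare (< 0.1% of records).
#' @export
#' @examples
#' cfg <- synthetic_config(n_pixels_per_ecoregion = 10, n_years = 10,
#'                         seed = 1)
#' land <- generate_landscape(cfg)
#' head(land$panel)
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n_eco <- length(config$ecoregions)
  npix <- config$n_pixels_per_ecoregion
  nyr <- config$n_years
  years <- seq(config$first_year, length.out = nyr)

  panels <- vector("list", n_eco)
  truths <- vector("list", n_eco)
  x_offset <- 0
  pid0 <- 0L

  for (e in seq_len(n_eco)) {
    eco <- config$ecoregions[[e]]
    lay <- .pixel_layout(npix, config$spatial_cluster_size,
                         x_offset = x_offset)
    x_offset <- x_offset + lay$band_width + 1500

    map_x <- runif(npix, eco$map_range[1], eco$map_range[2])
    herb_x <- runif(npix, eco$herb_range[1], eco$herb_range[2])
    tau_x <- config$tau0_true + config$delta_map_true * map_x +
      config$delta_herb_true * herb_x
    if (any(abs(tau_x) >= 1)) {
      stop("stationarity violation: |tau| >= 1 for ",
           sum(abs(tau_x) >= 1), " pixel(s) in ecoregion '", eco$name,
           "' (range ", round(min(tau_x), 3), " to ",
           round(max(tau_x), 3), ")")
    }

    burn <- if (config$init == "burnin") config$burn_in else 0L
    ntot <- nyr + burn

    # annual PPT: gamma with mean MAP_x, shape shared within the ecoregion
    scale_x <- map_x / eco$ppt_shape
    ppt <- matrix(rgamma(npix * ntot, shape = eco$ppt_shape,
                         scale = rep(scale_x, each = ntot)),
                  nrow = ntot)
    ppt_dev <- sweep(ppt, 2, map_x)
    tmean <- matrix(rnorm(npix * ntot, eco$temp_mean, eco$temp_sd),
                    nrow = ntot)
    temp_dev <- tmean - eco$temp_mean

    # residual: cluster-shared + pixel-specific components
    sd_shared <- config$noise_sd * sqrt(config$cluster_rho)
    sd_idio <- config$noise_sd * sqrt(1 - config$cluster_rho)
    clusters <- sort(unique(lay$cluster))
    shared <- matrix(rnorm(ntot * length(clusters), 0, sd_shared),
                     nrow = ntot)
    colnames(shared) <- as.character(clusters)
    eps <- shared[, as.character(lay$cluster), drop = FALSE] +
      matrix(rnorm(npix * ntot, 0, sd_idio), nrow = ntot)

    var_ppt <- eco$ppt_shape * scale_x^2
    stat_var <- (config$sigma_true^2 * var_ppt + config$noise_sd^2) /
      (1 - tau_x^2)

    npp_dev <- matrix(0, nrow = ntot, ncol = npix)
    drive <- config$sigma_true * ppt_dev +
      config$temp_effect_true * temp_dev + eps
    prev <- if (config$init == "stationary") {
      rnorm(npix, 0, sqrt(stat_var))
    } else rep(0, npix)
    for (t in seq_len(ntot)) {
      prev <- drive[t, ] + tau_x * prev
      npp_dev[t, ] <- prev
    }
    if (burn > 0) {
      keep <- seq(burn + 1L, ntot)
      npp_dev <- npp_dev[keep, , drop = FALSE]
      ppt <- ppt[keep, , drop = FALSE]
      tmean <- tmean[keep, , drop = FALSE]
    }

    npp_total <- pmax(sweep(npp_dev, 2, eco$mean_npp, `+`), 0)
    herb <- sweep(npp_total, 2, herb_x, `*`)
    woody <- npp_total - herb

    pixel_id <- pid0 + seq_len(npix)
    panels[[e]] <- data.frame(
      pixel_id = rep(pixel_id, each = nyr),
      ecoregion = eco$name,
      x = rep(lay$x, each = nyr),
      y = rep(lay$y, each = nyr),
      water_year = rep(years, times = npix),
      ppt_mm = as.vector(ppt),
      tmean_c = as.vector(tmean),
      npp_annual_herb = as.vector(herb) * 0.4,
      npp_perennial_herb = as.vector(herb) * 0.6,
      npp_shrub = as.vector(woody) * 0.85,
      npp_tree = as.vector(woody) * 0.15,
      stringsAsFactors = FALSE
    )
    truths[[e]] <- data.frame(
      pixel_id = pixel_id, ecoregion = eco$name,
      map_mm = map_x, herb_frac = herb_x, tau_true = tau_x,
      sigma_true = config$sigma_true, cluster = paste0(e, "_", lay$cluster),
      stringsAsFactors = FALSE
    )
    pid0 <- pid0 + npix
  }

  structure(list(panel = do.call(rbind, panels),
                 truth = do.call(rbind, truths),
                 config = config),
            class = "legacy_landscape")
}

#' @export
print.legacy_landscape <- function(x, ...) {
  cat("Synthetic dryland landscape\n")
  cat("  pixels:    ", nrow(x$truth), " in ",
      length(unique(x$truth$ecoregion)), " ecoregions\n", sep = "")
  cat("  years:     ", x$config$n_years, " (",
      min(x$panel$water_year), "-", max(x$panel$water_year), ")\n", sep = "")
  cat("  true tau:  ", round(min(x$truth$tau_true), 3), " to ",
      round(max(x$truth$tau_true), 3), "\n", sep = "")
  cat("  true sigma:", format(x$config$sigma_true), "g C m-2 per mm\n")
  invisible(x)
}

#' Write a pixel-year panel to disk as a test fixture
#'
#' Serializes a panel (and, for generated landscapes, its truth table)
#' either as a single tabular CSV or as a directory of one-band-per-year
#' ESRI ASCII grids, the package's plain-text raster dialect. Both
#' dialects round-trip losslessly through [read_panel()].
#'
#' @param panel A `legacy_landscape` or a panel data.frame.
#' @param path Output file (tabular) or directory (raster).
#' @param format `"tabular"` or `"raster"`.
#' @param digits Significant digits written; default 10 keeps round-trips
#'   below 1e-9 relative error at field magnitudes.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(panel, path, format = c("tabular", "raster"),
                          digits = 10) {
  format <- match.arg(format)
  truth <- NULL
  if (inherits(panel, "legacy_landscape")) {
    truth <- panel$truth
    panel <- panel$panel
  }
  if (!is.data.frame(panel) || nrow(panel) == 0L)
    stop("panel must be a nonempty data.frame")
  .validate_panel_columns(panel)

  if (format == "tabular") {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    out <- panel
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], signif, digits = digits)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    if (!is.null(truth))
      write.csv(truth, sub("\\.csv$", "", path) |> paste0("_truth.csv"),
                row.names = FALSE, quote = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    .write_raster_panel(panel, path, digits = digits)
    if (!is.null(truth))
      write.csv(truth, file.path(path, "truth.csv"),
                row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

.panel_value_cols <- c("ppt_mm", "tmean_c", "npp_annual_herb",
                       "npp_perennial_herb", "npp_shrub", "npp_tree")

.validate_panel_columns <- function(panel) {
  need <- c("pixel_id", "ecoregion", "water_year", .panel_value_cols)
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing required columns: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

# One .asc per variable-year plus an integer-coded ecoregion grid.
.write_raster_panel <- function(panel, path, digits = 10) {
  if (!all(c("x", "y") %in% names(panel)))
    stop("raster fixtures require x and y pixel coordinates")
  geo <- .panel_geometry(panel)
  years <- sort(unique(panel$water_year))
  for (v in .panel_value_cols) {
    for (yr in years) {
      sub <- panel[panel$water_year == yr, ]
      g <- .panel_to_grid(sub, v, geo)
      write_ascii_grid(g, file.path(path, sprintf("%s_%d.asc", v, yr)),
                       digits = digits)
    }
  }
  eco_levels <- sort(unique(panel$ecoregion))
  first <- panel[!duplicated(panel$pixel_id), ]
  first$.eco_code <- match(first$ecoregion, eco_levels)
  g <- .panel_to_grid(first, ".eco_code", geo)
  write_ascii_grid(g, file.path(path, "ecoregion.asc"), digits = digits)
  write.csv(data.frame(code = seq_along(eco_levels), ecoregion = eco_levels),
            file.path(path, "ecoregion_legend.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
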