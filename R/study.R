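# Study orchestration: run the full legacy-effect analysis from a
# declarative config, write per-stage outputs and a manifest.

#' Load and validate a study configuration
#'
#' The configuration is a named list (or a YAML file containing one)
#' with blocks `synthetic` (generator parameters, see
#' [synthetic_config()]; optional `ecoregions` list overrides the
#' default five), `filters` (see [apply_inclusion_filters()]),
#' `bootstrap` (`n_iterations`, `fraction`, `ci_level`), `pixelwise`
#' (`min_years`, `trim`), `extremes` (`threshold_sd`,
#' `sensitivity_sd`), plus top-level `name`, `seed` and `output_dir`.
#' Missing blocks fall back to study defaults. Validation failures
#' raise errors naming the offending field.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated config list of class `study_config`.
#' @export
study_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    name = "legacy_study", seed = 1, output_dir = "legacy_run",
    synthetic = list(), filters = list(),
    bootstrap = list(n_iterations = 1000, fraction = 0.001,
                     ci_level = 0.99),
    pixelwise = list(min_years = 5, trim = c(2.5, 97.5)),
    extremes = list(threshold_sd = 1, sensitivity_sd = 0.25)
  )
  for (blk in names(defaults)) {
    if (is.null(config[[blk]])) config[[blk]] <- defaults[[blk]]
    else if (is.list(defaults[[blk]]))
      for (f in names(defaults[[blk]]))
        if (is.null(config[[blk]][[f]]))
          config[[blk]][[f]] <- defaults[[blk]][[f]]
  }
  syn <- config$synthetic
  if (!is.null(syn$n_years) && syn$n_years < 3)
    stop("config error: synthetic.n_years must be >= 3")
  if (!is.null(syn$noise_sd) && syn$noise_sd <= 0)
    stop("config error: synthetic.noise_sd must be > 0")
  bt <- config$bootstrap
  if (bt$n_iterations < 1) stop("config error: bootstrap.n_iterations >= 1")
  if (bt$fraction <= 0 || bt$fraction > 1)
    stop("config error: bootstrap.fraction must be in (0, 1]")
  if (bt$ci_level <= 0 || bt$ci_level >= 1)
    stop("config error: bootstrap.ci_level must be in (0, 1)")
  if (config$extremes$threshold_sd <= 0)
    stop("config error: extremes.threshold_sd must be > 0")
  structure(config, class = "study_config")
}

.config_to_synthetic <- function(syn, seed) {
  eco <- if (!is.null(syn$ecoregions)) {
    lapply(syn$ecoregions, function(e)
      ecoregion_block(e$name, unlist(e$map_range), unlist(e$herb_range),
                      e$ppt_shape, e$temp_mean, e$temp_sd, e$mean_npp))
  } else default_ecoregions()
  args <- syn[setdiff(names(syn), c("ecoregions", "seed"))]
  args$ecoregions <- eco
  args$seed <- seed
  do.call(synthetic_config, args)
}

#' Run the full legacy-effect study
#'
#' Executes the staged analysis described by a [study_config()]:
#' generate the synthetic landscape (or ingest `input` when given),
#' apply inclusion filters, compute climatologies and anomalies, then
#' answer the three study questions — (Q1) paired bootstrap of the
#' PPT-only model against the lag model; (Q2) bootstraps of the MAP-
#' and herbaceous-interaction models, the pixel-wise lag-coefficient
#' map, and the extreme-to-normal transition analysis; (Q3) bootstrap
#' of the lag x current-PPT interaction model. Every stage derives its
#' seed from the master seed, so re-running the same config reproduces
#' all numeric outputs bit-exactly.
#'
#' @param config A [study_config()], list, or YAML path.
#' @param output_dir Override the config's output directory.
#' @param seed Override the config's master seed.
#' @param input Optional pre-built panel data.frame or path readable by
#'   [read_panel()]; skips the synthetic stage.
#' @return The output directory path, invisibly, with the full results
#'   list attached as attribute `results`.
#' @export
run_study <- function(config, output_dir = NULL, seed = NULL,
                      input = NULL) {
  config <- study_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(output_dir)) config$output_dir <- output_dir
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "log.txt")
  cat("", file = logf)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
  }
  stage_seeds <- .iteration_seeds(config$seed, 8L)

  # stage 1: data
  say("stage generate/ingest")
  truth <- NULL
  if (is.null(input)) {
    scfg <- .config_to_synthetic(config$synthetic, stage_seeds[1])
    land <- generate_landscape(scfg)
    panel <- land$panel; truth <- land$truth
  } else {
    panel <- if (is.character(input)) read_panel(input) else input
  }

  # stage 2: filters
  say("stage filter")
  filt <- apply_inclusion_filters(panel, config$filters)
  panel <- filt$panel
  write.csv(filt$report, file.path(out, "filter_report.csv"),
            row.names = FALSE)
  say("  pixels removed: ", sum(filt$report$pixels_removed))

  # stage 3: climatology + anomalies
  say("stage climatology/anomalies")
  clim <- compute_climatology(panel)
  anom <- compute_anomalies(panel, clim)
  write.csv(clim, file.path(out, "climatology.csv"), row.names = FALSE)

  bt <- config$bootstrap

  # stage 4 (Q1): eq1 vs eq2 paired bootstrap + pooled DW
  say("stage Q1 paired bootstrap")
  q1 <- paired_model_deltas(anom, clim, "eq1", "eq2",
                            n_iterations = bt$n_iterations,
                            fraction = bt$fraction,
                            ci_level = bt$ci_level, seed = stage_seeds[2])
  write.csv(q1$summaries, file.path(out, "q1_model_comparison.csv"),
            row.names = FALSE)
  lagged <- anom[stats::complete.cases(anom["lag_npp_dev"]), ]
  fit1 <- fit_legacy(lagged, clim, "eq1")
  fit2 <- fit_legacy(lagged, clim, "eq2")
  dw_tab <- data.frame(model = c("eq1", "eq2"),
                       dw = c(fit1$dw, fit2$dw),
                       r2 = c(fit1$r2, fit2$r2),
                       aic = c(fit1$aic, fit2$aic))
  write.csv(dw_tab, file.path(out, "durbin_watson.csv"), row.names = FALSE)

  # stage 5 (Q2): eq3 / eq4 bootstraps, pixel map, extremes
  say("stage Q2 bootstraps")
  boots <- list()
  spec_seed <- c(eq2 = stage_seeds[3], eq3 = stage_seeds[4],
                 eq4 = stage_seeds[5])
  for (m in c("eq2", "eq3", "eq4")) {
    b <- run_bootstrap(anom, clim, m, n_iterations = bt$n_iterations,
                       fraction = bt$fraction, ci_level = bt$ci_level,
                       seed = spec_seed[[m]])
    boots[[m]] <- b
    write.csv(b$summaries, file.path(out, paste0("boot_", m, ".csv")),
              row.names = FALSE)
  }

  say("stage Q2 pixel map")
  px <- fit_pixel_lag(anom, min_years = config$pixelwise$min_years)
  trim <- trim_percentiles(px$estimates$tau,
                           config$pixelwise$trim[1],
                           config$pixelwise$trim[2])
  px$estimates$trimmed <- !trim$mask
  write.csv(px$estimates, file.path(out, "pixel_tau.csv"),
            row.names = FALSE)
  tau_grid <- NULL
  if (all(c("x", "y") %in% names(clim))) {
    kept <- px$estimates[trim$mask, , drop = FALSE]
    tau_grid <- rasterize_coefficients(kept, clim, "tau",
                                       path = file.path(out, "tau_map.asc"))
  }

  say("stage Q2 extremes")
  trans <- extreme_transitions(anom, clim,
                               threshold_sd = config$extremes$threshold_sd)
  write.csv(trans, file.path(out, "transitions.csv"), row.names = FALSE)
  cors <- do.call(rbind, lapply(c("npp", "ppt", "temp"), function(v) {
    tv <- trans[trans$variable == v, ]
    main <- transition_correlation(tv, by_direction = TRUE)
    main$variable <- v
    main$threshold_sd <- config$extremes$threshold_sd
    strict <- filter_normal_following_year(tv,
                                           config$extremes$sensitivity_sd)
    st <- tryCatch(transition_correlation(strict), error = function(e) NULL)
    if (!is.null(st)) {
      st$variable <- v
      st$threshold_sd <- config$extremes$sensitivity_sd
      main <- rbind(main, st)
    }
    main
  }))
  write.csv(cors, file.path(out, "transition_correlations.csv"),
            row.names = FALSE)

  # stage 6 (Q3): eq5 bootstrap
  say("stage Q3 bootstrap")
  q3 <- run_bootstrap(anom, clim, "eq5", n_iterations = bt$n_iterations,
                      fraction = bt$fraction, ci_level = bt$ci_level,
                      seed = stage_seeds[6])
  boots[["eq5"]] <- q3
  write.csv(q3$summaries, file.path(out, "boot_eq5.csv"),
            row.names = FALSE)

  if (!is.null(truth))
    write.csv(truth, file.path(out, "truth.csv"), row.names = FALSE)
  manifest <- list(
    package = "npplegacy",
    version = as.character(utils::packageVersion("npplegacy")),
    seed = config$seed, stage_seeds = stage_seeds,
    n_pixels = length(unique(panel$pixel_id)),
    n_rows = nrow(panel),
    config = unclass(config))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done")

  results <- list(panel = panel, truth = truth, climatology = clim,
                  anomalies = anom, q1 = q1, dw = dw_tab, boots = boots,
                  pixelwise = px, tau_grid = tau_grid,
                  transitions = trans, correlations = cors)
  invisible(structure(out, results = results))
}

#' Collate summary tables from a completed run directory
#'
#' Reads the per-stage outputs of [run_study()] and returns tidy
#' tables: a coefficient table with one row per (model, term, ecoregion)
#' carrying the bootstrap mean, CI bounds and significance; the Q1
#' model-comparison (delta R2 / delta AIC) table; and the
#' transition-correlation table. When a truth table is present, the
#' coefficient table gains the true value and a recovery error column
#' for the terms the generator fixes.
#'
#' @param run_dir Directory written by [run_study()].
#' @return List with `coefficients`, `comparison`, `transitions`.
#' @export
export_summaries <- function(run_dir) {
  if (!dir.exists(run_dir)) stop("no such run directory: ", run_dir)
  boot_files <- list.files(run_dir, pattern = "^boot_.*\\.csv$",
                           full.names = TRUE)
  if (!length(boot_files))
    stop("run directory has no bootstrap outputs; run_study first")
  coefs <- do.call(rbind, lapply(boot_files, function(f) {
    s <- read.csv(f, stringsAsFactors = FALSE)
    s$model <- sub("^boot_(.*)\\.csv$", "\\1", basename(f))
    parts <- strsplit(s$metric, ":", fixed = TRUE)
    s$term <- vapply(parts, `[`, character(1), 1L)
    s$ecoregion <- vapply(parts, function(p)
      if (length(p) > 1L) p[2] else NA_character_, character(1))
    s
  }))
  truth_path <- file.path(run_dir, "truth.csv")
  if (file.exists(truth_path)) {
    truth <- read.csv(truth_path, stringsAsFactors = FALSE)
    true_vals <- c(tau = mean(truth$tau_true),
                   sigma = truth$sigma_true[1])
    coefs$true_value <- unname(true_vals[coefs$term])
    coefs$recovery_error <- coefs$mean - coefs$true_value
  }
  comparison <- read.csv(file.path(run_dir, "q1_model_comparison.csv"),
                         stringsAsFactors = FALSE)
  transitions <- read.csv(file.path(run_dir,
                                    "transition_correlations.csv"),
                          stringsAsFactors = FALSE)
  list(coefficients = coefs, comparison = comparison,
       transitions = transitions)
}
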