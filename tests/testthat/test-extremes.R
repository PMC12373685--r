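one_pixel_anom <- function(ppt_dev, npp_dev = seq_along(ppt_dev)) {
  n <- length(ppt_dev)
  data.frame(pixel_id = 1L, ecoregion = "e", water_year = seq_len(n) + 2000L,
             npp_dev = npp_dev - mean(npp_dev),
             ppt_dev = ppt_dev - mean(ppt_dev),
             temp_dev = 0,
             lag_npp_dev = NA_real_, lag_ppt_dev = NA_real_,
             lag_temp_dev = NA_real_)
}

test_that("extreme years are the argmax/argmin excluding the final year", {
  a <- one_pixel_anom(c(-30, 5, 25, 0) + 10)  # centering-safe offsets
  ex <- find_extreme_years(a, "ppt")
  expect_equal(ex$max_year, 2003L)  # wettest: +25 in year 3
  expect_equal(ex$min_year, 2001L)  # driest: -30 in year 1
  expect_false(ex$ties)
  # an extreme in the final year is never a candidate
  a2 <- one_pixel_anom(c(-30, 5, 25, 90))
  ex2 <- find_extreme_years(a2, "ppt")
  expect_equal(ex2$max_year, 2003L)  # next-most-extreme interior year
  # ties break to the earlier year and are flagged
  a3 <- one_pixel_anom(c(-30, -30, 5, 0))
  ex3 <- find_extreme_years(a3, "ppt")
  expect_equal(ex3$min_year, 2001L)
  expect_true(ex3$ties)
  expect_error(find_extreme_years(a3[1:2, ], "ppt"), "too short")
})

test_that("the normal-following-year filter applies the SD threshold inclusively", {
  rec <- data.frame(next_year_ppt_sd_units = c(0.8, 1.0, 0, -1.2),
                    passed_filter = NA)
  expect_equal(filter_normal_following_year(rec, 1.0)$passed_filter,
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(filter_normal_following_year(rec, 0.25)$passed_filter,
               c(FALSE, FALSE, TRUE, FALSE))
})

test_that("transition records pair extremes with the following year", {
  land <- small_landscape(n_pix = 10, n_years = 12, seed = 91)
  anom <- compute_anomalies(land$panel)
  clim <- compute_climatology(land$panel)
  tr <- extreme_transitions(anom, clim)
  # every pixel contributes max and min records for all three variables
  expect_equal(nrow(tr), 50 * 3 * 2)
  # the paired year is extreme_year + 1 and its anomaly is the pixel's
  i <- sample(nrow(tr), 20)
  for (k in i) {
    row <- tr[k, ]
    nxt <- anom[anom$pixel_id == row$pixel_id &
                  anom$water_year == row$extreme_year + 1L, ]
    expect_equal(nxt$npp_dev, row$next_year_npp_dev)
  }
  # a passing record's following year cannot be a PPT extreme that
  # itself breaches the filter threshold: the filter bounds its anomaly
  expect_true(all(abs(tr$next_year_ppt_sd_units[tr$passed_filter]) <= 1))
  sd_ppt <- clim$sd_ppt_mm[match(tr$pixel_id, clim$pixel_id)]
  big_ext <- tr$variable == "ppt" & abs(tr$extreme_anomaly) > sd_ppt
  for (k in which(big_ext)) {
    row <- tr[k, ]
    prior <- tr[tr$pixel_id == row$pixel_id & tr$variable == "ppt" &
                  tr$extreme_year == row$extreme_year - 1L, ]
    if (nrow(prior)) expect_false(any(prior$passed_filter))
  }
})

test_that("tightening the filter never increases the passing count", {
  land <- small_landscape(n_pix = 30, n_years = 20, seed = 92)
  anom <- compute_anomalies(land$panel)
  clim <- compute_climatology(land$panel)
  tr <- extreme_transitions(anom, clim, threshold_sd = 1)
  counts <- sapply(c(2, 1, 0.5, 0.25), function(th)
    sum(filter_normal_following_year(tr, th)$passed_filter))
  expect_true(all(diff(counts) <= 0))
})

test_that("Spearman correlation hits the monotone limits", {
  mono <- data.frame(extreme_anomaly = 1:12,
                     next_year_npp_dev = (1:12)^2,
                     direction = "max", passed_filter = TRUE)
  expect_equal(transition_correlation(mono)$rho, 1)
  anti <- mono
  anti$next_year_npp_dev <- -anti$next_year_npp_dev
  expect_equal(transition_correlation(anti)$rho, -1)
  expect_error(transition_correlation(mono[1:5, ]), "fewer than 10")
  tied <- mono
  tied$next_year_npp_dev <- 1
  expect_error(transition_correlation(tied), "all-tied")
})

test_that("legacy structure orders the transition correlations", {
  land <- small_landscape(n_pix = 150, n_years = 36, seed = 93)
  anom <- compute_anomalies(land$panel)
  clim <- compute_climatology(land$panel)
  tr <- extreme_transitions(anom, clim)
  rho_npp <- transition_correlation(tr[tr$variable == "npp", ])$rho
  rho_ppt <- transition_correlation(tr[tr$variable == "ppt", ])$rho
  expect_gt(rho_npp, 0)
  expect_gt(rho_ppt, 0)
  expect_gt(rho_npp, rho_ppt)
})

test_that("null-generator transition rho matches a brute-force null oracle", {
  # oracle: plain white-noise series, centered, same extreme+filter logic
  # written independently of the package
  set.seed(94)
  n_pix <- 600; n_yr <- 36
  ex_a <- nxt_a <- numeric(n_pix)
  for (i in seq_len(n_pix)) {
    y <- rnorm(n_yr); y <- y - mean(y)
    cand <- y[-n_yr]
    j <- which.max(cand)
    ex_a[i] <- cand[j]; nxt_a[i] <- y[j + 1]
  }
  rho_null <- cor(ex_a, nxt_a, method = "spearman")
  # package pipeline on a tau = 0 landscape (sigma small so NPP ~ noise)
  land <- generate_landscape(synthetic_config(
    n_pixels_per_ecoregion = 120, tau0_true = 0, sigma_true = 0.01,
    cluster_rho = 0, seed = 95))
  anom <- compute_anomalies(land$panel)
  clim <- compute_climatology(land$panel)
  tr <- extreme_transitions(anom, clim, threshold_sd = 100)  # filter off
  got <- transition_correlation(
    tr[tr$variable == "npp" & tr$direction == "max", ])$rho
  expect_lt(abs(got - rho_null), 0.12)
  expect_lt(got, 0.1)  # regression to the mean, not positive legacy
})

test_that("transition densities are scaled and ordered by legacy sign", {
  land <- small_landscape(n_pix = 100, n_years = 36, seed = 96)
  anom <- compute_anomalies(land$panel)
  clim <- compute_climatology(land$panel)
  tr <- extreme_transitions(anom, clim, variables = "ppt")
  td <- transition_densities(tr)
  expect_equal(max(td$densities$density), 1)
  med <- td$medians
  # following-dry median NPP anomaly < following-wet median (tau > 0)
  expect_lt(med$median_npp_dev[med$direction == "min"],
            med$median_npp_dev[med$direction == "max"])
  # identical groups give identical densities
  tr2 <- tr
  tr2$next_year_npp_dev <- abs(tr2$next_year_npp_dev)
  tr2$direction <- "max"
  tr3 <- tr2
  tr3$direction <- "min"
  td2 <- transition_densities(rbind(tr2, tr3))
  expect_equal(td2$densities$density[td2$densities$direction == "max"],
               td2$densities$density[td2$densities$direction == "min"])
  one <- tr[1, ]
  one$passed_filter <- TRUE
  expect_error(transition_densities(one), "fewer than 2")
})
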