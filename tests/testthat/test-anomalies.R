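test_that("water-year aggregation sums PPT and averages temperature", {
  d <- data.frame(date = seq(as.Date("1986-10-01"), as.Date("1987-09-30"),
                             by = "day"),
                  ppt_mm = 1, tmin_c = 0, tmax_c = 10)
  out <- water_year_aggregate(d)
  expect_equal(out$water_year, 1987L)
  expect_equal(out$ppt_mm, 365)
  expect_equal(out$tmean_c, 5)
})

test_that("incomplete edge water years are dropped", {
  d <- data.frame(date = seq(as.Date("1987-01-01"), as.Date("1988-09-30"),
                             by = "day"),
                  ppt_mm = 2, tmean_c = 8)
  out <- water_year_aggregate(d)
  expect_identical(out$water_year, 1988L)  # 1987 window starts 1986-10-01
  d2 <- d[sample(nrow(d)), ]
  expect_error(water_year_aggregate(d2), "date order")
  d3 <- rbind(d, d[1, ])
  expect_error(water_year_aggregate(d3), "duplicate")
})

test_that("climatology means, CV and herb fraction match hand arithmetic", {
  p <- tiny_panel()
  clim <- compute_climatology(p)
  # pixel 1: totals 100, 120, 80
  i <- clim$pixel_id == 1
  expect_equal(clim$mean_npp[i], 100)
  expect_equal(clim$cv_npp[i], sd(c(100, 120, 80)) / 100)
  expect_equal(clim$herb_frac[i], 0.70)  # herb 70/100, 84/120, 56/80
  expect_equal(clim$map_mm[i], 250)
  # pixel 2: herb fraction varies by year -> mean of yearly ratios
  j <- clim$pixel_id == 2
  expect_equal(clim$herb_frac[j], mean(c(50 / 100, 60 / 100, 70 / 100)))
  # ratio-of-means alternative differs
  clim2 <- compute_climatology(p, herb_method = "ratio_of_means")
  expect_equal(clim2$herb_frac[j], (50 + 60 + 70) / 300)
  expect_error(compute_climatology(p[p$water_year < 2003, ]), "fewer than 3")
})

test_that("anomalies decompose exactly with correct lags", {
  p <- tiny_panel()
  anom <- compute_anomalies(p)
  a1 <- anom[anom$pixel_id == 1, ]
  expect_equal(a1$npp_dev, c(0, 20, -20))
  expect_equal(a1$lag_npp_dev, c(NA, 0, 20))
  expect_equal(a1$ppt_dev, c(-50, 0, 50))
  # per-pixel anomaly means are 0; mean + dev reconstructs the value
  expect_true(all(abs(tapply(anom$npp_dev, anom$pixel_id, mean)) < 1e-9))
  clim <- compute_climatology(p)
  total <- p$npp_annual_herb + p$npp_perennial_herb + p$npp_shrub + p$npp_tree
  rec <- anom$npp_dev + clim$mean_npp[match(anom$pixel_id, clim$pixel_id)]
  expect_equal(rec, total[order(p$pixel_id, p$water_year)])
})

test_that("shifting a series by a constant changes no anomaly", {
  p <- tiny_panel()
  p2 <- p
  p2$ppt_mm <- p2$ppt_mm + 500
  p2$npp_shrub <- p2$npp_shrub + 40
  a <- compute_anomalies(p)
  b <- compute_anomalies(p2)
  expect_equal(a$ppt_dev, b$ppt_dev)
  expect_equal(a$npp_dev, b$npp_dev)
})

test_that("an all-herbaceous pixel has herb fraction exactly 1", {
  p <- tiny_panel()[1:3, ]
  p$npp_shrub <- 0
  p$npp_tree <- 0
  expect_equal(compute_climatology(p)$herb_frac, 1)
})

test_that("constant series give zero anomalies and zero CV", {
  p <- tiny_panel()[1:3, ]
  p[c("ppt_mm", "tmean_c")] <- list(300, 10)
  p[c("npp_annual_herb", "npp_perennial_herb", "npp_shrub",
      "npp_tree")] <- list(10, 60, 30, 0)
  clim <- compute_climatology(p)
  expect_equal(clim$cv_npp, 0)
  anom <- compute_anomalies(p, clim)
  expect_true(all(anom$npp_dev == 0))
})

test_that("standardization yields unit SD and keeps lag consistency", {
  p <- tiny_panel()
  anom <- compute_anomalies(p)
  # pixel 2 has constant total NPP, a zero-SD series: excluded, warned
  expect_warning(s <- standardize_anomalies(anom), "zero-SD")
  expect_false(2 %in% s$pixel_id)
  sds <- as.numeric(tapply(s$npp_dev, s$pixel_id, sd))
  expect_equal(sds, rep(1, 2))
  # lag column is still the shifted npp_dev
  s1 <- s[s$pixel_id == 1, ]
  expect_equal(s1$lag_npp_dev[-1], s1$npp_dev[-nrow(s1)])
  # hand check: {0, 20, -20} / sd
  expect_equal(s1$npp_dev, c(0, 20, -20) / sd(c(0, 20, -20)))
})

test_that("standardized and raw fits agree on the lag signal call", {
  land <- small_landscape(n_pix = 60, n_years = 36, seed = 31)
  anom <- compute_anomalies(land$panel)
  clim <- compute_climatology(land$panel)
  raw <- run_bootstrap(anom, clim, legacy_model("eq2"),
                       n_iterations = 40, fraction = 0.02, seed = 41)
  std <- run_bootstrap(anom, clim, legacy_model("eq2", standardize = TRUE),
                       n_iterations = 40, fraction = 0.02, seed = 41)
  tr <- raw$summaries[raw$summaries$metric == "tau", ]
  ts <- std$summaries[std$summaries$metric == "tau", ]
  expect_gt(tr$mean, 0)
  expect_gt(ts$mean, 0)
  expect_identical(tr$significant, ts$significant)
})
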