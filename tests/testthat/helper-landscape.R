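# Shared small synthetic fixtures, built in code at test time.

# A compact homogeneous landscape: known tau0/sigma, no gradients.
small_landscape <- function(n_pix = 40, n_years = 36, tau0 = 0.45,
                            sigma = 0.3, noise_sd = 45, seed = 101,
                            ...) {
  generate_landscape(synthetic_config(
    n_pixels_per_ecoregion = n_pix, n_years = n_years,
    sigma_true = sigma, tau0_true = tau0, noise_sd = noise_sd,
    seed = seed, ...))
}

# Three-pixel hand-buildable panel with exact numbers.
tiny_panel <- function() {
  data.frame(
    pixel_id = rep(1:3, each = 3),
    ecoregion = rep(c("grass", "grass", "shrub"), each = 3),
    x = rep(c(750, 2250, 3750), each = 3),
    y = 750,
    water_year = rep(2001:2003, 3),
    ppt_mm = c(200, 250, 300, 180, 200, 220, 300, 310, 320),
    tmean_c = c(10, 11, 12, 9, 10, 11, 14, 15, 16),
    npp_annual_herb = c(10, 12, 8, 5, 6, 7, 20, 21, 22),
    npp_perennial_herb = c(60, 72, 48, 45, 54, 63, 40, 42, 44),
    npp_shrub = c(30, 36, 24, 30, 30, 30, 90, 94, 98),
    npp_tree = c(0, 0, 0, 20, 10, 0, 50, 53, 56)
  )
}
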