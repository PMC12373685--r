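# Demo study: 5 ecoregions x 400 pixels x 36 water years, lag-1 legacy
# process with tau varying along the MAP and herbaceous gradients.
name: demo
seed: 20260101
output_dir: runs/demo
synthetic:
  n_pixels_per_ecoregion: 400
  n_years: 36
  sigma_true: 0.3
  tau0_true: 0.25
  delta_map_true: 0.0007
  delta_herb_true: -0.3
  noise_sd: 45
  cluster_rho: 0.5
  spatial_cluster_size: 25
filters:
  min_years: 36
bootstrap:
  n_iterations: 200
  fraction: 0.001
  ci_level: 0.99
pixelwise:
  min_years: 5
  trim: [2.5, 97.5]
extremes:
  threshold_sd: 1.0
  sensitivity_sd: 0.25
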