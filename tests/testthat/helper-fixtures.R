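# Small in-code fixtures shared across test files.

# A tiny spot_counts object on a line of spots.
toy_spot_counts <- function(counts, radius = 5) {
  counts <- as.matrix(counts)
  S <- nrow(counts)
  spot_counts(counts,
              spot_xy = cbind(x = seq_len(S) * 4 * radius, y = rep(0, S)),
              spot_radius = radius,
              spot_ids = paste0("s", seq_len(S)),
              gene_ids = paste0("g", seq_len(ncol(counts))))
}

# A small simulated dataset, cheap enough for unit tests.
toy_scenario <- function(scenario = "cell", seed = 7, n_spots = 40,
                         cells_per_spot = 5, encoder = "synthetic_cluster") {
  ref <- generate_reference(K = 3, G = 60, cells_per_cluster = 60,
                            markers_per_cluster = 5, seed = seed)
  cfg <- scenario_config(scenario, k_image_clusters = 3, keep_per_cluster = 40,
                         n_spots = n_spots, cells_per_spot = cells_per_spot,
                         image_cells_per_cluster = 60, embed_dim = 8,
                         encoder = encoder, seed = seed)
  run_scenario(cfg, ref)
}

# Brute-force Moran's I: explicit double loop over the weight matrix.
moran_brute <- function(values, w) {
  n <- length(values)
  xbar <- mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * (values[i] - xbar) * (values[j] - xbar)
  (n / sum(w)) * num / sum((values - xbar)^2)
}
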