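# Shared phantom fixtures, built in code at test time.

# standard segmentation phantom: 100 cells, SNR ~10, spacing >= 3 radii
standard_seg_phantom <- function(seed = 11) {
  cfg <- phantom_config(
    tile_size = 360, grid_rows = 1, grid_cols = 1, n_cycles = 1,
    cell_types = data.frame(type = c("T", "E"),
                            CD3 = c(100, 5), Cytokeratin = c(5, 100),
                            CD45 = c(80, 80)),
    n_cells = 100, min_spacing = 12, nucleus_radius = 4,
    nucleus_radius_sd = 0.3, membrane_width = 2,
    background = 0, blur_sigma = 1, noise_sd = 10, seed = seed)
  generate_tissue_phantom(cfg)
}

# small multicycle phantom with drift and flanking blank cycles
drift_phantom <- function(drift, seed = 3, tile_size = 220, n_cells = 120,
                          noise_sd = 2, blank_cycles = integer(0)) {
  cfg <- phantom_config(
    tile_size = tile_size, n_cycles = nrow(drift), n_cells = n_cells,
    drift = drift, background = 20, blur_sigma = 1, noise_sd = noise_sd,
    seed = seed)
  generate_tissue_phantom(cfg, blank_cycles = blank_cycles)
}

# cell table with planted spatial structure for density correlations:
# types A and B share hotspots, type C occupies the complement
colocalization_table <- function(n_hot = 12, per_spot = 30, dim_yx = c(1200, 1200),
                                 seed = 21) {
  set.seed(seed)
  hot <- cbind(runif(n_hot, 100, dim_yx[1] - 100),
               runif(n_hot, 100, dim_yx[2] - 100))
  rows <- list()
  id <- 1
  for (h in seq_len(n_hot)) {
    for (ty in c("A", "B")) {
      k <- rpois(1, per_spot)
      if (k == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        id = id:(id + k - 1),
        y_px = pmin(pmax(rnorm(k, hot[h, 1], 40), 0), dim_yx[1] - 1),
        x_px = pmin(pmax(rnorm(k, hot[h, 2], 40), 0), dim_yx[2] - 1),
        area = 50, cluster = ty)
      id <- id + k
    }
  }
  # type C: uniform, thinned near hotspots (spatial exclusion)
  nC <- n_hot * per_spot * 2
  yc <- runif(nC * 3, 0, dim_yx[1] - 1)
  xc <- runif(nC * 3, 0, dim_yx[2] - 1)
  dmin <- apply(sqrt(outer(yc, hot[, 1], "-")^2 + outer(xc, hot[, 2], "-")^2),
                1, min)
  keep <- which(dmin > 150)[seq_len(min(nC, sum(dmin > 150)))]
  rows[[length(rows) + 1]] <- data.frame(
    id = id:(id + length(keep) - 1), y_px = yc[keep], x_px = xc[keep],
    area = 50, cluster = "C")
  do.call(rbind, rows)
}

# small end-to-end pipeline configuration shared by pipeline and acceptance
# tests
small_run_config <- function(dir, seed = 5) {
  run_config(
    output_dir = dir,
    stages = c("phantom", "process", "segment", "cluster"),
    seed = seed,
    phantom = list(
      tile_size = 200, grid_rows = 2, grid_cols = 2, n_cycles = 3,
      cell_types = data.frame(type = c("T", "E"),
                              CD3 = c(100, 5), Cytokeratin = c(5, 100),
                              CD45 = c(80, 80), M4 = c(0, 0), M5 = c(0, 0),
                              M6 = c(0, 0)),
      n_cells = 150, min_spacing = 12,
      drift = rbind(c(0, 0), c(2.5, -1.5), c(-1, 2)),
      membrane_markers = "CD45"),
    blank_cycles = 3,
    process = list(subtract = TRUE),
    segment = list(membrane_channel = "CD45"),
    cluster = list(K = 25, exclude = c("M4", "M5", "M6")))
}

# the 59-barcode singlet-spread phantom with one planted cross-talking pair
standard_singlet_phantom <- function(seed = 5, leak_from = 17, leak_into = 42,
                                     leakage = 0.2) {
  ct <- matrix(0, 59, 59)
  ct[leak_from, leak_into] <- leakage
  cfg <- phantom_config(tile_size = 600, n_cells = 590, min_spacing = 16,
                        seed = seed, noise_sd = 1, blur_sigma = 0.8)
  generate_singlet_spread(cfg, 59, crosstalk = ct)
}
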