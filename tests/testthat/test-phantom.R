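# Synthetic phantom generator: construction guarantees and determinism.

test_that("zero-cell phantom is background plus noise with empty truth", {
  cfg <- phantom_config(tile_size = 64, n_cycles = 1, n_cells = 0,
                        background = 20, blur_sigma = 0, noise_sd = 2,
                        seed = 4)
  ph <- generate_tissue_phantom(cfg)
  expect_equal(nrow(ph$truth$cells), 0)
  img <- ph$stack$images[[1]][[1]]
  expect_equal(mean(img), 20, tolerance = 0.05)
  expect_lt(sd(as.vector(img)), 3)
})

test_that("single-cell reporter signal is conserved exactly without noise or blur", {
  cfg <- phantom_config(
    tile_size = 96, n_cycles = 1,
    cell_types = data.frame(type = "A", M = 100, N = 0),
    positions = cbind(40, 50), n_cells = 1,
    nucleus_radius = 5, nucleus_radius_sd = 0, membrane_width = 2,
    background = 0, blur_sigma = 0, noise_sd = 0, seed = 1)
  ph <- generate_tissue_phantom(cfg)
  ents <- ph$stack$map$entries[ph$stack$map$entries$cycle == 1, ]
  img <- ph$stack$images[[1]][[1]]
  m_plane <- img[, , which(ents$marker == "M")]
  n_plane <- img[, , which(ents$marker == "N")]
  mask <- m_plane > 0
  n_pix <- sum(mask)
  expect_gt(n_pix, 0)
  expect_equal(sum(m_plane[mask]), 100 * n_pix)
  expect_true(all(n_plane[mask] == 0))
  # mask size matches the analytic disk footprint within pixelization
  expect_equal(n_pix, pi * 7^2, tolerance = 0.05)
})

test_that("identical config and seed give bit-identical phantom output", {
  cfg <- phantom_config(tile_size = 96, grid_rows = 2, grid_cols = 2,
                        n_cycles = 2, n_cells = 25, seed = 9,
                        drift = rbind(c(0, 0), c(1.5, -0.75)))
  a <- generate_tissue_phantom(cfg)
  b <- generate_tissue_phantom(cfg)
  expect_identical(a$stack$images, b$stack$images)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("truth cells lie inside the mosaic with unique dense ids", {
  cfg <- phantom_config(tile_size = 128, grid_rows = 2, grid_cols = 1,
                        n_cells = 40, seed = 2)
  ph <- generate_tissue_phantom(cfg)
  dims <- c(128 + round(128 * 0.9), 128)
  tc <- ph$truth$cells
  expect_identical(tc$id, seq_len(nrow(tc)))
  expect_true(all(tc$y >= 0 & tc$y < dims[1]))
  expect_true(all(tc$x >= 0 & tc$x < dims[2]))
})

test_that("infeasible packing density fails with an explicit error", {
  cfg <- phantom_config(tile_size = 64, n_cells = 500, min_spacing = 12,
                        seed = 1)
  expect_error(generate_tissue_phantom(cfg), "spacing.*infeasible|infeasible")
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(overlap = 0.6), "overlap")
  expect_error(phantom_config(
    cell_types = data.frame(type = "A", M = -5)), "intensities")
  expect_error(phantom_config(n_cycles = 2,
                              drift = rbind(c(0, 0), c(100, 0)),
                              tile_size = 100), "drift")
  expect_error(phantom_config(crosstalk = matrix(1.5, 2, 2)), "cross-talk")
})

test_that("singlet spread schedules barcodes at up to three per cycle", {
  cfg <- phantom_config(tile_size = 200, n_cells = 59, min_spacing = 10,
                        seed = 6, blur_sigma = 0, noise_sd = 0)
  sp <- generate_singlet_spread(cfg, 59)
  expect_equal(length(sp$stack$images), ceiling(59 / 3))  # 20 cycles
  e <- sp$stack$map$entries
  per_cycle <- table(e$cycle[!e$blank & e$fluor != "Hoechst"])
  expect_true(all(per_cycle <= 3))
  expect_equal(sum(per_cycle), 59)
  # nuclear channel present every cycle
  expect_true(all(vapply(seq_len(20), function(cy)
    "Hoechst" %in% e$fluor[e$cycle == cy], logical(1))))
})

test_that("each singlet cell is positive in exactly one reporter channel", {
  cfg <- phantom_config(tile_size = 150, n_cells = 20, min_spacing = 14,
                        seed = 8, blur_sigma = 0, noise_sd = 0,
                        background = 0)
  sp <- generate_singlet_spread(cfg, 6)
  e <- sp$stack$map$entries
  tc <- sp$truth$cells
  bc <- sprintf("BC%02d", 1:6)
  for (i in seq_len(nrow(tc))) {
    on <- vapply(bc, function(b) tc[[b]][i] > 0, logical(1))
    expect_equal(sum(on), 1)
    expect_equal(names(on)[on], tc$type[i])
  }
  # pixels: each cell's footprint lights up only its own channel
  img_of <- function(marker) {
    cy <- e$cycle[e$marker == marker]
    sp$stack$images[[cy]][[1]][, , e$fluor[e$marker == marker]]
  }
  for (b in bc) {
    on_cells <- tc[tc$type == b, ]
    other <- setdiff(bc, b)
    im <- img_of(b)
    for (i in seq_len(nrow(on_cells)))
      expect_gt(im[round(on_cells$y[i]) + 1, round(on_cells$x[i]) + 1], 50)
    for (o in other) {
      imo <- img_of(o)
      for (i in seq_len(nrow(on_cells)))
        expect_equal(imo[round(on_cells$y[i]) + 1, round(on_cells$x[i]) + 1], 0)
    }
  }
})

test_that("planted cross-talk appears at the configured leakage fraction", {
  ct <- matrix(0, 4, 4)
  ct[1, 3] <- 0.1   # barcode 1 leaks into barcode 3's channel
  cfg <- phantom_config(tile_size = 180, n_cells = 40, min_spacing = 12,
                        seed = 13, blur_sigma = 0, noise_sd = 0,
                        background = 0)
  sp <- generate_singlet_spread(cfg, 4, crosstalk = ct)
  e <- sp$stack$map$entries
  tc <- sp$truth$cells
  img_of <- function(marker) {
    cy <- e$cycle[e$marker == marker]
    sp$stack$images[[cy]][[1]][, , e$fluor[e$marker == marker]]
  }
  im1 <- img_of("BC01"); im3 <- img_of("BC03")
  cells1 <- tc[tc$type == "BC01", ]
  px1 <- which(im1 > 0)
  expect_gt(length(px1), 0)
  expect_equal(mean(im3[px1]) / mean(im1[px1]), 0.1, tolerance = 0.01)
})

test_that("on/off schedule follows the repeating A, B, both, none pattern", {
  s16 <- generate_on_off_schedule(16, c("CD21", "CD3"))
  expect_equal(dim(s16), c(16L, 2L))
  expect_equal(sum(s16[, "CD21"]), 8)   # on in cycles 1 and 3 of each block
  expect_equal(sum(s16[, "CD3"]), 8)
  expect_equal(unname(s16[1:4, "CD21"]), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(s16[1:4, "CD3"]), c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(unname(s16[5:8, ]), unname(s16[1:4, ]))

  s4 <- generate_on_off_schedule(4, c("A", "B"))
  expect_equal(unname(s4), matrix(c(TRUE, FALSE, TRUE, FALSE,
                                    FALSE, TRUE, TRUE, FALSE), 4, 2))
  expect_error(generate_on_off_schedule(5, c("A", "B")), "multiple of 4")
  expect_error(generate_on_off_schedule(8, c("A")), "2 markers")
})

test_that("marker-space mixture phantom has the requested geometry", {
  mm <- simulate_marker_mixture(n = 600, n_types = 3, n_markers = 6,
                                separation = 6, seed = 2)
  expect_equal(dim(mm$features), c(600L, 6L))
  expect_equal(sort(unique(mm$labels)), 1:3)
  cents <- rowsum(mm$features, mm$labels) / as.numeric(table(mm$labels))
  # means lie `separation` sd from the origin along orthonormal directions,
  # so pairwise centre distance is separation * sqrt(2)
  expect_equal(unname(sqrt(rowSums(cents^2))), rep(6, 3), tolerance = 0.05)
  d <- as.matrix(dist(cents))
  expect_equal(mean(d[upper.tri(d)]), 6 * sqrt(2), tolerance = 0.05)
  expect_identical(simulate_marker_mixture(n = 600, n_types = 3,
                                           n_markers = 6, separation = 6,
                                           seed = 2), mm)
})
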