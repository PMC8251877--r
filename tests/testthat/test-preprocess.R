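# Registration, background subtraction, deconvolution, stitching,
# concatenation.

test_that("phase correlation recovers zero and integer shifts exactly", {
  set.seed(2)
  im <- as.matrix(EBImage::gblur(matrix(runif(96 * 96), 96), 1.2)) * 100
  r0 <- phase_cross_correlation(im, im)
  expect_equal(c(r0$dy, r0$dx), c(0, 0))
  expect_equal(r0$score, 1, tolerance = 1e-8)
  # integer circular shift: exact, and agrees with the exhaustive NCC oracle
  for (sh in list(c(3, -2), c(-5, 7), c(0, 4))) {
    mov <- int_shift(im, sh[1], sh[2])
    est <- phase_cross_correlation(im, mov, upsample = 1)
    expect_equal(c(est$dy, est$dx), sh)
    expect_equal(oracle_best_shift(im, mov, rad = 10), sh)
  }
})

test_that("subpixel shifts are recovered within 0.25 px", {
  set.seed(3)
  im <- as.matrix(EBImage::gblur(matrix(runif(128 * 128), 128), 1.5)) * 100
  for (sh in list(c(0.5, -1.25), c(2.3, 0.7), c(-0.05, 3.4))) {
    mov <- codexr:::fourier_shift(im, sh[1], sh[2]) +
      matrix(rnorm(128 * 128, 0, 1), 128)
    est <- phase_cross_correlation(im, mov, upsample = 20, window = TRUE)
    expect_lt(abs(est$dy - sh[1]), 0.25)
    expect_lt(abs(est$dx - sh[2]), 0.25)
  }
})

test_that("constant registration channel is rejected", {
  expect_error(phase_cross_correlation(matrix(5, 32, 32), matrix(5, 32, 32)),
               "registration channel empty")
})

test_that("drift estimation on a phantom recovers planted drift within 0.25 px", {
  drift <- rbind(c(0, 0), c(7.5, -8), c(-0.25, 6.75))
  ph <- drift_phantom(drift, seed = 3)
  dt <- estimate_drift(ph$stack)
  for (cy in 2:3) {
    row <- dt[dt$cycle == cy, ]
    expect_lt(abs(row$dy - drift[cy, 1]), 0.25)
    expect_lt(abs(row$dx - drift[cy, 2]), 0.25)
    expect_gt(row$score, 0.9)
  }
})

test_that("zero drift application is a bit-exact identity", {
  ph <- drift_phantom(matrix(0, 2, 2), seed = 5, tile_size = 96, n_cells = 20)
  dt <- estimate_drift(ph$stack)
  reg <- apply_drift(ph$stack, dt)
  expect_identical(reg$images, ph$stack$images)
})

test_that("integer shift then unshift restores the interior exactly", {
  set.seed(4)
  im <- matrix(runif(80 * 80) * 100, 80)
  sh <- codexr:::fourier_shift(im, 4, -3)  # circular, exact for integers
  back <- codexr:::unshift_plane(sh, 4, -3)
  interior_r <- 5:76
  interior_c <- 4:80
  expect_equal(back[interior_r, interior_c], im[interior_r, interior_c])
  # border band zeroed
  expect_true(all(back[77:80, ] == 0))
})

test_that("registration aligns phantom cycles to > 0.99 nuclear correlation", {
  drift <- rbind(c(0, 0), c(5.5, -3.25), c(-2, 4))
  ph <- drift_phantom(drift, seed = 7, noise_sd = 0)
  dt <- estimate_drift(ph$stack)
  reg <- apply_drift(ph$stack, dt)
  ref <- reg$images[[1]][[1]][, , "Hoechst"]
  interior <- 12:208
  for (cy in 2:3) {
    cyc <- reg$images[[cy]][[1]][, , "Hoechst"]
    expect_gt(cor(as.vector(ref[interior, interior]),
                  as.vector(cyc[interior, interior])), 0.99)
  }
})

make_mstack <- function(planes_by_cycle, blanks, fluor = "Cy3") {
  # single-fluor helper around the mosaic_stack layout
  n_cycles <- length(planes_by_cycle)
  entries <- do.call(rbind, lapply(seq_len(n_cycles), function(cy)
    rbind(data.frame(cycle = cy, fluor = "Hoechst",
                     marker = sprintf("Hoechst_c%d", cy), barcode = NA,
                     exposure = 0.1, blank = FALSE),
          data.frame(cycle = cy, fluor = fluor,
                     marker = if (cy %in% blanks) sprintf("blank_c%d", cy)
                              else sprintf("M%d", cy),
                     barcode = NA, exposure = 0.1,
                     blank = cy %in% blanks))))
  map <- channel_map(entries, pixel_size_um = 1)
  d <- dim(planes_by_cycle[[1]])
  planes <- lapply(planes_by_cycle, function(p) {
    arr <- array(0, c(d, 2), dimnames = list(NULL, NULL, c("Hoechst", fluor)))
    arr[, , 2] <- p
    arr
  })
  structure(list(planes = planes, map = map), class = "mosaic_stack")
}

test_that("subtracting a blank equal to the signal yields zero", {
  p <- matrix(20, 32, 32)
  ms <- make_mstack(list(p, p), blanks = 1)
  out <- subtract_background(ms)
  expect_true(all(out$planes[[2]][, , "Cy3"] == 0))
})

test_that("object over background survives subtraction; background does not", {
  bg <- matrix(20, 40, 40)
  sig <- bg
  sig[10:15, 10:15] <- sig[10:15, 10:15] + 100
  ms <- make_mstack(list(bg, sig), blanks = 1)
  out <- subtract_background(ms)
  res <- out$planes[[2]][, , "Cy3"]
  expect_true(all(res[10:15, 10:15] == 100))
  res[10:15, 10:15] <- 0
  expect_true(all(res == 0))
})

test_that("flanking blanks are interpolated by cycle index", {
  b1 <- matrix(10, 16, 16)
  b2 <- matrix(30, 16, 16)
  sig <- matrix(20, 16, 16)   # cycle 2 of 3: interpolated blank = 20
  ms <- make_mstack(list(b1, sig, b2), blanks = c(1, 3))
  out <- subtract_background(ms)
  expect_true(all(out$planes[[2]][, , "Cy3"] == 0))
})

test_that("missing blank cycle raises an instructive error", {
  ms <- make_mstack(list(matrix(1, 8, 8), matrix(1, 8, 8)), blanks = integer(0))
  expect_error(subtract_background(ms), "no blank cycle")
})

test_that("phantom blank-cycle residual is within twice the noise sd", {
  drift <- matrix(0, 3, 2)
  ph <- drift_phantom(drift, seed = 9, noise_sd = 2,
                      blank_cycles = c(1, 3))
  pr <- process_stack(ph$stack, subtract = TRUE)
  # cell-free pixels: nowhere near any truth cell
  nr <- dim(pr$mosaic)[1]
  cellfree <- matrix(TRUE, nr, dim(pr$mosaic)[2])
  tc <- ph$truth$cells
  for (i in seq_len(nrow(tc))) {
    px <- codexr:::disk_pixels(tc$y[i], tc$x[i], tc$radius[i] + 8,
                               nrow(cellfree), ncol(cellfree))
    cellfree[px] <- FALSE
  }
  for (m in attr(pr$mosaic, "dimnames")[[3]][-1]) {
    resid <- pr$mosaic[, , m][cellfree]
    expect_lte(mean(resid), 2 * 2)
  }
})

test_that("deconvolution sharpens a blurred impulse and conserves flux", {
  im <- matrix(0, 64, 64)
  im[32, 32] <- 1000
  blurred <- as.matrix(EBImage::gblur(im, 2))
  dec <- deconvolve(blurred, sigma = 2, iterations = 30)
  expect_gt(max(dec), max(blurred))
  expect_equal(sum(dec), sum(blurred), tolerance = 0.01)
  expect_true(all(dec >= 0))
  expect_error(deconvolve(blurred, sigma = 2, iterations = 0), "iterations")
  flat <- matrix(7, 32, 32)
  expect_equal(deconvolve(flat, sigma = 1, iterations = 5), flat,
               tolerance = 1e-8)
})

test_that("1x1 stitching returns the tile unchanged", {
  t1 <- matrix(runif(50 * 50), 50)
  st <- stitch(list(t1), tile_grid(1, 1, 0, 50))
  expect_equal(st$mosaic, t1)
})

test_that("2x2 tiles cut from a known image reconstruct it exactly", {
  set.seed(6)
  grid <- tile_grid(2, 2, 0.1, 220)
  step <- round(220 * 0.9)
  msz <- 220 + step
  src <- as.matrix(EBImage::gblur(matrix(runif(msz * msz), msz), 2)) * 100
  tiles <- list()
  for (r in 0:1) for (c0 in 0:1)
    tiles[[length(tiles) + 1]] <- src[r * step + 1:220, c0 * step + 1:220]
  st <- stitch(tiles, grid, refine = FALSE)
  # identical data in overlaps: blending is exact everywhere
  expect_equal(st$mosaic, src, tolerance = 1e-12)
  expect_error(stitch(c(tiles[1:3], list(matrix(0, 10, 10))), grid),
               "inconsistent tile shapes")
})

test_that("refinement recovers planted stage error within 0.5 px", {
  set.seed(6)
  grid <- tile_grid(2, 2, 0.1, 220)
  step <- round(220 * 0.9)
  msz <- 220 + step + 8
  src <- as.matrix(EBImage::gblur(matrix(runif(msz * msz), msz), 2)) * 100
  err <- rbind(c(0, 0), c(2, -1), c(-2, 2), c(1, 2))
  tiles <- list(); k <- 1
  for (r in 0:1) for (c0 in 0:1) {
    tiles[[k]] <- src[4 + r * step + err[k, 1] + 1:220,
                      4 + c0 * step + err[k, 2] + 1:220]
    k <- k + 1
  }
  st <- stitch(tiles, grid, refine = TRUE)
  nom <- rbind(c(0, 0), c(0, step), c(step, 0), c(step, step))
  true_off <- sweep(nom + err, 2, apply(nom + err, 2, min))
  expect_lte(max(abs(as.matrix(st$offsets[, c("y", "x")]) - true_off)), 0.5)
})

test_that("concatenation emits nuclear plus one plane per non-blank marker", {
  cfg <- phantom_config(tile_size = 80, n_cycles = 1, n_cells = 6,
                        min_spacing = 10, seed = 2)
  ph <- generate_tissue_phantom(cfg)    # default 2 markers in 1 cycle
  ms <- stitch_stack(ph$stack)
  mo <- concatenate_cycles(ms)
  expect_equal(dimnames(mo)[[3]], c("nuclear", "M1", "M2"))
  # duplicate marker names are rejected
  ms2 <- ms
  ms2$map$entries$marker[ms2$map$entries$marker == "M2"] <- "M1"
  expect_error(concatenate_cycles(ms2), "duplicate marker")
})

test_that("preprocessing is reproducible on identical input", {
  drift <- rbind(c(0, 0), c(1.5, -2))
  ph <- drift_phantom(drift, seed = 12, tile_size = 96, n_cells = 20)
  a <- process_stack(ph$stack, subtract = FALSE)
  b <- process_stack(ph$stack, subtract = FALSE)
  expect_identical(a$mosaic, b$mosaic)
  expect_identical(a$drift, b$drift)
  expect_true(any(grepl("stitch_stack", attr(a$mosaic, "provenance"))))
})
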