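# Follicle rings, regional composition, windowed density correlation.

disk_mask <- function(nr, nc, cy, cx, r, label = 1L) {
  m <- matrix(0L, nr, nc)
  m[codexr:::disk_pixels(cy, cx, r, nr, nc)] <- label
  m
}

test_that("factor 1.0 gives an empty ring; default geometry is analytic", {
  mask <- disk_mask(200, 200, 100, 100, 50)
  # two cells at diametrically opposite boundary points: D = 2r = 100
  tb <- data.frame(id = 1:2, y_px = c(50, 150), x_px = c(100, 100), area = 40,
                   cluster = "A")
  ring0 <- follicle_ring(mask, tb, factor = 1.0)
  expect_true(all(ring0 == 0))
  ring <- follicle_ring(mask, tb, factor = 1.2)
  # dilation radius 0.2 * 100 / 2 = 10: ring area ~ pi(60^2 - 50^2)
  expect_equal(sum(ring == 1), pi * (60^2 - 50^2), tolerance = 0.05)
  expect_true(all(ring[mask == 1] == 0))
  # rings are clipped at other follicles
  mask2 <- mask
  mask2[codexr:::disk_pixels(100, 165, 8, 200, 200)] <- 2L
  ring2 <- follicle_ring(mask2, rbind(tb,
    data.frame(id = 3:4, y_px = c(95, 105), x_px = c(165, 165), area = 40,
               cluster = "A")), factor = 1.2)
  expect_true(all(ring2[mask2 == 2] == 0))
})

test_that("a follicle with fewer than two cells is skipped with a warning", {
  mask <- disk_mask(80, 80, 40, 40, 20)
  tb <- data.frame(id = 1, y_px = 40, x_px = 40, area = 40, cluster = "A")
  expect_warning(ring <- follicle_ring(mask, tb), "fewer than 2")
  expect_true(all(ring == 0))
})

test_that("composition counts centroids inside regions", {
  mask <- disk_mask(120, 120, 60, 60, 30)
  tb <- data.frame(id = 1:30,
                   y_px = runif(30, 45, 75), x_px = runif(30, 45, 75),
                   area = 40, cluster = "A")
  cp <- composition(tb, mask)
  expect_equal(unname(cp$tissue_average["A"]), 1)
  # two follicles with opposite pure types average to (0.5, 0.5)
  mask2 <- disk_mask(120, 240, 60, 60, 25) +
           disk_mask(120, 240, 60, 180, 25) * 2L
  tb2 <- data.frame(id = 1:20,
                    y_px = 60, x_px = c(rep(60, 10), rep(180, 10)), area = 40,
                    cluster = rep(c("A", "B"), each = 10))
  cp2 <- composition(tb2, mask2)
  expect_equal(unname(cp2$tissue_average), c(0.5, 0.5))
  expect_equal(cp2$per_region$freq[cp2$per_region$region == 1 &
                                   cp2$per_region$type == "A"], 1)
  # empty region warns and reports zeros
  mask3 <- disk_mask(120, 120, 20, 20, 10, label = 1L)
  expect_warning(cp3 <- composition(tb, mask3), "no cells")
  expect_equal(sum(cp3$per_region$count), 0)
})

test_that("planted 70/30 follicle composition is recovered within 3 points", {
  set.seed(19)
  mask <- disk_mask(400, 400, 200, 200, 150)
  n <- 500
  th <- runif(n) * 2 * pi
  rr <- 150 * sqrt(runif(n))
  types <- sample(rep(c("B", "T"), c(350, 150)))   # 70/30 planted exactly
  tb <- data.frame(id = 1:n, y_px = 200 + rr * sin(th),
                   x_px = 200 + rr * cos(th), area = 40, cluster = types)
  cp <- composition(tb, mask)
  expect_lte(abs(unname(cp$tissue_average["B"]) - 0.7), 0.03)
  expect_equal(sum(cp$tissue_average), 1)
})

test_that("windowed sampling matches the Poisson expectation", {
  set.seed(23)
  lambda_per_px <- 600 / (600 * 600)
  n <- 600
  tb <- data.frame(id = 1:n, y_px = runif(n, 0, 600), x_px = runif(n, 0, 600),
                   area = 40, cluster = "A")
  counts <- sample_density(tb, c(600, 600), window = 100, n_windows = 500,
                           seed = 7)
  lambda <- lambda_per_px * 100 * 100
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 500))
  # reproducible under the seed; empty table gives zeros
  counts2 <- sample_density(tb, c(600, 600), window = 100, n_windows = 500,
                            seed = 7)
  expect_identical(counts, counts2)
  tb0 <- tb[0, ]
  c0 <- sample_density(tb0, c(600, 600), window = 100, n_windows = 20,
                       seed = 1)
  expect_true(all(c0 == 0))
  expect_error(sample_density(tb, c(50, 600), window = 100, n_windows = 20),
               "smaller than the window")
})

test_that("masked domains restrict windows to lie fully inside", {
  set.seed(29)
  mask <- matrix(0L, 400, 400)
  mask[51:250, 51:250] <- 1L
  tb <- data.frame(id = 1:100, y_px = runif(100, 0, 400),
                   x_px = runif(100, 0, 400), area = 40, cluster = "A")
  counts <- sample_density(tb, dim(mask), window = 100, n_windows = 50,
                           mask = mask, seed = 3)
  org <- attr(counts, "origins")
  expect_true(all(org[, "y"] >= 50 & org[, "y"] + 100 <= 250))
  expect_true(all(org[, "x"] >= 50 & org[, "x"] + 100 <= 250))
})

test_that("Spearman matrix equals the brute-force rank oracle", {
  set.seed(31)
  counts <- matrix(rpois(20 * 4, 5), 20, 4,
                   dimnames = list(NULL, letters[1:4]))
  dc <- density_correlation(counts)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(dc$rho[i, j], oracle_spearman(counts[, i], counts[, j]),
                 tolerance = 1e-12)
  expect_equal(dc$rho, t(dc$rho))
  expect_equal(unname(diag(dc$rho)), rep(1, 4))
})

test_that("Spearman edge cases: identity, reversal, known value, ties", {
  base <- matrix(c(1:12, 12:1), 12, 2, dimnames = list(NULL, c("a", "b")))
  dc <- density_correlation(cbind(base, c = base[, "a"]))
  expect_equal(dc$rho["a", "c"], 1)
  expect_equal(dc$rho["a", "b"], -1)
  x <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5, 2, 1, 4, 3, 5)
  dc2 <- density_correlation(cbind(a = x, b = y))
  # rank differences d^2 sum to 4 per block: rho = 1 - 6*4/(5*24) = 0.8,
  # confirmed by the brute-force rank oracle
  expect_equal(dc2$rho["a", "b"], oracle_spearman(x, y))
  expect_equal(dc2$rho["a", "b"], 0.8)
  # zero-variance type flagged and reported as 0
  cz <- cbind(a = rpois(15, 4), b = rep(3, 15))
  expect_equal(density_correlation(cz)$rho["a", "b"], 0)
  expect_true(density_correlation(cz)$zero_variance["b"])
  expect_error(density_correlation(matrix(1, 5, 2)), "at least 10")
  expect_error(density_correlation(matrix(1, 15, 1)), "at least 2")
})

test_that("co-localized and excluded cell types show the planted sign pattern", {
  tb <- colocalization_table()
  counts <- sample_density(tb, c(1200, 1200), window = 100, n_windows = 500,
                           seed = 11)
  dc <- density_correlation(counts)
  expect_gte(dc$rho["A", "B"], 0.5)
  expect_lte(dc$rho["A", "C"], -0.3)
  expect_lte(dc$rho["B", "C"], -0.3)
  # dendrogram order puts the co-localized pair adjacent
  ord <- colnames(dc$rho)[dc$order]
  expect_equal(abs(which(ord == "A") - which(ord == "B")), 1)
})

test_that("doubling the window count shrinks the standard error as expected", {
  set.seed(37)
  n <- 800
  tb <- data.frame(id = 1:n, y_px = runif(n, 0, 600), x_px = runif(n, 0, 600),
                   area = 40, cluster = "A")
  se_of <- function(nw, seed) {
    counts <- sample_density(tb, c(600, 600), window = 100, n_windows = nw,
                             seed = seed)
    sd(counts[, 1]) / sqrt(nw)
  }
  se1 <- mean(vapply(1:8, function(s) se_of(250, s), numeric(1)))
  se2 <- mean(vapply(1:8, function(s) se_of(500, s + 100), numeric(1)))
  expect_equal(se2 / se1, 1 / sqrt(2), tolerance = 0.3)
})

test_that("heatmap export writes a file", {
  set.seed(41)
  counts <- matrix(rpois(30 * 3, 5), 30, 3, dimnames = list(NULL, c("A", "B", "C")))
  dc <- density_correlation(counts)
  f <- withr::local_tempfile(fileext = ".png")
  plot_density_heatmap(dc, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
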