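#' Spatial analyses: follicle composition and windowed density correlation
#'
#' Cells are treated as points (their segmentation centroids) for all region
#' membership tests. Follicle masks are inputs (drawn from e.g. CD19
#' expression); a surrounding ring is derived per follicle, and cell-type
#' frequencies are compared inside versus around each follicle. Local
#' cell-type densities are sampled in randomly placed square windows and
#' correlated pairwise by Spearman's rank correlation.
#'
#' @name spatial
NULL

#' Derive the surrounding ring of each follicle
#'
#' For each labeled follicle, `D` is the maximum pairwise centroid distance
#' among the cells inside its mask; the ring is the set of pixels outside the
#' mask but within Euclidean distance `(factor - 1) * D / 2` of it, so the
#' follicle-plus-ring extent scales to `factor * D`. Rings are clipped at
#' image borders and at other follicles' masks. `factor = 1` yields empty
#' rings. Follicles with fewer than 2 cells are skipped with a warning.
#'
#' @param mask integer matrix, 0 outside, k inside follicle k (labels dense
#'   1..F, non-overlapping).
#' @param table cell table with `y_px`, `x_px`.
#' @param factor ring scale factor (default 1.2).
#' @return integer matrix of ring labels (0 or follicle label).
#' @export
follicle_ring <- function(mask, table, factor = 1.2) {
  stopifnot(factor >= 1)
  labels <- setdiff(sort(unique(as.vector(mask))), 0)
  ring <- matrix(0L, nrow(mask), ncol(mask))
  any_mask <- mask > 0
  for (k in labels) {
    inside <- cells_in_region(table, mask, k)
    if (nrow(inside) < 2) {
      warning("follicle ", k, " has fewer than 2 cells; ring skipped")
      next
    }
    D <- max(stats::dist(inside[, c("y_px", "x_px")]))
    r <- (factor - 1) * D / 2
    if (r <= 0) next
    outside_dist <- as.matrix(EBImage::distmap(mask != k))
    sel <- !any_mask & outside_dist > 0 & outside_dist <= r
    ring[sel & ring == 0L] <- k
  }
  ring
}

# rows of `table` whose centroid pixel lies in region k of `mask`
cells_in_region <- function(table, mask, k) {
  iy <- floor(table$y_px) + 1L
  ix <- floor(table$x_px) + 1L
  ok <- iy >= 1 & iy <= nrow(mask) & ix >= 1 & ix <= ncol(mask)
  sel <- ok
  sel[ok] <- mask[cbind(iy[ok], ix[ok])] == k
  table[sel, , drop = FALSE]
}

#' Cell-type composition inside regions
#'
#' A cell belongs to a region iff its centroid pixel lies inside the region's
#' mask. Frequencies are counts divided by the region total; the tissue-level
#' average is the unweighted mean of per-follicle frequency vectors. Empty
#' regions are reported as all-zero with count 0 and a warning.
#'
#' @param table cell table with a `cluster` (or `type`) column.
#' @param mask labeled region mask.
#' @param type_col column holding the cell-type label.
#' @return list with `per_region` (data.frame region, type, count, freq),
#'   `tissue_average` (named frequency vector) and `totals` (cells per
#'   region).
#' @export
composition <- function(table, mask, type_col = "cluster") {
  if (!type_col %in% names(table)) stop("missing cell-type column: ", type_col)
  regions <- setdiff(sort(unique(as.vector(mask))), 0)
  types <- sort(unique(table[[type_col]]))
  rows <- list()
  freqs <- matrix(NA_real_, length(regions), length(types),
                  dimnames = list(regions, types))
  totals <- stats::setNames(integer(length(regions)), regions)
  for (i in seq_along(regions)) {
    k <- regions[i]
    inside <- cells_in_region(table, mask, k)
    cnt <- table(factor(inside[[type_col]], levels = types))
    tot <- sum(cnt)
    totals[i] <- tot
    if (tot == 0) {
      warning("region ", k, " contains no cells; frequencies reported as 0")
      fr <- rep(0, length(types))
    } else {
      fr <- as.numeric(cnt) / tot
    }
    freqs[i, ] <- fr
    rows[[i]] <- data.frame(region = k, type = types,
                            count = as.integer(cnt), freq = fr)
  }
  nonempty <- totals > 0
  tissue <- if (any(nonempty)) colMeans(freqs[nonempty, , drop = FALSE])
            else stats::setNames(rep(0, length(types)), types)
  list(per_region = do.call(rbind, rows), tissue_average = tissue,
       totals = totals)
}

#' Sample per-window cell-type counts
#'
#' Draws `n_windows` square windows of side `window` px whose full extent
#' lies inside the domain (the whole image, or the union of mask regions when
#' a mask is given), uniformly at random with replacement (windows may
#' overlap), and counts cells of each type whose centroid falls in each
#' window.
#'
#' @param table cell table with `y_px`, `x_px` and a type column.
#' @param dim_yx image dimensions c(rows, cols) in px.
#' @param window window side in px (>= 10).
#' @param n_windows number of windows (>= 10).
#' @param mask optional domain mask (any label > 0 is inside).
#' @param seed RNG seed.
#' @param type_col cell-type column.
#' @return integer count matrix (n_windows x types) with attribute `origins`
#'   (window top-left corners, 0-based).
#' @export
sample_density <- function(table, dim_yx, window = 100L, n_windows = 500L,
                           mask = NULL, seed = 1L, type_col = "cluster") {
  stopifnot(window >= 10, n_windows >= 10)
  if (any(dim_yx < window)) stop("domain is smaller than the window")
  types <- sort(unique(table[[type_col]]))
  with_seed(seed, {
    if (is.null(mask)) {
      oy <- sample.int(dim_yx[1] - window + 1L, n_windows, replace = TRUE) - 1L
      ox <- sample.int(dim_yx[2] - window + 1L, n_windows, replace = TRUE) - 1L
    } else {
      # valid origins: window fully inside the mask union (integral image)
      m <- (mask > 0) * 1L
      nr <- nrow(m); nc <- ncol(m)
      S <- matrix(0, nr + 1L, nc + 1L)
      S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
      oy_all <- seq_len(nr - window + 1L)   # 1-based candidate origins
      ox_all <- seq_len(nc - window + 1L)
      area <- S[oy_all + window, ox_all + window, drop = FALSE] -
              S[oy_all, ox_all + window, drop = FALSE] -
              S[oy_all + window, ox_all, drop = FALSE] +
              S[oy_all, ox_all, drop = FALSE]
      valid <- which(area == window^2)
      if (!length(valid)) stop("domain is smaller than the window")
      pick <- valid[sample.int(length(valid), n_windows, replace = TRUE)]
      oy <- oy_all[(pick - 1L) %% length(oy_all) + 1L] - 1L   # 0-based
      ox <- ox_all[(pick - 1L) %/% length(oy_all) + 1L] - 1L
    }
    counts <- matrix(0L, n_windows, length(types),
                     dimnames = list(NULL, types))
    ty <- factor(table[[type_col]], levels = types)
    for (w in seq_len(n_windows)) {
      sel <- table$y_px >= oy[w] & table$y_px < oy[w] + window &
             table$x_px >= ox[w] & table$x_px < ox[w] + window
      counts[w, ] <- as.integer(table(ty[sel]))
    }
    attr(counts, "origins") <- cbind(y = oy, x = ox)
    counts
  })
}

#' Spearman correlation of windowed cell-type densities
#'
#' Pairwise Spearman rank correlation (average-rank tie handling) over the
#' per-window count matrix. Zero-variance types get correlation 0 with a
#' flag. Display order comes from average-linkage hierarchical clustering of
#' `1 - rho`.
#'
#' @param counts count matrix from [sample_density()] (windows x types).
#' @return list with `rho` (symmetric matrix, unit diagonal), `order`
#'   (dendrogram display order of the types) and `zero_variance` (logical
#'   vector flagging degenerate types).
#' @export
density_correlation <- function(counts) {
  if (nrow(counts) < 10) stop("at least 10 windows are required")
  if (ncol(counts) < 2) stop("at least 2 cell types are required")
  zv <- apply(counts, 2, function(x) stats::var(x) == 0)
  rho <- suppressWarnings(stats::cor(counts, method = "spearman"))
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  ord <- if (ncol(counts) > 2) {
    stats::hclust(stats::as.dist(1 - rho), method = "average")$order
  } else seq_len(ncol(counts))
  list(rho = rho, order = ord, zero_variance = zv)
}

#' Export a red-to-green density-correlation heatmap
#'
#' Writes a PNG of the Spearman matrix in dendrogram order, red
#' (anticorrelated) through black to green (correlated).
#'
#' @param dc result of [density_correlation()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_density_heatmap <- function(dc, path) {
  ord <- dc$order
  M <- dc$rho[ord, ord, drop = FALSE]
  pal <- grDevices::colorRampPalette(c("red", "black", "green"))(101)
  grDevices::png(path, width = 640, height = 640)
  op <- graphics::par(mar = c(6, 6, 2, 1))
  graphics::image(seq_len(ncol(M)), seq_len(nrow(M)),
                  t(M[rev(seq_len(nrow(M))), , drop = FALSE]),
                  col = pal, zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, seq_len(ncol(M)), colnames(M), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(M)), rev(rownames(M)), las = 2, cex.axis = 0.8)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Convenience automatic follicle mask from a marker plane
#'
#' Threshold (Otsu) a chosen marker plane (e.g. CD19), morphologically close
#' and open with a disc, and label connected components. Manual masks remain
#' the primary input; this is a convenience only.
#'
#' @param plane numeric matrix of the marker used to define regions.
#' @param brush_size disc diameter for closing/opening (odd integer).
#' @param min_area minimum region area in px.
#' @return labeled integer mask.
#' @export
auto_follicle_mask <- function(plane, brush_size = 15L, min_area = 500) {
  fg <- plane > otsu_threshold(plane)
  br <- EBImage::makeBrush(brush_size, "disc")
  cl <- EBImage::opening(EBImage::closing(fg, br), br)
  lab <- EBImage::bwlabel(cl)
  areas <- tabulate(as.integer(lab[lab > 0]))
  keep <- which(areas >= min_area)
  m <- matrix(0L, nrow(plane), ncol(plane))
  m[as.matrix(lab) %in% keep] <- match(as.matrix(lab)[as.matrix(lab) %in% keep], keep)
  m
}
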