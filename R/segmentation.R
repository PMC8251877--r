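#' Watershed single-cell segmentation and per-cell quantification
#'
#' The segmenter follows the classic nuclear-seeded watershed construction:
#' Gaussian-smooth the nuclear plane, threshold foreground (Otsu by default),
#' take the Euclidean distance transform, seed at its local maxima subject to
#' a minimum seed distance, and flood the elevation map
#' `-distance + membrane_weight * normalized membrane gradient` inside the
#' foreground. An optional membrane channel (e.g. CD45) sharpens boundaries
#' between touching cells. Segmentation uses no randomness and is fully
#' deterministic.
#'
#' @name segmentation
NULL

#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian smoothing sigma for the nuclear plane (px).
#' @param threshold `"otsu"` or a fixed numeric threshold on the smoothed
#'   nuclear plane.
#' @param min_seed_distance minimum distance between watershed seeds (px,
#'   >= 1).
#' @param membrane_weight weight of the normalized membrane gradient in the
#'   elevation map, in \[0, 1\].
#' @param min_area,max_area size filter in px (labels outside are dropped).
#' @return a `seg_params` list.
#' @export
seg_params <- function(smooth_sigma = 1.5, threshold = "otsu",
                       min_seed_distance = 5, membrane_weight = 0.3,
                       min_area = 20, max_area = 10000) {
  stopifnot(min_seed_distance >= 1, min_area < max_area,
            membrane_weight >= 0, membrane_weight <= 1)
  list(smooth_sigma = smooth_sigma, threshold = threshold,
       min_seed_distance = min_seed_distance,
       membrane_weight = membrane_weight,
       min_area = min_area, max_area = max_area)
}

# Sobel gradient magnitude, scaled to [0, 1]
gradient_magnitude <- function(m) {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(m, sx))
  gy <- as.matrix(EBImage::filter2(m, t(sx)))
  g <- sqrt(gx^2 + gy^2)
  mx <- max(g)
  if (mx > 0) g / mx else g
}

# Local maxima of the distance map with greedy minimum-distance suppression.
# Plateaus (h-maxima at depth 1 and exact ties) are broken toward the lowest
# (y, x) pixel for determinism.
find_seeds <- function(dist, min_dist) {
  brush_size <- 2L * as.integer(ceiling(min_dist)) + 1L
  mx <- as.matrix(EBImage::dilate(dist, EBImage::makeBrush(brush_size, "disc")))
  cand <- which(dist >= mx - 1e-9 & dist >= 1)
  if (!length(cand)) return(NULL)
  nr <- nrow(dist)
  cy <- (cand - 1L) %% nr
  cx <- (cand - 1L) %/% nr
  ord <- order(-dist[cand], cy, cx)
  keep_y <- numeric(0); keep_x <- numeric(0)
  for (i in ord) {
    if (!length(keep_y) ||
        min((keep_y - cy[i])^2 + (keep_x - cx[i])^2) >= min_dist^2) {
      keep_y <- c(keep_y, cy[i]); keep_x <- c(keep_x, cx[i])
    }
  }
  cbind(y = keep_y, x = keep_x)
}

#' Segment cells from a nuclear plane (optionally aided by a membrane plane)
#'
#' @param nuclear numeric matrix, registered nuclear-stain plane.
#' @param membrane optional numeric matrix of a membrane marker, same shape.
#' @param params a [seg_params()].
#' @return integer label matrix (0 = background), labels dense `1..N`, each
#'   region 4-connected; attribute `n_cells` gives N. All-background input
#'   yields 0 cells with a warning.
#' @export
segment_cells <- function(nuclear, membrane = NULL, params = seg_params()) {
  if (!is.null(membrane) && !all(dim(membrane) == dim(nuclear)))
    stop("nuclear and membrane planes must share dimensions")
  sm <- if (params$smooth_sigma > 0)
    as.matrix(EBImage::gblur(nuclear, sigma = params$smooth_sigma))
  else nuclear
  thr <- if (identical(params$threshold, "otsu")) otsu_threshold(sm)
         else as.numeric(params$threshold)
  fg <- sm > thr
  if (!any(fg)) {
    warning("no foreground after threshold; returning 0 cells")
    out <- matrix(0L, nrow(nuclear), ncol(nuclear))
    attr(out, "n_cells") <- 0L
    return(out)
  }
  dist <- as.matrix(EBImage::distmap(fg))
  seeds_yx <- find_seeds(dist, params$min_seed_distance)
  if (is.null(seeds_yx)) {
    warning("no watershed seeds found; returning 0 cells")
    out <- matrix(0L, nrow(nuclear), ncol(nuclear))
    attr(out, "n_cells") <- 0L
    return(out)
  }
  seeds <- matrix(0L, nrow(nuclear), ncol(nuclear))
  seeds[cbind(seeds_yx[, "y"] + 1L, seeds_yx[, "x"] + 1L)] <-
    seq_len(nrow(seeds_yx))
  elev <- -dist
  if (!is.null(membrane) && params$membrane_weight > 0) {
    elev <- elev + params$membrane_weight * max(dist) *
      gradient_magnitude(membrane)
  }
  lab <- watershed_flood(elev, seeds, fg)
  # size filter, then dense relabel in first-pixel order
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  lab[!(lab %in% keep)] <- 0L
  relab <- integer(max(lab, 1L))
  relab[sort(unique(lab[lab > 0]))] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  attr(lab, "n_cells") <- length(keep)
  lab
}

#' Quantify segmented cells over a marker mosaic
#'
#' Per cell: mean intensity over the cell's pixels in every marker plane,
#' unweighted pixel centroid (0-based px, and mm via the pixel size), and
#' area in px.
#'
#' @param labels integer label matrix from [segment_cells()].
#' @param mosaic a `codex_mosaic` ([concatenate_cycles()]) or plain
#'   (y, x, plane) array with plane dimnames.
#' @param pixel_size_um micrometres per pixel (default from the mosaic
#'   attribute).
#' @return cell table data.frame: id, y_px, x_px, y_mm, x_mm, area, one
#'   column per plane; attribute `markers` lists the non-nuclear planes.
#' @export
quantify_cells <- function(labels, mosaic,
                           pixel_size_um = attr(mosaic, "pixel_size_um")) {
  if (!all(dim(labels) == dim(mosaic)[1:2]))
    stop("labels and mosaic planes must share spatial dimensions")
  n <- max(labels)
  planes <- dimnames(mosaic)[[3]]
  pix <- which(labels > 0)
  lb <- labels[pix]
  nr <- nrow(labels)
  y0 <- (pix - 1L) %% nr       # 0-based row
  x0 <- (pix - 1L) %/% nr      # 0-based col
  area <- tabulate(lb, n)
  tb <- data.frame(id = seq_len(n),
                   y_px = as.numeric(rowsum(y0, lb)) / area,
                   x_px = as.numeric(rowsum(x0, lb)) / area,
                   area = area)
  tb$y_mm <- tb$y_px * (pixel_size_um %||% 1) / 1000
  tb$x_mm <- tb$x_px * (pixel_size_um %||% 1) / 1000
  for (p in planes) {
    v <- mosaic[, , p][pix]
    tb[[p]] <- as.numeric(rowsum(v, lb)) / area
  }
  attr(tb, "markers") <- setdiff(planes, "nuclear")
  validate_cell_table(tb)
  tb
}

#' Gate a cell population on one marker's intensity
#'
#' @param table cell table.
#' @param marker marker column name.
#' @param threshold lower threshold (cells with intensity > threshold pass),
#'   or a length-2 interval `c(lo, hi)` gating `lo < x <= hi`.
#' @return the subset of rows passing the gate (spatial columns retained).
#' @export
gate_population <- function(table, marker, threshold) {
  if (!marker %in% names(table)) stop("unknown marker: ", marker)
  x <- table[[marker]]
  sel <- if (length(threshold) == 2) x > threshold[1] & x <= threshold[2]
         else x > threshold
  table[sel, , drop = FALSE]
}

#' Match segmented cells to ground-truth cells by nearest centroid
#'
#' Greedy one-to-one matching within `max_dist` px, used to score detection
#' against phantom truth.
#'
#' @param table cell table (detected).
#' @param truth_cells phantom truth cell data.frame (columns y, x).
#' @param max_dist maximum centroid distance for a match (px).
#' @return list with `matches` (data.frame id, truth_id, dist), `f1`,
#'   `precision`, `recall` and `mean_centroid_error`.
#' @export
match_to_truth <- function(table, truth_cells, max_dist = 5) {
  nd <- nrow(table); nt <- nrow(truth_cells)
  if (nd == 0 || nt == 0) {
    return(list(matches = data.frame(), f1 = 0, precision = 0, recall = 0,
                mean_centroid_error = NA_real_))
  }
  D <- outer(table$y_px, truth_cells$y, "-")^2 +
       outer(table$x_px, truth_cells$x, "-")^2
  D <- sqrt(D)
  matches <- data.frame(id = integer(0), truth_id = integer(0),
                        dist = numeric(0))
  used_d <- rep(FALSE, nd); used_t <- rep(FALSE, nt)
  ord <- order(D)
  for (k in ord) {
    if (D[k] > max_dist) break
    i <- (k - 1L) %% nd + 1L
    j <- (k - 1L) %/% nd + 1L
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    matches <- rbind(matches, data.frame(id = table$id[i],
                                         truth_id = truth_cells$id[j],
                                         dist = D[k]))
  }
  tp <- nrow(matches)
  precision <- tp / nd
  recall <- tp / nt
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(matches = matches, f1 = f1, precision = precision, recall = recall,
       mean_centroid_error = if (tp) mean(matches$dist) else NA_real_)
}
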