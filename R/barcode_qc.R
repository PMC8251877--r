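#' Barcode orthogonality and cycle-chemistry QC
#'
#' Quantifies how cleanly each DNA barcode reports its own channel: the
#' top-3 rank image (blue/green/red = highest/second/third pixel intensity
#' across all reporter planes), per-barcode positive-cell gating, the
#' pairwise intersection-over-union matrix, and on/off cycle reproducibility
#' statistics for annealing/stripping chemistry.
#'
#' @name barcode_qc
#' @importFrom mclust Mclust mclustBIC
NULL

#' Top-3 rank image across reporter planes
#'
#' Per pixel, the reporter planes are sorted by intensity; the top three
#' values form the blue/green/red planes (ties broken by plane order). The
#' dominance fraction summarises how often the strongest channel exceeds the
#' runner-up by at least `dominance_ratio` (orthogonal barcodes make most
#' pixels strongly rank-1 dominated).
#'
#' @param planes numeric array (y, x, plane) of >= 3 registered reporter
#'   planes, or a list of matrices.
#' @param dominance_ratio ratio rank-1/rank-2 defining a dominant pixel.
#' @return list with `blue`, `green`, `red` matrices (rank-1..3 intensity),
#'   `argmax` (plane index of the rank-1 channel) and `dominance_fraction`.
#' @export
rank_image <- function(planes, dominance_ratio = 2) {
  if (is.list(planes)) planes <- simplify2array(planes)
  np <- dim(planes)[3]
  if (is.na(np) || np < 3) stop("at least 3 reporter planes are required")
  d <- dim(planes)[1:2]
  top1 <- matrix(-Inf, d[1], d[2]); top2 <- top1; top3 <- top1
  arg1 <- matrix(0L, d[1], d[2])
  for (k in seq_len(np)) {
    v <- planes[, , k]
    n1 <- v > top1                 # strict: ties keep the earlier plane
    n2 <- !n1 & v > top2
    n3 <- !n1 & !n2 & v > top3
    top3[n3] <- v[n3]
    top3[n2] <- top2[n2]; top2[n2] <- v[n2]
    top3[n1] <- top2[n1]; top2[n1] <- top1[n1]
    top1[n1] <- v[n1]; arg1[n1] <- k
  }
  stopifnot(all(top1 >= top2), all(top2 >= top3))
  dom <- mean(top1 >= dominance_ratio * pmax(top2, .Machine$double.eps))
  list(blue = top1, green = top2, red = top3, argmax = arg1,
       dominance_fraction = dom)
}

#' Gate barcode-positive cells
#'
#' Default method fits a 2-component 1D Gaussian mixture to `log1p`
#' intensities; positives are cells whose posterior for the upper component
#' exceeds 0.5. Degenerate (effectively unimodal) distributions fall back to
#' an Otsu threshold with a warning. A fixed threshold is supported for
#' reproducibility.
#'
#' @param table cell table.
#' @param channel marker/barcode column name.
#' @param method `"gmm"`, `"otsu"`, or `"fixed"`.
#' @param threshold numeric threshold for `method = "fixed"` (cells with
#'   intensity > threshold are positive).
#' @return integer vector of positive cell ids.
#' @export
gate_barcode_positive <- function(table, channel,
                                  method = c("gmm", "otsu", "fixed"),
                                  threshold = NULL) {
  method <- match.arg(method)
  if (!channel %in% names(table)) stop("unknown channel: ", channel)
  if (method != "fixed" && nrow(table) < 10)
    stop("at least 10 cells are required for automated gating")
  x <- table[[channel]]
  pos <- switch(method,
    fixed = {
      if (is.null(threshold)) stop("fixed gating needs a threshold")
      x > threshold
    },
    otsu = x > otsu_threshold(x),
    gmm = {
      lx <- log1p(x)
      if (stats::sd(lx) == 0) {
        warning("degenerate intensity distribution for ", channel,
                "; falling back to Otsu")
        lx > otsu_threshold(lx)
      } else {
        fit <- tryCatch(
          suppressWarnings(Mclust(lx, G = 2, modelNames = "V",
                                  verbose = FALSE)),
          error = function(e) NULL)
        if (is.null(fit) || length(unique(fit$classification)) < 2) {
          warning("unimodal intensity distribution for ", channel,
                  "; falling back to Otsu")
          lx > otsu_threshold(lx)
        } else {
          upper <- which.max(fit$parameters$mean)
          # a low outlier of the tight background component can get a high
          # posterior under the wide upper component; positives must also
          # lie above the background mean
          fit$z[, upper] > 0.5 & lx > min(fit$parameters$mean)
        }
      }
    })
  table$id[pos]
}

#' Intersection-over-union matrix of barcode-positive cell sets
#'
#' `IoU(i, j) = |A_i intersect A_j| / |A_i union A_j|`; the diagonal is 1 by
#' convention, and a pair of empty sets is defined as 0 with a warning (keeps
#' heatmaps renderable). The matrix is symmetric and invariant to cell-id
#' relabeling.
#'
#' @param sets named list of cell-id vectors, one per barcode.
#' @return symmetric numeric matrix in \[0, 1\].
#' @export
iou_matrix <- function(sets) {
  if (length(sets) < 2) stop("at least 2 barcode sets are required")
  n <- length(sets)
  M <- diag(1, n)
  dimnames(M) <- list(names(sets), names(sets))
  warned <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    u <- length(union(sets[[i]], sets[[j]]))
    if (u == 0) {
      if (!warned) {
        warning("empty union for at least one barcode pair; IoU set to 0")
        warned <- TRUE
      }
      v <- 0
    } else {
      v <- length(intersect(sets[[i]], sets[[j]])) / u
    }
    M[i, j] <- v
    M[j, i] <- v
  }
  M
}

#' On/off cycle reproducibility statistics
#'
#' For each marker, given its per-cycle mean on-target intensity and the
#' on/off schedule: the first-on-cycle intensity is the reference signal;
#' the reproducibility deviation is the maximum relative deviation of later
#' on-cycles from it, `max |I_c - I_1| / I_1`; carryover is the mean off-cycle
#' intensity as a fraction of the reference (off-cycles measure stripping
#' efficiency). Both are compared against a configurable bound (default 0.20).
#'
#' @param trace numeric matrix (cycles x markers) of mean on-target
#'   intensities, columns named by marker.
#' @param schedule logical matrix from [generate_on_off_schedule()] (same
#'   dimensions).
#' @param bound acceptance bound on the reproducibility deviation.
#' @return data.frame per marker: `marker`, `on_mean`, `first_on`,
#'   `deviation`, `carryover`, `pass`.
#' @export
cycle_reproducibility <- function(trace, schedule, bound = 0.20) {
  trace <- as.matrix(trace)
  if (!all(dim(trace) == dim(schedule)))
    stop("trace and schedule must share dimensions (cycles x markers)")
  markers <- colnames(schedule) %||% colnames(trace) %||%
    paste0("marker", seq_len(ncol(trace)))
  out <- lapply(seq_len(ncol(trace)), function(j) {
    on <- trace[schedule[, j], j]
    off <- trace[!schedule[, j], j]
    if (length(on) == 0 || on[1] <= 0)
      stop("marker ", markers[j],
           " has no usable on-cycle signal (first on-cycle must be > 0)")
    dev <- if (length(on) > 1) max(abs(on[-1] - on[1]) / on[1]) else 0
    carry <- if (length(off)) mean(off) / on[1] else 0
    data.frame(marker = markers[j], on_mean = mean(on), first_on = on[1],
               deviation = dev, carryover = carry, pass = dev <= bound)
  })
  do.call(rbind, out)
}

#' End-to-end barcode QC from a singlet-spread cell table
#'
#' Gates every barcode channel and assembles the IoU matrix.
#'
#' @param table cell table with one intensity column per barcode.
#' @param barcodes barcode column names (default: attribute `markers`).
#' @param method,threshold passed to [gate_barcode_positive()].
#' @return list with `iou` (matrix) and `sets` (gated positives per barcode).
#' @export
barcode_iou <- function(table, barcodes = attr(table, "markers"),
                        method = "gmm", threshold = NULL) {
  sets <- lapply(barcodes, function(b)
    gate_barcode_positive(table, b, method = method, threshold = threshold))
  names(sets) <- barcodes
  list(iou = iou_matrix(sets), sets = sets)
}
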