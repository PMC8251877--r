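# Internal numerical helpers shared across modules.

#' @useDynLib codexr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# DFT sample frequencies (cycles/sample), numpy-style ordering.
fft_freq <- function(n) {
  half <- ceiling(n / 2)
  c(0:(half - 1), seq.int(half - n, -1, length.out = n - half)) / n
}

#' Translate an image by a (sub)pixel vector in the Fourier domain
#'
#' Circular translation: `out[y, x] = im[y - dy, x - dx]` (0-based, periodic
#' boundary). Exact for integer shifts; band-limited interpolation for
#' subpixel shifts, so a known fractional drift can be planted and recovered
#' without resampling error.
#'
#' @param im numeric matrix.
#' @param dy,dx shift in pixels along rows (down) and columns (right).
#' @return shifted numeric matrix of the same dimension.
#' @keywords internal
fourier_shift <- function(im, dy, dx) {
  if (dy == 0 && dx == 0) return(im)
  fy <- fft_freq(nrow(im))
  fx <- fft_freq(ncol(im))
  ph <- exp(-2i * pi * outer(fy * dy, rep(1, ncol(im)))) *
        exp(-2i * pi * outer(rep(1, nrow(im)), fx * dx))
  out <- Re(stats::fft(stats::fft(im) * ph, inverse = TRUE)) / length(im)
  out
}

# Evaluate the (phase-)cross-correlation surface of spectrum P at fractional
# lags (ys, xs) by matrix-multiply DFT; used for subpixel peak refinement.
upsampled_cc <- function(P, ys, xs) {
  fr <- fft_freq(nrow(P))
  fc <- fft_freq(ncol(P))
  Er <- exp(2i * pi * outer(ys, fr))
  Ec <- exp(2i * pi * outer(fc, xs))
  Re(Er %*% P %*% Ec)
}

#' Phase cross-correlation between two images
#'
#' Estimates the translation `(dy, dx)` of `mov` relative to `ref`
#' (i.e. `mov ~ ref` shifted down by `dy` and right by `dx`), with subpixel
#' refinement by upsampled matrix-multiply DFT around the integer peak.
#'
#' @param ref,mov numeric matrices of equal dimension.
#' @param upsample integer upsampling factor for subpixel refinement
#'   (resolution 1/upsample px); must be >= 1.
#' @param window apply a 2D Hann window before correlating; suppresses the
#'   wraparound bias of the periodic DFT on non-periodic field-of-view data
#'   (recommended whenever the two images are crops of a larger scene rather
#'   than circular shifts of each other).
#' @return list with `dy`, `dx` (possibly fractional) and `score`, the
#'   normalized cross-correlation peak in \[0, 1\].
#' @export
phase_cross_correlation <- function(ref, mov, upsample = 20, window = FALSE) {
  stopifnot(all(dim(ref) == dim(mov)), upsample >= 1)
  r <- ref - mean(ref)
  m <- mov - mean(mov)
  if (window) {
    hann <- function(n) if (n > 1) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)) else 1
    w <- outer(hann(nrow(r)), hann(ncol(r)))
    r <- r * w
    m <- m * w
  }
  if (sum(r^2) == 0 || sum(m^2) == 0) {
    stop("registration channel empty: constant image has no phase content")
  }
  F1 <- stats::fft(r)
  F2 <- stats::fft(m)
  prod_raw <- Conj(F1) * F2
  # plain cross-correlation for the integer peak and the quality score
  cc <- Re(stats::fft(prod_raw, inverse = TRUE)) / length(prod_raw)
  idx <- which.max(cc)
  nr <- nrow(ref); nc <- ncol(ref)
  pr <- (idx - 1) %% nr
  pc <- (idx - 1) %/% nr
  dy <- if (pr > nr / 2) pr - nr else pr
  dx <- if (pc > nc / 2) pc - nc else pc
  score <- max(cc) / sqrt(sum(r^2) * sum(m^2))
  if (upsample > 1) {
    # refine on the raw cross-power spectrum: whitening would amplify
    # noise-only high frequencies of blurred microscopy images
    P <- prod_raw / length(prod_raw)
    ys <- dy + seq(-1, 1, by = 1 / upsample)
    xs <- dx + seq(-1, 1, by = 1 / upsample)
    cu <- upsampled_cc(P, ys, xs)
    pk <- which(cu == max(cu), arr.ind = TRUE)[1, ]
    dy <- ys[pk[1]]
    dx <- xs[pk[2]]
  }
  list(dy = dy, dx = dx, score = max(0, min(1, score)))
}

# Otsu threshold for a numeric vector (256-bin histogram).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(findInterval(x, seq(rng[1], rng[2], length.out = nbins + 1),
                             all.inside = TRUE), nbins)
  w <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = nbins + 1)
  mids <- (mids[-1] + mids[-(nbins + 1)]) / 2
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mt <- cm[nbins]
  between <- (mt * cw - cm)^2 / (cw * (1 - cw))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Blocked brute-force k-nearest neighbours (Euclidean). Returns k columns of
# neighbour indices and distances, excluding self. Exact.
knn_brute <- function(X, k, block = 1024L) {
  n <- nrow(X)
  stopifnot(k >= 1, k < n)
  ss <- rowSums(X^2)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    D2 <- outer(ss[rows], ss, "+") - 2 * tcrossprod(X[rows, , drop = FALSE], X)
    D2[cbind(seq_along(rows), rows)] <- Inf
    for (j in seq_along(rows)) {
      o <- order(D2[j, ], seq_len(n))[seq_len(k)]   # ties by lowest index
      idx[rows[j], ] <- o
      dst[rows[j], ] <- sqrt(pmax(D2[j, o], 0))
    }
  }
  list(index = idx, dist = dst)
}

# Evaluate an expression with a temporary RNG state seeded at `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Draw a filled disk of radius r centred at (cy, cx) (0-based) into logical
# matrix dims; returns integer index vector of covered pixels.
disk_pixels <- function(cy, cx, r, nr, nc) {
  y0 <- max(0L, floor(cy - r)); y1 <- min(nr - 1L, ceiling(cy + r))
  x0 <- max(0L, floor(cx - r)); x1 <- min(nc - 1L, ceiling(cx + r))
  if (y1 < y0 || x1 < x0) return(integer(0))
  ys <- y0:y1; xs <- x0:x1
  g <- expand.grid(y = ys, x = xs)
  keep <- (g$y - cy)^2 + (g$x - cx)^2 <= r^2
  (g$x[keep]) * nr + g$y[keep] + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
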