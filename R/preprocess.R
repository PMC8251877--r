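#' Multicycle preprocessing: drift compensation, background subtraction,
#' deconvolution, stitching, cycle concatenation
#'
#' Stage order in [process_stack()] follows the package's design: register
#' cycles first (translation-only, estimated on the nuclear channel), then
#' stitch tiles, then subtract blank-cycle background, then concatenate
#' cycles into one multichannel mosaic. All arithmetic is in floating point;
#' conversion back to 16-bit happens only at export.
#'
#' @name preprocess
NULL

prov_append <- function(x, msg) {
  attr(x, "provenance") <- c(attr(x, "provenance"), msg)
  x
}

#' Estimate inter-cycle stage drift from the nuclear channel
#'
#' Translation-only model via phase cross-correlation with subpixel
#' upsampling. Drift is estimated per tile, then median-filtered across the
#' tiles of a cycle: per-tile estimates deviating from the cycle median by
#' more than `outlier_px` are replaced by the median (robustness against
#' low-content tiles).
#'
#' @param stack a `codex_stack`.
#' @param reference_cycle cycle whose geometry defines the reference frame.
#' @param upsample subpixel upsampling factor (>= 10 recommended).
#' @param outlier_px per-axis deviation from the cycle median beyond which a
#'   tile estimate is replaced by the median.
#' @return drift table: data.frame(cycle, tile, dy, dx, score); the reference
#'   cycle rows are (0, 0) with score 1.
#' @export
estimate_drift <- function(stack, reference_cycle = 1L, upsample = 20L,
                           outlier_px = 2) {
  nuc <- stack$map$nuclear_channel
  n_tiles <- length(stack$images[[1]])
  rows <- list()
  for (cy in seq_along(stack$images)) {
    for (ti in seq_len(n_tiles)) {
      if (cy == reference_cycle) {
        rows[[length(rows) + 1L]] <- data.frame(cycle = cy, tile = ti,
                                                dy = 0, dx = 0, score = 1)
      } else {
        ref <- stack$images[[reference_cycle]][[ti]][, , nuc]
        mov <- stack$images[[cy]][[ti]][, , nuc]
        est <- phase_cross_correlation(ref, mov, upsample = upsample,
                                       window = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(cycle = cy, tile = ti,
                                                dy = est$dy, dx = est$dx,
                                                score = est$score)
      }
    }
  }
  dt <- do.call(rbind, rows)
  for (cy in setdiff(unique(dt$cycle), reference_cycle)) {
    sel <- dt$cycle == cy
    for (ax in c("dy", "dx")) {
      med <- stats::median(dt[[ax]][sel])
      bad <- sel & abs(dt[[ax]] - med) > outlier_px
      dt[[ax]][bad] <- med
    }
  }
  ts <- stack$grid$tile_size
  if (any(abs(dt$dy) >= ts / 4) || any(abs(dt$dx) >= ts / 4))
    warning("estimated drift exceeds tile size / 4; registration is suspect")
  dt
}

# shift one plane by (-dy, -dx) and zero the wrapped border band
unshift_plane <- function(pl, dy, dx) {
  out <- fourier_shift(pl, -dy, -dx)
  nr <- nrow(out); nc <- ncol(out)
  by <- ceiling(abs(dy)); bx <- ceiling(abs(dx))
  if (by > 0) {
    if (dy > 0) out[(nr - by + 1):nr, ] <- 0 else out[1:by, ] <- 0
  }
  if (bx > 0) {
    if (dx > 0) out[, (nc - bx + 1):nc] <- 0 else out[, 1:bx] <- 0
  }
  out
}

#' Apply (invert) a drift table to a stack
#'
#' All channels of a (cycle, tile) are translated jointly by the negated
#' drift vector; pixels translated in from outside the field are set to 0.
#' Zero drift is an exact identity.
#'
#' @param stack a `codex_stack`.
#' @param drift drift table from [estimate_drift()]; must cover every
#'   (cycle, tile).
#' @return the registered `codex_stack`.
#' @export
apply_drift <- function(stack, drift) {
  n_tiles <- length(stack$images[[1]])
  for (cy in seq_along(stack$images)) {
    for (ti in seq_len(n_tiles)) {
      row <- drift[drift$cycle == cy & drift$tile == ti, ]
      if (nrow(row) != 1)
        stop("drift table does not cover cycle ", cy, " tile ", ti)
      if (row$dy == 0 && row$dx == 0) next
      arr <- stack$images[[cy]][[ti]]
      for (k in seq_len(dim(arr)[3]))
        arr[, , k] <- unshift_plane(arr[, , k], row$dy, row$dx)
      stack$images[[cy]][[ti]] <- arr
    }
  }
  prov_append(stack, sprintf("apply_drift: %d cycles registered",
                             length(stack$images)))
}

#' Stitch a grid of tiles into one mosaic plane
#'
#' Nominal placement from grid geometry (tile origins every
#' `round(tile_size * (1 - overlap))` px). With `refine = TRUE`, pairwise
#' phase correlation on the nominal overlap strips of adjacent tiles
#' estimates per-edge placement errors (bounded by half the overlap), which
#' are accumulated over a spanning tree from the first tile into per-tile
#' offset corrections. Overlaps are blended with separable linear feather
#' weights, which reproduces identical overlapping data exactly.
#'
#' @param tiles list of numeric matrices in row-major grid order.
#' @param grid a [tile_grid()].
#' @param refine logical; phase-correlation refinement of tile placement.
#' @param upsample subpixel upsampling for refinement.
#' @return list with `mosaic` (numeric matrix) and `offsets`
#'   (data.frame tile, y, x of each tile origin, possibly subpixel when
#'   refined; placement uses rounded offsets).
#' @export
stitch <- function(tiles, grid, refine = FALSE, upsample = 10L) {
  ts <- grid$tile_size
  if (!all(vapply(tiles, function(t) all(dim(t) == c(ts, ts)), logical(1))))
    stop("inconsistent tile shapes: all tiles must be ", ts, "x", ts)
  step <- as.integer(round(ts * (1 - grid$overlap)))
  ov <- ts - step
  if (refine && ov <= 0) stop("refinement requires overlap > 0")
  nom <- t(vapply(seq_along(tiles), function(ti) {
    rc <- tile_rc(grid, ti)
    c((rc[1] - 1L) * step, (rc[2] - 1L) * step)
  }, numeric(2)))
  corr <- matrix(0, length(tiles), 2)
  if (refine && length(tiles) > 1) {
    # per-edge placement error of the neighbour relative to the anchor.
    # Two passes: an integer estimate on the nominal overlap strips, then a
    # subpixel estimate on the integer-aligned common region (removes the
    # toward-zero bias that non-common strip content induces).
    edge_err <- function(a, b, horizontal) {
      if (horizontal) {
        sa <- tiles[[a]][, (step + 1):ts, drop = FALSE]
        sb <- tiles[[b]][, 1:ov, drop = FALSE]
      } else {
        sa <- tiles[[a]][(step + 1):ts, , drop = FALSE]
        sb <- tiles[[b]][1:ov, , drop = FALSE]
      }
      e0 <- phase_cross_correlation(sa, sb, upsample = 1, window = TRUE)
      e0 <- c(-e0$dy, -e0$dx)               # sb[y, x] = sa[y + e, x + e]
      if (any(abs(e0) > ov / 2)) return(c(0, 0))  # implausible; keep nominal
      nr <- nrow(sa); nc <- ncol(sa)
      ra <- (1 + max(e0[1], 0)):(nr + min(e0[1], 0))
      ca <- (1 + max(e0[2], 0)):(nc + min(e0[2], 0))
      if (length(ra) < 8 || length(ca) < 8) return(e0)
      est <- phase_cross_correlation(sa[ra, ca, drop = FALSE],
                                     sb[ra - e0[1], ca - e0[2], drop = FALSE],
                                     upsample = upsample, window = TRUE)
      err <- e0 + c(-est$dy, -est$dx)
      if (any(abs(err) > ov / 2)) e0 else err
    }
    # BFS spanning tree over grid adjacency, accumulating corrections
    index_of <- function(r, c) (r - 1L) * grid$cols + c
    visited <- rep(FALSE, length(tiles))
    visited[1] <- TRUE
    queue <- 1L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %/% grid$cols + 1L
      c0 <- (cur - 1L) %% grid$cols + 1L
      nbrs <- list(c(r, c0 + 1L, TRUE, +1), c(r, c0 - 1L, TRUE, -1),
                   c(r + 1L, c0, FALSE, +1), c(r - 1L, c0, FALSE, -1))
      for (nb in nbrs) {
        rr <- nb[1]; cc <- nb[2]
        if (rr < 1 || rr > grid$rows || cc < 1 || cc > grid$cols) next
        ni <- index_of(rr, cc)
        if (visited[ni]) next
        visited[ni] <- TRUE
        if (nb[4] > 0) e <- edge_err(cur, ni, as.logical(nb[3]))
        else e <- -edge_err(ni, cur, as.logical(nb[3]))
        corr[ni, ] <- corr[cur, ] + e
        queue <- c(queue, ni)
      }
    }
  }
  off <- nom + corr
  off <- sweep(off, 2, apply(off, 2, min))  # anchor at (0, 0)
  ioff <- round(off)
  H <- max(ioff[, 1]) + ts
  W <- max(ioff[, 2]) + ts
  ramp <- pmin(seq_len(ts), rev(seq_len(ts)))
  wtile <- outer(ramp, ramp)
  acc <- matrix(0, H, W)
  wacc <- matrix(0, H, W)
  for (ti in seq_along(tiles)) {
    ys <- ioff[ti, 1] + seq_len(ts)
    xs <- ioff[ti, 2] + seq_len(ts)
    acc[ys, xs] <- acc[ys, xs] + tiles[[ti]] * wtile
    wacc[ys, xs] <- wacc[ys, xs] + wtile
  }
  list(mosaic = acc / pmax(wacc, .Machine$double.eps),
       offsets = data.frame(tile = seq_along(tiles), y = off[, 1], x = off[, 2]))
}

#' Stitch every (cycle, channel) plane of a registered stack
#'
#' Tile offsets are estimated once on the reference cycle's nuclear channel
#' (or taken as nominal) and applied to all planes so channels stay aligned.
#'
#' @param stack registered `codex_stack`.
#' @param refine see [stitch()].
#' @param reference_cycle cycle used to estimate refined offsets.
#' @return a `mosaic_stack`: list(`planes[[cycle]]` array (y, x, channel),
#'   `map`, `offsets`).
#' @export
stitch_stack <- function(stack, refine = FALSE, reference_cycle = 1L) {
  nuc <- stack$map$nuclear_channel
  ref_tiles <- lapply(stack$images[[reference_cycle]], function(a) a[, , nuc])
  ref <- stitch(ref_tiles, stack$grid, refine = refine)
  ioff <- ref$offsets
  grid <- stack$grid
  ts <- grid$tile_size
  ramp <- pmin(seq_len(ts), rev(seq_len(ts)))
  wtile <- outer(ramp, ramp)
  H <- nrow(ref$mosaic); W <- ncol(ref$mosaic)
  planes <- vector("list", length(stack$images))
  for (cy in seq_along(stack$images)) {
    ents <- stack$map$entries[stack$map$entries$cycle == cy, , drop = FALSE]
    arr <- array(0, c(H, W, nrow(ents)), dimnames = list(NULL, NULL, ents$fluor))
    for (k in seq_len(nrow(ents))) {
      acc <- matrix(0, H, W); wacc <- matrix(0, H, W)
      for (ti in seq_along(stack$images[[cy]])) {
        ys <- round(ioff$y[ti]) + seq_len(ts)
        xs <- round(ioff$x[ti]) + seq_len(ts)
        acc[ys, xs] <- acc[ys, xs] + stack$images[[cy]][[ti]][, , k] * wtile
        wacc[ys, xs] <- wacc[ys, xs] + wtile
      }
      arr[, , k] <- acc / pmax(wacc, .Machine$double.eps)
    }
    planes[[cy]] <- arr
  }
  out <- structure(list(planes = planes, map = stack$map,
                        offsets = ref$offsets), class = "mosaic_stack")
  prov_append(out, sprintf("stitch_stack: %dx%d grid, refine=%s",
                           grid$rows, grid$cols, refine))
}

#' Blank-cycle background subtraction
#'
#' For each reporter fluor, background is estimated from the cycles whose
#' entry for that fluor is flagged blank. A signal cycle flanked by blanks on
#' both sides gets their per-pixel linear interpolation by cycle index;
#' otherwise the nearest blank is used. Blank cycles themselves are corrected
#' leave-one-out (or zeroed when they are the only blank). Results are
#' clamped at 0.
#'
#' @param mstack a `mosaic_stack` (registered and stitched).
#' @return the background-subtracted `mosaic_stack`.
#' @export
subtract_background <- function(mstack) {
  e <- mstack$map$entries
  nuc <- mstack$map$nuclear_channel
  fluors <- setdiff(unique(e$fluor), nuc)
  n_cycles <- length(mstack$planes)
  for (f in fluors) {
    ef <- e[e$fluor == f, , drop = FALSE]
    blanks <- sort(ef$cycle[ef$blank])
    if (length(blanks) == 0)
      stop("no blank cycle for fluor '", f,
           "'; disable background subtraction explicitly if intended")
    orig <- lapply(ef$cycle, function(cy) mstack$planes[[cy]][, , f])
    names(orig) <- as.character(ef$cycle)
    bg_plane <- function(cy) orig[[as.character(cy)]]
    estimate <- function(cy, pool) {
      lo <- pool[pool <= cy]; hi <- pool[pool >= cy]
      if (length(lo) && length(hi)) {
        c1 <- max(lo); c2 <- min(hi)
        if (c1 == c2) return(bg_plane(c1))
        w <- (cy - c1) / (c2 - c1)
        return((1 - w) * bg_plane(c1) + w * bg_plane(c2))
      }
      bg_plane(if (length(lo)) max(lo) else min(hi))
    }
    for (cy in ef$cycle) {
      pool <- if (cy %in% blanks) setdiff(blanks, cy) else blanks
      est <- if (length(pool)) estimate(cy, pool) else bg_plane(cy)
      mstack$planes[[cy]][, , f] <- pmax(mstack$planes[[cy]][, , f] - est, 0)
    }
  }
  prov_append(mstack, sprintf("subtract_background: fluors %s",
                              paste(fluors, collapse = ",")))
}

#' Richardson-Lucy deconvolution with a Gaussian point-spread function
#'
#' Optional sharpening step (off by default in [process_stack()]; enabling it
#' requires an explicit sigma since no instrument PSF is assumed).
#' Convolution is periodic (FFT); output is non-negative and conserves flux.
#'
#' @param image numeric matrix (non-negative).
#' @param sigma Gaussian PSF sigma in px (> 0).
#' @param iterations Richardson-Lucy iterations (>= 1).
#' @return deconvolved matrix.
#' @export
deconvolve <- function(image, sigma, iterations = 10L) {
  stopifnot(sigma > 0)
  if (iterations < 1) stop("iterations must be >= 1")
  nr <- nrow(image); nc <- ncol(image)
  gy <- stats::dnorm(outer(fft_freq(nr) * nr, rep(1, nc)), sd = sigma)
  gx <- stats::dnorm(outer(rep(1, nr), fft_freq(nc) * nc), sd = sigma)
  psf <- gy * gx
  psf <- psf / sum(psf)
  OTF <- stats::fft(psf)
  conv <- function(m) pmax(Re(stats::fft(stats::fft(m) * OTF,
                                         inverse = TRUE)) / length(m), 0)
  u <- pmax(image, .Machine$double.eps)
  d <- pmax(image, 0)
  for (it in seq_len(iterations)) {
    ratio <- d / pmax(conv(u), .Machine$double.eps)
    u <- u * conv(ratio)   # Gaussian PSF is symmetric: correlation == convolution
  }
  u
}

#' Concatenate cycles into one multichannel marker mosaic
#'
#' Emits one plane per non-blank reporter marker in channel-map order, plus
#' the nuclear plane of the reference cycle first. Blank planes are dropped.
#'
#' @param mstack a `mosaic_stack` (registered, stitched, background
#'   subtracted).
#' @param reference_cycle cycle providing the retained nuclear plane.
#' @return a `codex_mosaic`: numeric array (y, x, plane) with plane dimnames
#'   `c("nuclear", markers...)`, attributes `pixel_size_um` and `provenance`.
#' @export
concatenate_cycles <- function(mstack, reference_cycle = 1L) {
  e <- mstack$map$entries
  nuc <- mstack$map$nuclear_channel
  keep <- e[!e$blank & e$fluor != nuc, , drop = FALSE]
  if (anyDuplicated(keep$marker))
    stop("duplicate marker name(s) in channel map: ",
         paste(unique(keep$marker[duplicated(keep$marker)]), collapse = ", "))
  H <- dim(mstack$planes[[1]])[1]; W <- dim(mstack$planes[[1]])[2]
  out <- array(0, c(H, W, nrow(keep) + 1L),
               dimnames = list(NULL, NULL, c("nuclear", keep$marker)))
  out[, , 1] <- mstack$planes[[reference_cycle]][, , nuc]
  for (i in seq_len(nrow(keep)))
    out[, , i + 1L] <- mstack$planes[[keep$cycle[i]]][, , keep$fluor[i]]
  attr(out, "pixel_size_um") <- mstack$map$pixel_size_um
  attr(out, "provenance") <- c(attr(mstack, "provenance"),
                               sprintf("concatenate_cycles: %d marker planes + nuclear",
                                       nrow(keep)))
  class(out) <- c("codex_mosaic", class(out))
  out
}

#' Full preprocessing chain: register, stitch, subtract, concatenate
#'
#' @param stack a `codex_stack` (e.g. from [read_experiment()] or the phantom
#'   generator).
#' @param reference_cycle reference cycle for registration/concatenation.
#' @param refine_stitch phase-correlation refinement of tile placement.
#' @param subtract blank-cycle background subtraction (requires blanks in the
#'   channel map).
#' @param deconvolve_sigma if > 0, Richardson-Lucy deconvolution with this
#'   PSF sigma is applied to every reporter plane (off by default).
#' @param deconvolve_iterations iterations for deconvolution.
#' @param upsample subpixel registration upsampling factor.
#' @return list with `mosaic` (a `codex_mosaic`), `drift` (drift table) and
#'   `offsets` (tile offsets).
#' @export
process_stack <- function(stack, reference_cycle = 1L, refine_stitch = FALSE,
                          subtract = TRUE, deconvolve_sigma = 0,
                          deconvolve_iterations = 10L, upsample = 20L) {
  drift <- estimate_drift(stack, reference_cycle, upsample = upsample)
  reg <- apply_drift(stack, drift)
  mstack <- stitch_stack(reg, refine = refine_stitch,
                         reference_cycle = reference_cycle)
  if (subtract) mstack <- subtract_background(mstack)
  mosaic <- concatenate_cycles(mstack, reference_cycle)
  if (deconvolve_sigma > 0) {
    for (k in 2:dim(mosaic)[3])
      mosaic[, , k] <- deconvolve(mosaic[, , k], deconvolve_sigma,
                                  deconvolve_iterations)
    attr(mosaic, "provenance") <- c(attr(mosaic, "provenance"),
                                    sprintf("deconvolve: sigma=%g iters=%d",
                                            deconvolve_sigma,
                                            deconvolve_iterations))
  }
  list(mosaic = mosaic, drift = drift, offsets = mstack$offsets)
}
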