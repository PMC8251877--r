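#' Synthetic multicycle CODEX phantom generator
#'
#' Builds seeded, fully ground-truthed synthetic datasets emulating multicycle
#' DNA-barcode immunofluorescence imaging: point-spread-blurred nuclei and
#' membranes, per-cell-type marker expression, inter-cycle stage drift,
#' additive background, blank cycles, optional barcode cross-talk, and
#' overlapping tiles. Every downstream operator (registration, stitching,
#' background subtraction, segmentation, clustering, barcode QC, spatial
#' statistics) can be validated against the returned truth tables.
#'
#' @name phantom
NULL

#' Configuration for the synthetic phantom
#'
#' @param tile_size tile side length in px (square tiles).
#' @param grid_rows,grid_cols tile grid dimensions.
#' @param overlap fraction of tile size shared between adjacent tiles, in
#'   \[0, 0.5).
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param n_cycles number of imaging cycles.
#' @param cell_types data.frame with column `type` plus one numeric column
#'   per marker giving the type's expected mean intensity (arbitrary units,
#'   all >= 0).
#' @param type_props optional named proportions over cell types (default
#'   uniform).
#' @param n_cells number of cells to place (Poisson-disk style with minimum
#'   spacing); 0 gives a background-only phantom.
#' @param positions optional matrix/data.frame of fixed (y, x) cell centres
#'   in mosaic coordinates (0-based px); overrides `n_cells`.
#' @param min_spacing minimum centre-to-centre distance in px.
#' @param nucleus_radius,nucleus_radius_sd mean/sd of nucleus radius (px).
#' @param membrane_width width of the annular membrane ring (px).
#' @param nuclear_intensity mean nuclear-stain intensity inside nuclei.
#' @param membrane_markers character vector of markers painted only on the
#'   membrane annulus (e.g. "CD45"); all other markers fill the whole cell
#'   footprint (nucleus + membrane).
#' @param drift matrix `n_cycles x 2` of per-cycle (dy, dx) stage drift in px
#'   (may be subpixel); row 1 is the reference cycle and should be (0, 0).
#' @param background per-channel additive background level; either a single
#'   number or a named vector by fluor.
#' @param blur_sigma Gaussian point-spread sigma in px (0 disables blurring).
#' @param noise one of "gaussian" or "poisson".
#' @param noise_sd standard deviation for Gaussian noise (ignored for
#'   Poisson).
#' @param crosstalk optional square matrix over barcodes/markers; entry
#'   \[i, j\] is the fraction of marker i's clean signal leaking into the
#'   channel that reads marker j. Fractions in \[0, 1\].
#' @param seed RNG seed; the phantom is bit-reproducible for a fixed seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(tile_size = 200L, grid_rows = 1L, grid_cols = 1L,
                           overlap = 0.1, pixel_size_um = 0.377,
                           n_cycles = 3L,
                           cell_types = NULL, type_props = NULL,
                           n_cells = 100L, positions = NULL,
                           min_spacing = 12, nucleus_radius = 4,
                           nucleus_radius_sd = 0.5, membrane_width = 2,
                           nuclear_intensity = 120,
                           membrane_markers = character(0),
                           drift = NULL, background = 20,
                           blur_sigma = 1, noise = c("gaussian", "poisson"),
                           noise_sd = 2, crosstalk = NULL, seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(cell_types)) {
    cell_types <- data.frame(type = c("A", "B"), M1 = c(100, 5), M2 = c(5, 100))
  }
  if (is.null(drift)) drift <- matrix(0, n_cycles, 2)
  cfg <- structure(list(
    tile_size = as.integer(tile_size), grid_rows = as.integer(grid_rows),
    grid_cols = as.integer(grid_cols), overlap = overlap,
    pixel_size_um = pixel_size_um, n_cycles = as.integer(n_cycles),
    cell_types = cell_types, type_props = type_props,
    n_cells = as.integer(n_cells), positions = positions,
    min_spacing = min_spacing, nucleus_radius = nucleus_radius,
    nucleus_radius_sd = nucleus_radius_sd, membrane_width = membrane_width,
    nuclear_intensity = nuclear_intensity,
    membrane_markers = membrane_markers,
    drift = drift, background = background, blur_sigma = blur_sigma,
    noise = noise, noise_sd = noise_sd, crosstalk = crosstalk,
    seed = as.integer(seed)), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(cfg$n_cells >= 0,
            cfg$overlap >= 0, cfg$overlap < 0.5,
            cfg$tile_size >= 16, cfg$grid_rows >= 1, cfg$grid_cols >= 1,
            cfg$n_cycles >= 1, cfg$nucleus_radius > 0,
            cfg$membrane_width >= 0, cfg$nuclear_intensity >= 0,
            all(cfg$background >= 0), cfg$blur_sigma >= 0, cfg$noise_sd >= 0)
  ints <- as.matrix(cfg$cell_types[, -1, drop = FALSE])
  if (any(ints < 0)) stop("cell-type expected intensities must be >= 0")
  if (nrow(cfg$drift) != cfg$n_cycles || ncol(cfg$drift) != 2)
    stop("drift must be an n_cycles x 2 matrix of (dy, dx)")
  fs <- phantom_mosaic_dim(cfg)
  if (any(abs(cfg$drift) >= min(fs) / 4))
    stop("drift magnitude must be < field size / 4")
  if (!is.null(cfg$crosstalk)) {
    ct <- cfg$crosstalk
    if (any(ct < 0) || any(ct > 1)) stop("cross-talk fractions must lie in [0, 1]")
  }
  invisible(cfg)
}

# Step between tile origins and full mosaic (rows, cols) in px.
phantom_tile_step <- function(cfg) as.integer(round(cfg$tile_size * (1 - cfg$overlap)))
phantom_mosaic_dim <- function(cfg) {
  st <- phantom_tile_step(cfg)
  c(cfg$tile_size + (cfg$grid_rows - 1L) * st,
    cfg$tile_size + (cfg$grid_cols - 1L) * st)
}

# Dart-throwing placement with minimum spacing; errors when density is
# infeasible after bounded retries.
place_cells <- function(n, dims, spacing, margin) {
  if (n == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x"))))
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  max_tries <- 200L * n
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, margin, dims[1] - 1 - margin),
              stats::runif(1, margin, dims[2] - 1 - margin))
    if (placed == 0L ||
        min((pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2) >= spacing^2) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  if (placed < n) {
    stop(sprintf(paste0("cell placement failed: %d of %d cells placed; ",
                        "minimum spacing %.1f px is infeasible at this density ",
                        "(field %d x %d px)"), placed, n, spacing, dims[1], dims[2]))
  }
  colnames(pts) <- c("y", "x")
  pts
}

# Default channel map for a tissue phantom: markers round-robin over up to 3
# reporter fluors per cycle, nuclear channel every cycle, remaining reporter
# slots blank.
phantom_channel_map <- function(cfg, blank_cycles = integer(0)) {
  markers <- setdiff(names(cfg$cell_types), "type")
  fluors <- c("FAM", "Cy3", "Cy5")
  entries <- data.frame(cycle = integer(0), fluor = character(0),
                        marker = character(0), barcode = character(0),
                        exposure = numeric(0), blank = logical(0))
  mi <- 1L
  for (cy in seq_len(cfg$n_cycles)) {
    entries <- rbind(entries, data.frame(
      cycle = cy, fluor = "Hoechst", marker = sprintf("Hoechst_c%d", cy),
      barcode = NA_character_, exposure = 0.1, blank = FALSE))
    for (f in fluors) {
      if (!(cy %in% blank_cycles) && mi <= length(markers)) {
        entries <- rbind(entries, data.frame(
          cycle = cy, fluor = f, marker = markers[mi],
          barcode = sprintf("BC%02d", mi), exposure = 0.1, blank = FALSE))
        mi <- mi + 1L
      } else {
        entries <- rbind(entries, data.frame(
          cycle = cy, fluor = f, marker = sprintf("blank_c%d_%s", cy, f),
          barcode = NA_character_, exposure = 0.1, blank = TRUE))
      }
    }
  }
  channel_map(entries, pixel_size_um = cfg$pixel_size_um,
              nuclear_channel = "Hoechst")
}

# Render clean (noise-free, unblurred, undrifted) full-mosaic planes:
# one per marker plus the nuclear plane. Returns list(nuclear=, markers=list).
render_clean_planes <- function(cfg, centers, radii, types) {
  dims <- phantom_mosaic_dim(cfg)
  markers <- setdiff(names(cfg$cell_types), "type")
  nuc <- matrix(0, dims[1], dims[2])
  mk <- lapply(markers, function(m) matrix(0, dims[1], dims[2]))
  names(mk) <- markers
  tt <- cfg$cell_types
  for (i in seq_len(nrow(centers))) {
    nucpix <- disk_pixels(centers[i, 1], centers[i, 2], radii[i],
                          dims[1], dims[2])
    allpix <- disk_pixels(centers[i, 1], centers[i, 2],
                          radii[i] + cfg$membrane_width, dims[1], dims[2])
    ringpix <- setdiff(allpix, nucpix)
    nuc[nucpix] <- nuc[nucpix] + cfg$nuclear_intensity
    prof <- tt[tt$type == types[i], markers, drop = FALSE]
    for (m in markers) {
      v <- as.numeric(prof[[m]])
      if (v > 0) {
        px <- if (m %in% cfg$membrane_markers) ringpix else allpix
        mk[[m]][px] <- mk[[m]][px] + v
      }
    }
  }
  list(nuclear = nuc, markers = mk)
}

#' Generate a synthetic multicycle tissue phantom
#'
#' Places disk-shaped cells (nucleus + annular membrane) in a tiled mosaic,
#' paints per-type marker intensities, assigns markers to (cycle, fluor)
#' slots (up to three reporters per cycle plus a nuclear channel in every
#' cycle), applies optional barcode cross-talk, Gaussian blurring, per-cycle
#' Fourier-domain stage drift, additive background, cuts overlapping tiles,
#' and adds noise. Intensities are clipped to the 16-bit range and rounded,
#' matching microscope TIFF depth.
#'
#' @param config a [phantom_config()].
#' @param blank_cycles cycles whose reporter slots carry no marker (background
#'   only), used downstream for background subtraction.
#' @param channel_map optional pre-built [channel_map()]; by default markers
#'   are scheduled round-robin.
#' @return list with elements `stack` (a `codex_stack`: `images[[cycle]][[tile]]`
#'   arrays of y, x, channel; `map`; `grid`) and `truth` (a `phantom_truth`:
#'   `cells` data.frame with id, y, x, radius, type and true per-marker mean
#'   intensity; `drift`; `background`; `config`).
#' @export
generate_tissue_phantom <- function(config, blank_cycles = integer(0),
                                    channel_map = NULL) {
  validate_phantom_config(config)
  cfg <- config
  dims <- phantom_mosaic_dim(cfg)
  markers <- setdiff(names(cfg$cell_types), "type")
  map <- channel_map %||% phantom_channel_map(cfg, blank_cycles)
  with_seed(cfg$seed, {
    margin <- cfg$nucleus_radius + cfg$membrane_width + 2
    if (!is.null(cfg$positions)) {
      centers <- as.matrix(cfg$positions)
      colnames(centers) <- c("y", "x")
    } else {
      centers <- place_cells(cfg$n_cells, dims, cfg$min_spacing, margin)
    }
    ncell <- nrow(centers)
    radii <- pmax(1.5, stats::rnorm(ncell, cfg$nucleus_radius,
                                    cfg$nucleus_radius_sd))
    props <- cfg$type_props %||%
      stats::setNames(rep(1 / nrow(cfg$cell_types), nrow(cfg$cell_types)),
                      cfg$cell_types$type)
    types <- if (ncell > 0)
      sample(names(props), ncell, replace = TRUE, prob = props)
    else character(0)

    clean <- render_clean_planes(cfg, centers, radii, types)

    # barcode cross-talk mixes clean marker planes before optics
    mixed <- clean$markers
    if (!is.null(cfg$crosstalk)) {
      ct <- cfg$crosstalk
      for (j in seq_along(markers)) {
        leak <- matrix(0, dims[1], dims[2])
        for (i in seq_along(markers)) {
          if (i != j && ct[i, j] > 0) leak <- leak + ct[i, j] * clean$markers[[i]]
        }
        mixed[[j]] <- mixed[[j]] + leak
      }
    }
    if (cfg$blur_sigma > 0) {
      blur <- function(m) as.matrix(EBImage::gblur(m, sigma = cfg$blur_sigma))
      clean$nuclear <- blur(clean$nuclear)
      mixed <- lapply(mixed, blur)
    }

    fluors <- unique(map$entries$fluor)
    bg <- cfg$background
    if (is.null(names(bg))) bg <- stats::setNames(rep(bg[1], length(fluors)), fluors)

    st <- phantom_tile_step(cfg)
    n_tiles <- cfg$grid_rows * cfg$grid_cols
    images <- vector("list", cfg$n_cycles)
    for (cy in seq_len(cfg$n_cycles)) {
      ents <- map$entries[map$entries$cycle == cy, , drop = FALSE]
      planes <- vector("list", nrow(ents))
      for (k in seq_len(nrow(ents))) {
        e <- ents[k, ]
        base <- if (e$fluor == map$nuclear_channel) {
          clean$nuclear
        } else if (!e$blank && e$marker %in% names(mixed)) {
          mixed[[e$marker]]
        } else matrix(0, dims[1], dims[2])
        pl <- base + bg[[e$fluor]]
        d <- cfg$drift[cy, ]
        if (any(d != 0)) pl <- fourier_shift(pl, d[1], d[2])
        planes[[k]] <- pl
      }
      tiles <- vector("list", n_tiles)
      t_i <- 1L
      for (r in seq_len(cfg$grid_rows)) for (cl in seq_len(cfg$grid_cols)) {
        y0 <- (r - 1L) * st
        x0 <- (cl - 1L) * st
        arr <- array(0, c(cfg$tile_size, cfg$tile_size, nrow(ents)),
                     dimnames = list(NULL, NULL, ents$fluor))
        for (k in seq_len(nrow(ents))) {
          sub <- planes[[k]][y0 + seq_len(cfg$tile_size),
                             x0 + seq_len(cfg$tile_size)]
          if (cfg$noise == "gaussian" && cfg$noise_sd > 0) {
            sub <- sub + matrix(stats::rnorm(length(sub), 0, cfg$noise_sd),
                                nrow(sub))
          } else if (cfg$noise == "poisson") {
            sub <- matrix(stats::rpois(length(sub), pmax(sub, 0)), nrow(sub))
          }
          arr[, , k] <- round(pmin(pmax(sub, 0), 65535))
        }
        tiles[[t_i]] <- arr
        t_i <- t_i + 1L
      }
      images[[cy]] <- tiles
    }
    truth_cells <- data.frame(id = seq_len(ncell),
                              y = centers[, 1], x = centers[, 2],
                              radius = radii, type = types,
                              stringsAsFactors = FALSE)
    for (m in markers) {
      truth_cells[[m]] <- if (ncell > 0)
        as.numeric(cfg$cell_types[match(types, cfg$cell_types$type), m])
      else numeric(0)
    }
    stack <- structure(list(
      images = images,
      map = map,
      grid = tile_grid(cfg$grid_rows, cfg$grid_cols, cfg$overlap,
                       cfg$tile_size)), class = "codex_stack")
    truth <- structure(list(
      cells = truth_cells,
      drift = data.frame(cycle = seq_len(cfg$n_cycles),
                         dy = cfg$drift[, 1], dx = cfg$drift[, 2]),
      background = bg, config = cfg), class = "phantom_truth")
    list(stack = stack, truth = truth)
  })
}

#' Generate a pooled singlet-spread phantom for barcode QC
#'
#' Emulates the pooled single-cell spread used to screen barcode
#' orthogonality: every cell carries exactly one barcode, barcodes are
#' spread over cycles at up to three reporter fluors (FAM/Cy3/Cy5) per cycle,
#' and a nuclear channel is imaged every cycle. Optional cross-talk plants
#' leakage between chosen barcode pairs.
#'
#' @param config a [phantom_config()]; its `cell_types` is replaced by one
#'   type per barcode expressing only that barcode's channel.
#' @param n_barcodes number of unique barcodes (> 0, one per cell type).
#' @param intensity on-barcode mean intensity.
#' @param crosstalk optional `n_barcodes x n_barcodes` leakage matrix.
#' @return as [generate_tissue_phantom()]; marker columns are `BC01` ...
#' @export
generate_singlet_spread <- function(config, n_barcodes, intensity = 100,
                                    crosstalk = NULL) {
  if (n_barcodes <= 0) stop("n_barcodes must be > 0")
  bc <- sprintf("BC%02d", seq_len(n_barcodes))
  tt <- as.data.frame(matrix(0, n_barcodes, n_barcodes,
                             dimnames = list(NULL, bc)))
  for (i in seq_len(n_barcodes)) tt[i, i] <- intensity
  tt <- cbind(data.frame(type = bc, stringsAsFactors = FALSE), tt)
  cfg <- config
  cfg$cell_types <- tt
  cfg$type_props <- NULL
  cfg$crosstalk <- crosstalk
  n_rep_cycles <- ceiling(n_barcodes / 3)
  cfg$n_cycles <- as.integer(n_rep_cycles)
  if (nrow(cfg$drift) != cfg$n_cycles) cfg$drift <- matrix(0, cfg$n_cycles, 2)
  validate_phantom_config(cfg)
  generate_tissue_phantom(cfg)
}

#' On/off reporter schedule for cycle-reproducibility experiments
#'
#' Builds the repeating 4-cycle pattern used to test annealing/stripping
#' chemistry with two markers: marker A alone, marker B alone, both, neither;
#' the block repeats to fill `n_cycles`.
#'
#' @param n_cycles total cycles; must be a positive multiple of 4.
#' @param markers character vector of exactly 2 marker names.
#' @return logical matrix `n_cycles x 2` (TRUE = reporter added that cycle),
#'   with one column per marker.
#' @export
generate_on_off_schedule <- function(n_cycles, markers) {
  if (length(markers) != 2) stop("exactly 2 markers are required")
  if (n_cycles <= 0 || n_cycles %% 4 != 0)
    stop("n_cycles must be a positive multiple of 4 (pattern A, B, A+B, none)")
  block <- matrix(c(TRUE, FALSE, TRUE, FALSE,
                    FALSE, TRUE, TRUE, FALSE), 4, 2)
  sched <- block[rep(seq_len(4), n_cycles / 4), , drop = FALSE]
  dimnames(sched) <- list(paste0("cycle", seq_len(n_cycles)), markers)
  sched
}

#' Simulate a Gaussian cell-type mixture in marker space
#'
#' Feature-space phantom for validating unsupervised clustering: `n_types`
#' spherical Gaussian components of unit within-type standard deviation whose
#' means lie `separation` standard deviations from the origin along random
#' orthonormal directions (pairwise centre distance `separation * sqrt(2)`).
#'
#' @param n cells, `n_types` components, `n_markers` dimensions,
#'   `separation` centre separation in within-type sd units, `seed` RNG seed.
#' @param n_types,n_markers,separation,seed see above.
#' @return list with `features` (n x n_markers matrix) and `labels`
#'   (integer vector in 1..n_types).
#' @export
simulate_marker_mixture <- function(n = 5000, n_types = 5, n_markers = 8,
                                    separation = 4, seed = 1L) {
  stopifnot(n_types >= 1, n_markers >= 2, n > n_types)
  with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(n_markers * n_markers), n_markers)))
    centers <- Q[, seq_len(n_types), drop = FALSE] * separation
    labels <- sort(rep_len(seq_len(n_types), n))
    X <- t(centers[, labels]) +
      matrix(stats::rnorm(n * n_markers), n, n_markers)
    colnames(X) <- sprintf("M%02d", seq_len(n_markers))
    list(features = X, labels = labels)
  })
}

#' Write a phantom to disk in the canonical experiment layout
#'
#' Writes per-cycle per-tile multichannel TIFFs named `cyc{CC}_tile{TTT}.tif`
#' (nuclear channel first), the channel map as YAML, the ground-truth cell
#' table and the per-cycle drift table as CSV.
#'
#' @param phantom result of [generate_tissue_phantom()] or
#'   [generate_singlet_spread()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- phantom$stack
  for (cy in seq_along(st$images)) {
    for (ti in seq_along(st$images[[cy]])) {
      arr <- st$images[[cy]][[ti]]
      pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 65535)
      tiff::writeTIFF(pages, file.path(dir, sprintf("cyc%02d_tile%03d.tif",
                                                    cy, ti)),
                      bits.per.sample = 16L)
    }
  }
  write_channel_map(st$map, file.path(dir, "channel_map.yaml"))
  utils::write.csv(phantom$truth$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(phantom$truth$drift, file.path(dir, "truth_drift.csv"),
                   row.names = FALSE)
  grid <- st$grid
  yaml::write_yaml(list(rows = grid$rows, cols = grid$cols,
                        overlap = grid$overlap, tile_size = grid$tile_size,
                        order = grid$order),
                   file.path(dir, "tile_grid.yaml"))
  invisible(dir)
}
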