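#' On-disk formats: TIFF stacks, channel maps, cell tables
#'
#' Pixel convention used throughout the package: 0-based, half-open indexing
#' with origin at the top-left, x rightward (columns) and y downward (rows).
#' Millimetre coordinates appear only at export: `mm = px * pixel_size_um / 1000`.
#'
#' @name stack_io
NULL

#' Channel map: (cycle, fluor) -> marker/barcode assignments
#'
#' @param entries data.frame with columns `cycle` (1-based), `fluor`,
#'   `marker`, `barcode` (NA allowed), `exposure` (seconds), `blank`
#'   (logical).
#' @param pixel_size_um physical pixel size (micrometres per pixel).
#' @param nuclear_channel fluor name of the nuclear stain, which must be
#'   present in every cycle (it is the registration channel).
#' @return object of class `channel_map`.
#' @details Validation enforces: at most 3 non-nuclear entries per cycle
#'   (three reporter fluors per cycle), a nuclear entry in every cycle,
#'   unique (cycle, fluor) pairs, unique marker names among non-blank
#'   non-nuclear entries, and exposures in (0, 10\] s.
#' @export
channel_map <- function(entries, pixel_size_um, nuclear_channel = "Hoechst") {
  cm <- structure(list(entries = as.data.frame(entries),
                       pixel_size_um = pixel_size_um,
                       nuclear_channel = nuclear_channel),
                  class = "channel_map")
  validate_channel_map(cm)
  cm
}

#' @rdname channel_map
#' @param map a `channel_map` to validate.
#' @export
validate_channel_map <- function(map) {
  e <- map$entries
  need <- c("cycle", "fluor", "marker", "exposure", "blank")
  if (!all(need %in% names(e)))
    stop("channel map entries need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(e[, c("cycle", "fluor")]))
    stop("duplicate (cycle, fluor) pair in channel map")
  for (cy in unique(e$cycle)) {
    sub <- e[e$cycle == cy, ]
    if (!map$nuclear_channel %in% sub$fluor)
      stop("nuclear channel '", map$nuclear_channel,
           "' missing in cycle ", cy)
    n_rep <- sum(sub$fluor != map$nuclear_channel)
    if (n_rep > 3)
      stop("cycle ", cy, " has ", n_rep,
           " reporter channels; at most 3 per cycle are supported")
  }
  mk <- e$marker[!e$blank & e$fluor != map$nuclear_channel]
  if (anyDuplicated(mk))
    stop("duplicate marker name(s): ",
         paste(unique(mk[duplicated(mk)]), collapse = ", "))
  if (any(e$exposure <= 0 | e$exposure > 10))
    stop("exposures must be in (0, 10] seconds")
  if (map$pixel_size_um <= 0) stop("pixel size must be positive")
  invisible(map)
}

#' Non-blank reporter markers of a channel map, in map order
#' @param map a `channel_map`.
#' @export
reporter_markers <- function(map) {
  e <- map$entries
  e$marker[!e$blank & e$fluor != map$nuclear_channel]
}

#' @rdname channel_map
#' @param path YAML file path.
#' @export
write_channel_map <- function(map, path) {
  yaml::write_yaml(list(pixel_size_um = map$pixel_size_um,
                        nuclear_channel = map$nuclear_channel,
                        channels = lapply(seq_len(nrow(map$entries)),
                                          function(i) as.list(map$entries[i, ]))),
                   path)
  invisible(path)
}

#' @rdname channel_map
#' @export
read_channel_map <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- do.call(rbind, lapply(y$channels, function(ch)
    data.frame(cycle = as.integer(ch$cycle), fluor = ch$fluor,
               marker = ch$marker,
               barcode = if (is.null(ch$barcode)) NA_character_ else ch$barcode,
               exposure = as.numeric(ch$exposure), blank = isTRUE(ch$blank),
               stringsAsFactors = FALSE)))
  channel_map(entries, pixel_size_um = y$pixel_size_um,
              nuclear_channel = y$nuclear_channel)
}

#' Tile grid geometry
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param overlap fraction of tile size shared by adjacent tiles, in
#'   \[0, 0.5).
#' @param tile_size tile side length in px.
#' @param order acquisition order, `"row-major"` or `"serpentine"`.
#' @return object of class `tile_grid`.
#' @export
tile_grid <- function(rows, cols, overlap, tile_size,
                      order = c("row-major", "serpentine")) {
  order <- match.arg(order)
  stopifnot(rows >= 1, cols >= 1, overlap >= 0, overlap < 0.5, tile_size >= 1)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 overlap = overlap, tile_size = as.integer(tile_size),
                 order = order), class = "tile_grid")
}

# tile index (row-major storage) -> grid (row, col), honouring acquisition order
tile_rc <- function(grid, ti) {
  r <- (ti - 1L) %/% grid$cols + 1L
  c0 <- (ti - 1L) %% grid$cols + 1L
  if (grid$order == "serpentine" && r %% 2L == 0L) c0 <- grid$cols + 1L - c0
  c(r, c0)
}

#' Read a multicycle tiled experiment from disk
#'
#' Expects the canonical layout `cyc{CC}_tile{TTT}.tif` (multipage TIFF, one
#' page per channel, nuclear first) plus a channel-map YAML and a
#' `tile_grid.yaml`. All (cycle, tile) files must be present and share
#' dimensions; gaps are reported by name.
#'
#' @param dir experiment directory.
#' @param channel_map_path path to the channel map YAML (default
#'   `<dir>/channel_map.yaml`).
#' @return a `codex_stack` (see [generate_tissue_phantom()]).
#' @export
read_experiment <- function(dir, channel_map_path = file.path(dir, "channel_map.yaml")) {
  map <- read_channel_map(channel_map_path)
  gy <- yaml::read_yaml(file.path(dir, "tile_grid.yaml"))
  grid <- tile_grid(gy$rows, gy$cols, gy$overlap, gy$tile_size,
                    gy$order %||% "row-major")
  n_cycles <- max(map$entries$cycle)
  n_tiles <- grid$rows * grid$cols
  images <- vector("list", n_cycles)
  dims0 <- NULL
  for (cy in seq_len(n_cycles)) {
    ents <- map$entries[map$entries$cycle == cy, , drop = FALSE]
    tiles <- vector("list", n_tiles)
    for (ti in seq_len(n_tiles)) {
      f <- file.path(dir, sprintf("cyc%02d_tile%03d.tif", cy, ti))
      if (!file.exists(f))
        stop("missing image file: ", basename(f))
      pages <- tiff::readTIFF(f, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      if (length(pages) != nrow(ents))
        stop(basename(f), ": ", length(pages),
             " channel pages but channel map lists ", nrow(ents),
             " channels for cycle ", cy)
      arr <- array(0, c(dim(pages[[1]]), length(pages)),
                   dimnames = list(NULL, NULL, ents$fluor))
      for (k in seq_along(pages)) arr[, , k] <- round(pages[[k]] * 65535)
      if (is.null(dims0)) dims0 <- dim(arr)[1:2]
      if (!all(dim(arr)[1:2] == dims0))
        stop(basename(f), ": tile dimensions ", paste(dim(arr)[1:2], collapse = "x"),
             " differ from ", paste(dims0, collapse = "x"))
      tiles[[ti]] <- arr
    }
    images[[cy]] <- tiles
  }
  structure(list(images = images, map = map, grid = grid),
            class = "codex_stack")
}

#' Validate a single-cell table
#'
#' A cell table is a data.frame with one row per segmented cell: `id`,
#' `x_px`, `y_px` (0-based centroid), `x_mm`, `y_mm`, `area` (px), one mean
#' intensity column per marker, and optionally `tile`, `cluster`, `region`.
#'
#' @param table data.frame.
#' @param markers marker column names expected to be present.
#' @export
validate_cell_table <- function(table, markers = attr(table, "markers")) {
  need <- c("id", "x_px", "y_px", "area")
  if (!all(need %in% names(table)))
    stop("cell table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(table$id)) stop("cell ids must be unique")
  if (!is.null(markers)) {
    miss <- setdiff(markers, names(table))
    if (length(miss)) stop("missing marker columns: ", paste(miss, collapse = ", "))
    if (any(as.matrix(table[, markers, drop = FALSE]) < 0))
      stop("marker intensities must be >= 0")
  }
  invisible(table)
}

#' Write / read a cell table (CSV or FCS 3.1)
#'
#' CSV round-trips the full table losslessly. FCS 3.1 carries one float32
#' parameter per marker plus `x`, `y` (px) and `area`; intensities are written
#' linearly with no transform.
#'
#' @param table cell table data.frame (see [validate_cell_table()]).
#' @param path output path.
#' @param format `"csv"` or `"fcs"` (default from the file extension).
#' @param markers marker columns to carry into FCS (default: attribute
#'   `markers`, else all numeric columns besides coordinates and area).
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path, format = NULL, markers = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("csv", "fcs")) stop("format must be csv or fcs")
  markers <- markers %||% attr(table, "markers") %||%
    setdiff(names(table)[vapply(table, is.numeric, logical(1))],
            c("id", "tile", "x_px", "y_px", "x_mm", "y_mm", "area", "cluster"))
  if (nrow(table) == 0) warning("writing empty cell table (header only)")
  if (format == "csv") {
    utils::write.csv(table, path, row.names = FALSE)
  } else {
    cols <- c(markers, "x_px", "y_px", "area")
    mat <- as.matrix(table[, cols, drop = FALSE])
    colnames(mat) <- c(markers, "x", "y", "area")
    write_fcs(mat, path)
  }
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "csv") {
    tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (format == "fcs") {
    tb <- as.data.frame(read_fcs(path))
  } else stop("format must be csv or fcs")
  tb
}
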