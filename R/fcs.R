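# Minimal FCS 3.1 writer/reader: single dataset, float32 data, little-endian
# ($BYTEORD 1,2,3,4), list mode. One parameter per matrix column; $PnN from
# column names. Written linearly (no transform) so the file is a faithful
# measurement record; sufficient for round-tripping segmented-cell
# intensities into cytometry tools.

#' Write a numeric matrix as an FCS 3.1 file
#'
#' @param mat numeric matrix, one event (cell) per row, one parameter per
#'   named column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(mat, path) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) stop("matrix columns must be named")
  n_par <- ncol(mat)
  n_evt <- nrow(mat)
  delim <- "/"
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(n_par), "$TOT", as.character(n_evt),
          "$NEXTDATA", "0")
  for (p in seq_len(n_par)) {
    rng <- max(1, ceiling(max(mat[, p], 0, na.rm = TRUE)) + 1)
    kw <- c(kw,
            sprintf("$P%dN", p), colnames(mat)[p],
            sprintf("$P%dB", p), "32",
            sprintf("$P%dE", p), "0,0",
            sprintf("$P%dR", p), as.character(rng))
  }
  data_len <- 4L * n_par * n_evt
  # text segment length depends on the BEGINDATA/ENDDATA digits; fix widths
  make_text <- function(begin_data, end_data) {
    all_kw <- c("$BEGINDATA", sprintf("%10d", begin_data),
                "$ENDDATA", sprintf("%10d", end_data),
                "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
                "$BEGINSTEXT", "0", "$ENDSTEXT", "0", kw)
    paste0(delim, paste(all_kw, collapse = delim), delim)
  }
  text0 <- make_text(0, 0)
  text_begin <- 58L
  text_end <- text_begin + nchar(text0, type = "bytes") - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + data_len - 1L
  text <- make_text(data_begin, data_end)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end,
                    if (data_end <= 99999999) data_begin else 0,
                    if (data_end <= 99999999) data_end else 0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS file written by [write_fcs()] (FCS 3.0/3.1, float or double
#' data, little- or big-endian)
#'
#' @param path FCS file path.
#' @return numeric matrix, one event per row, columns named from `$PnN`.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (!startsWith(header, "FCS3"))
    stop("not an FCS 3.x file: ", path)
  text_begin <- as.integer(substr(header, 11, 18))
  text_end <- as.integer(substr(header, 19, 26))
  seek(con, text_begin)
  text <- readChar(con, text_end - text_begin + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts) - 1, by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(vals, toupper(trimws(keys)))
  n_par <- as.integer(kw[["$PAR"]])
  n_evt <- as.integer(kw[["$TOT"]])
  data_begin <- as.integer(kw[["$BEGINDATA"]])
  dtype <- kw[["$DATATYPE"]]
  size <- if (identical(dtype, "D")) 8L else 4L
  if (!dtype %in% c("F", "D")) stop("unsupported $DATATYPE: ", dtype)
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  seek(con, data_begin)
  vec <- readBin(con, "numeric", n = n_par * n_evt, size = size,
                 endian = endian)
  mat <- matrix(vec, nrow = n_evt, ncol = n_par, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(n_par), function(p)
    kw[[sprintf("$P%dN", p)]] %||% sprintf("P%d", p), character(1))
  mat
}
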