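#' Read a raster grid from disk
#'
#' Supports two plain single-band raster formats:
#'
#' * `"ascii"` — ESRI ASCII grid (`ncols/nrows/xllcorner/yllcorner/cellsize/`
#'   `NODATA_value` header followed by north-to-south rows). Values of any
#'   range; exact round-trip with [write_grid()].
#' * `"tiff"` — single-band TIFF written by [write_grid()]: channel 1 holds
#'   the value (restricted to `[0, 1]`, stored at 32-bit fixed-point
#'   precision, about 2e-10), channel 2 the validity mask, and a `.tfw`
#'   world-file sidecar carries the georeferencing.
#'
#' Values are returned untouched — no standardisation is applied.
#'
#' @param path File path.
#' @param format `"ascii"` or `"tiff"`; by default guessed from the file
#'   extension (`.asc`/`.txt` vs `.tif`/`.tiff`).
#' @return A [score_map()] with the mask set from the file's no-data cells.
#' @seealso [write_grid()], [as_binary_map()]
#' @export
read_grid <- function(path, format = c("auto", "ascii", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    ascii = read_ascii_grid(path),
    tiff = read_tiff_grid(path)
  )
}

#' Write a raster grid to disk
#'
#' Inverse of [read_grid()]; see there for the formats. No-data cells are
#' written as the sentinel `-9999` in ASCII grids and flagged through the
#' mask channel in TIFF.
#'
#' @param map A [score_map()] or [binary_map()].
#' @param path Output file path.
#' @inheritParams read_grid
#' @return Invisibly, `path`.
#' @export
write_grid <- function(map, path, format = c("auto", "ascii", "tiff")) {
  stopifnot(inherits(map, "raster_map"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    ascii = write_ascii_grid(map, path),
    tiff = write_tiff_grid(map, path)
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("asc", "txt", "grd")) return("ascii")
  stop("cannot guess raster format from extension: ", path, call. = FALSE)
}

#' Coerce a score map read from disk to a binary map
#'
#' Values within `tolerance` of 0 or 1 are snapped to the exact integer —
#' TIFF storage is 32-bit fixed point, so a written 1 reads back a few
#' 1e-10 short of it. Anything farther from {0, 1} is an error.
#'
#' @param map A [score_map()] whose valid cells are all (near) 0 or 1.
#' @param tolerance Maximum distance from 0 or 1 to snap (default 1e-6).
#' @return A [binary_map()] with the same metadata and mask.
#' @export
as_binary_map <- function(map, tolerance = 1e-6) {
  stopifnot(inherits(map, "raster_map"))
  v <- map$values
  snapped <- round(v[map$mask])
  if (any(abs(v[map$mask] - snapped) > tolerance)) {
    stop("valid cells are not within `tolerance` of 0 or 1", call. = FALSE)
  }
  v[map$mask] <- snapped
  binary_map(map$meta, v, map$mask)
}

# ---- ESRI ASCII grid ------------------------------------------------------

ASCII_NODATA <- -9999

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) {
    stop("malformed ASCII grid (expected 6 header lines + data): ", path,
      call. = FALSE
    )
  }
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) {
      stop("malformed ASCII grid header line ", i, ": ", lines[i], call. = FALSE)
    }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need]))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(
      "ASCII grid data size mismatch: expected ", nr * nc, " values, got ",
      length(vals),
      call. = FALSE
    )
  }
  values <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- values != hdr$nodata_value
  values[!mask] <- NA_real_
  meta <- grid_meta(
    n_rows = nr, n_cols = nc, cell_size = hdr$cellsize,
    origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  )
  score_map(meta, values, mask)
}

write_ascii_grid <- function(map, path) {
  meta <- map$meta
  values <- map$values
  values[!map$mask] <- ASCII_NODATA
  hdr <- c(
    sprintf("ncols %d", meta$n_cols),
    sprintf("nrows %d", meta$n_rows),
    sprintf("xllcorner %.10g", meta$origin[1]),
    sprintf("yllcorner %.10g", meta$origin[2] - meta$n_rows * meta$cell_size),
    sprintf("cellsize %.10g", meta$cell_size),
    sprintf("NODATA_value %d", ASCII_NODATA)
  )
  rows <- apply(values, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  ok <- tryCatch(
    {
      writeLines(c(hdr, rows), path)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) stop("cannot write ASCII grid to ", path, call. = FALSE)
}

# ---- single-band float TIFF + world file ----------------------------------

read_tiff_grid <- function(path) {
  arr <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(arr)) != 3 || dim(arr)[3] != 2) {
    stop("expected a two-channel (value, mask) TIFF: ", path, call. = FALSE)
  }
  values <- arr[, , 1, drop = TRUE]
  mask <- arr[, , 2, drop = TRUE] > 0.5
  values[!mask] <- NA_real_
  tfw <- paste0(tools::file_path_sans_ext(path), ".tfw")
  if (!file.exists(tfw)) stop("missing world file: ", tfw, call. = FALSE)
  w <- as.numeric(readLines(tfw, warn = FALSE))
  if (length(w) != 6 || anyNA(w)) stop("malformed world file: ", tfw, call. = FALSE)
  cell <- w[1]
  # world files reference the centre of the upper-left pixel
  meta <- grid_meta(
    n_rows = nrow(values), n_cols = ncol(values), cell_size = cell,
    origin = c(w[5] - cell / 2, w[6] + cell / 2)
  )
  score_map(meta, matrix(values, nrow(values), ncol(values)), mask)
}

write_tiff_grid <- function(map, path) {
  v <- map$values
  vv <- v[map$mask]
  if (length(vv) && (min(vv) < 0 || max(vv) > 1)) {
    stop(
      "TIFF output stores values in [0, 1] only; standardize() first or ",
      "use the ascii format",
      call. = FALSE
    )
  }
  v[!map$mask] <- 0
  arr <- array(c(v, as.numeric(map$mask)), dim = c(nrow(v), ncol(v), 2))
  ok <- tryCatch(
    {
      tiff::writeTIFF(arr, path, bits.per.sample = 32L)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) stop("cannot write TIFF to ", path, call. = FALSE)
  meta <- map$meta
  tfw <- paste0(tools::file_path_sans_ext(path), ".tfw")
  writeLines(sprintf("%.12g", c(
    meta$cell_size, 0, 0, -meta$cell_size,
    meta$origin[1] + meta$cell_size / 2,
    meta$origin[2] - meta$cell_size / 2
  )), tfw)
}
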