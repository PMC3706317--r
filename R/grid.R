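#' Grid metadata
#'
#' Describes the geometry of a regular lon/lat raster grid. Row 1 is the
#' northernmost row, columns run west to east, and `origin` is the outer
#' (north-west) corner of the top-left cell. Any lat/lon reported for a cell
#' refers to its centre.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in degrees per pixel. A 10-arcminute
#'   grid has `cell_size = 1/6`.
#' @param origin Numeric length-2 `(lon, lat)` of the upper-left cell's
#'   outer corner.
#' @return A `grid_meta` object.
#' @examples
#' grid_meta(60, 72, cell_size = 1/6, origin = c(-11, 72))
#' @export
grid_meta <- function(n_rows, n_cols, cell_size = 1 / 6, origin = c(0, 0)) {
  stopifnot(
    length(n_rows) == 1, length(n_cols) == 1,
    n_rows >= 1, n_cols >= 1,
    n_rows == as.integer(n_rows), n_cols == as.integer(n_cols),
    length(cell_size) == 1, cell_size > 0,
    length(origin) == 2, is.numeric(origin)
  )
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size = as.numeric(cell_size), origin = as.numeric(origin)
    ),
    class = "grid_meta"
  )
}

#' @export
format.grid_meta <- function(x, ...) {
  sprintf(
    "<grid_meta: %d x %d cells, %.6g deg/cell, NW corner (%.6g, %.6g)>",
    x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]
  )
}

#' @export
print.grid_meta <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

meta_equal <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

new_raster_map <- function(meta, values, mask, subclass) {
  stopifnot(inherits(meta, "grid_meta"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(values), c(meta$n_rows, meta$n_cols))) {
    stop("`values` must be a ", meta$n_rows, " x ", meta$n_cols, " matrix", call. = FALSE)
  }
  if (!identical(dim(mask), dim(values))) {
    stop("`mask` must share the shape of `values`", call. = FALSE)
  }
  if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
  structure(
    list(meta = meta, values = values, mask = mask),
    class = c(subclass, "raster_map")
  )
}

#' Continuous score map
#'
#' A 2-D grid of real-valued model scores (occurrence probability, an LAI
#' proxy, a fitness index, ...) with a validity mask. Invalid cells (sea /
#' no-data) are excluded from every statistic in the package.
#'
#' @param meta A [grid_meta()].
#' @param values Numeric matrix of shape `n_rows x n_cols`. `NA` entries are
#'   treated as invalid when `mask` is not given.
#' @param mask Logical matrix of the same shape; `TRUE` marks a valid cell.
#'   Defaults to `!is.na(values)`.
#' @return A `score_map` object.
#' @seealso [binary_map()], [standardize()], [as_tibble.raster_map()]
#' @export
score_map <- function(meta, values, mask = NULL) {
  m <- new_raster_map(meta, values, mask, "score_map")
  if (anyNA(m$values[m$mask])) stop("valid cells must not be NA", call. = FALSE)
  m
}

#' Binary presence/absence map
#'
#' Like [score_map()] but valid cells must be exactly 0 (absence) or
#' 1 (presence).
#'
#' @inheritParams score_map
#' @return A `binary_map` object.
#' @export
binary_map <- function(meta, values, mask = NULL) {
  m <- new_raster_map(meta, values, mask, "binary_map")
  v <- m$values[m$mask]
  if (anyNA(v) || !all(v %in% c(0, 1))) {
    stop("valid cells of a binary_map must be exactly 0 or 1", call. = FALSE)
  }
  m
}

#' @export
print.raster_map <- function(x, ...) {
  kind <- class(x)[1]
  v <- x$values[x$mask]
  cat(sprintf(
    "<%s> %s\n  valid cells: %d / %d", kind, format(x$meta),
    sum(x$mask), length(x$mask)
  ))
  if (length(v)) {
    cat(sprintf("\n  range: [%.4g, %.4g]  mean: %.4g", min(v), max(v), mean(v)))
  }
  cat("\n")
  invisible(x)
}

#' Convert a raster map to a tibble of cell records
#'
#' One row per grid cell with row/column indices, cell-centre longitude and
#' latitude, the cell value (`NA` where invalid) and the validity flag —
#' the bridge from the matrix-backed grid containers to tidy tooling.
#'
#' @param x A [score_map()] or [binary_map()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `lon`, `lat`, `value`, `valid`.
#' @importFrom tibble as_tibble
#' @method as_tibble raster_map
#' @export
as_tibble.raster_map <- function(x, ...) {
  meta <- x$meta
  rows <- seq_len(meta$n_rows)
  cols <- seq_len(meta$n_cols)
  out <- tidyr::expand_grid(row = rows, col = cols)
  out$lon <- meta$origin[1] + (out$col - 0.5) * meta$cell_size
  out$lat <- meta$origin[2] - (out$row - 0.5) * meta$cell_size
  idx <- cbind(out$row, out$col)
  out$value <- x$values[idx]
  out$valid <- x$mask[idx]
  out$value[!out$valid] <- NA_real_
  out
}

#' Check that two maps are co-registered
#'
#' Two maps are comparable only when they share identical grid geometry and
#' identical validity masks. Mask intersection is deliberately *not* taken
#' silently: differing masks in a comparison study usually indicate a data
#' error upstream.
#'
#' @param a,b [score_map()] or [binary_map()] objects.
#' @return Invisibly `TRUE`; otherwise an error naming the differing field.
#' @export
assert_coregistered <- function(a, b) {
  stopifnot(inherits(a, "raster_map"), inherits(b, "raster_map"))
  ma <- a$meta
  mb <- b$meta
  if (ma$n_rows != mb$n_rows || ma$n_cols != mb$n_cols) {
    stop("maps are not co-registered: grid dimensions differ", call. = FALSE)
  }
  if (!isTRUE(all.equal(ma$cell_size, mb$cell_size))) {
    stop("maps are not co-registered: cell_size differs", call. = FALSE)
  }
  if (!isTRUE(all.equal(ma$origin, mb$origin))) {
    stop("maps are not co-registered: origin differs", call. = FALSE)
  }
  if (!identical(a$mask, b$mask)) {
    stop("maps are not co-registered: validity masks differ", call. = FALSE)
  }
  invisible(TRUE)
}

#' Min-max standardise a score map to [0, 1]
#'
#' Rescales valid cells to `(v - min) / (max - min)` so every model output
#' ranks from 0 to 1 before dichotomisation or map comparison. Invalid cells
#' are untouched. A constant map (no discrimination) maps to all zeros, which
#' keeps downstream thresholding conservative.
#'
#' @param map A [score_map()] with at least one valid cell.
#' @return A standardised [score_map()].
#' @examples
#' m <- score_map(grid_meta(1, 3), matrix(c(2, 4, 6), 1))
#' standardize(m)$values
#' @export
standardize <- function(map) {
  stopifnot(inherits(map, "score_map"))
  v <- map$values[map$mask]
  if (!length(v)) stop("standardize() needs at least one valid cell", call. = FALSE)
  lo <- min(v)
  hi <- max(v)
  out <- map$values
  if (hi > lo) {
    out[map$mask] <- (v - lo) / (hi - lo)
  } else {
    out[map$mask] <- 0
  }
  score_map(map$meta, out, map$mask)
}
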