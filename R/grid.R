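#' Grid specification
#'
#' A `grid_spec` fixes the single georeferenced grid on which every layer of a
#' pipeline run lives. Coordinates follow the top-left-origin convention:
#' row 1 / col 1 is the north-west cell, rows increase southwards, columns
#' eastwards, indices are 1-based (R), and each cell occupies the half-open
#' square `[x0 + (c-1)s, x0 + c s) x (y0 - r s, y0 - (r-1)s]`.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin_x,origin_y Top-left corner of the grid in metres.
#' @param crs_id Free-text CRS identifier (e.g. `"EPSG:32630"`). Operations
#'   never reproject; layers with different `crs_id` refuse to combine.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(4, 4, cell_size = 100)
#' cell_area_ha(g)  # 1 ha per cell
#' @export
grid_spec <- function(n_rows, n_cols, cell_size,
                      origin_x = 0, origin_y = n_rows * cell_size,
                      crs_id = "EPSG:32630") {
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L, length(cell_size) == 1L)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid_spec: n_rows and n_cols must be integers >= 1")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("grid_spec: cell_size must be > 0")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 cell_size = as.numeric(cell_size),
                 origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 crs_id = as.character(crs_id)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec %d x %d @ %g m, origin (%g, %g), %s>\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

#' Cell area in hectares
#'
#' Derived from `cell_size` (never stored): `cell_size^2 / 1e4`.
#' @param grid A [grid_spec()].
#' @return Scalar hectares per cell.
#' @export
cell_area_ha <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$cell_size^2 / 1e4
}

#' Cell-centre coordinates
#'
#' @param grid A [grid_spec()].
#' @return A list with matrices `x` and `y` (n_rows x n_cols) of cell-centre
#'   coordinates in grid CRS units.
#' @export
cell_centres <- function(grid) {
  s <- grid$cell_size
  xs <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * s
  ys <- grid$origin_y - (seq_len(grid$n_rows) - 0.5) * s
  list(x = matrix(xs, grid$n_rows, grid$n_cols, byrow = TRUE),
       y = matrix(ys, grid$n_rows, grid$n_cols))
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Assert that layers share one grid
#'
#' Every multi-layer operation refuses mixed grids rather than resampling
#' implicitly: silent resampling is the framework's main source of spatial
#' inconsistency.
#' @param ... Rasters (or grid_specs) to compare.
#' @return The shared [grid_spec()], invisibly.
#' @export
check_same_grid <- function(...) {
  layers <- list(...)
  grids <- lapply(layers, function(l) if (inherits(l, "grid_spec")) l else l$grid)
  g0 <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!same_grid(g0, g))
      stop("layers do not share one grid_spec; resample explicitly first")
  }
  invisible(g0)
}

#' Categorical raster
#'
#' Integer class codes on a [grid_spec()], with a legend mapping each code to
#' a class name. Codes are non-negative integers; every non-nodata code
#' present must appear in the legend.
#'
#' @param grid A [grid_spec()].
#' @param codes Integer matrix (`n_rows` x `n_cols`) or vector recycled to it.
#' @param legend Named integer vector: `c(forest = 1, water = 2, ...)`.
#' @param nodata_code Integer sentinel for missing cells (default `-1`).
#' @return An object of class `categorical_raster`.
#' @export
categorical_raster <- function(grid, codes, legend, nodata_code = -1L) {
  stopifnot(inherits(grid, "grid_spec"))
  codes <- matrix(as.integer(codes), grid$n_rows, grid$n_cols)
  legend <- vapply(legend, as.integer, integer(1))
  if (is.null(names(legend)) || any(!nzchar(names(legend))))
    stop("categorical_raster: legend must be a fully named code vector")
  nodata_code <- as.integer(nodata_code)
  present <- unique(codes[!is.na(codes) & codes != nodata_code])
  if (any(present < 0L))
    stop("categorical_raster: codes must be non-negative integers")
  missing_codes <- setdiff(present, legend)
  if (length(missing_codes))
    stop("categorical_raster: codes not in legend: ",
         paste(missing_codes, collapse = ", "))
  codes[is.na(codes)] <- nodata_code
  structure(list(grid = grid, codes = codes, legend = legend,
                 nodata_code = nodata_code),
            class = "categorical_raster")
}

#' Continuous raster
#'
#' Real values on a [grid_spec()]; `NA` marks nodata internally and is mapped
#' to `nodata_sentinel` on disk. Non-nodata values must be finite.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix or vector recycled to `n_rows` x `n_cols`.
#' @param nodata_sentinel Value used on disk for missing cells.
#' @return An object of class `continuous_raster`.
#' @export
continuous_raster <- function(grid, values, nodata_sentinel = -9999) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  if (any(!is.na(values) & !is.finite(values)))
    stop("continuous_raster: non-nodata values must be finite")
  structure(list(grid = grid, values = values,
                 nodata_sentinel = as.numeric(nodata_sentinel)),
            class = "continuous_raster")
}

#' @export
print.categorical_raster <- function(x, ...) {
  n_valid <- sum(x$codes != x$nodata_code)
  cat(sprintf("<categorical_raster %dx%d, %d valid cells, %d classes>\n",
              x$grid$n_rows, x$grid$n_cols, n_valid, length(x$legend)))
  invisible(x)
}

#' @export
print.continuous_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<continuous_raster %dx%d, %d valid cells, range [%g, %g]>\n",
              x$grid$n_rows, x$grid$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Valid-cell mask of a raster
#' @param r A categorical or continuous raster.
#' @return Logical matrix, `TRUE` where the cell carries data.
#' @export
valid_mask <- function(r) {
  if (inherits(r, "categorical_raster")) r$codes != r$nodata_code
  else if (inherits(r, "continuous_raster")) !is.na(r$values)
  else stop("valid_mask: not a raster")
}

#' Decode a categorical raster to class names
#' @param r A [categorical_raster()].
#' @return Character matrix of class names; `NA` on nodata cells.
#' @export
decode_classes <- function(r) {
  stopifnot(inherits(r, "categorical_raster"))
  lut <- names(r$legend)[match(r$codes, r$legend)]
  matrix(lut, r$grid$n_rows, r$grid$n_cols)
}

# look up the code for a class name, erroring on unknown names
class_code <- function(legend, name) {
  if (!name %in% names(legend)) stop("unknown class name: ", name)
  unname(legend[[name]])
}
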