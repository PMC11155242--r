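# even-odd ray-casting containment, vectorized over query points.
# Points exactly on a boundary follow the half-open convention of the
# crossing count (left/bottom edges in, right/top out), which is
# deterministic — what zonal statistics needs.
point_in_polygon <- function(px, py, ring) {
  if (isTRUE(all(ring[1, ] == ring[nrow(ring), ])))
    ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize id-carrying polygons onto a grid
#'
#' Each cell receives the id of the polygon containing its centre; cells
#' outside all polygons are nodata. If several polygons contain one centre
#' (overlap), the smallest id wins deterministically and a warning is
#' logged.
#'
#' @param polys List of `list(id, name, ring)` features (ids positive
#'   integers, `ring` a two-column boundary matrix), as returned by
#'   [read_polygons_geojson()].
#' @param grid Target [grid_spec()].
#' @return A [categorical_raster()] whose legend maps names to ids.
#' @export
rasterize_polygons <- function(polys, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  codes <- matrix(-1L, grid$n_rows, grid$n_cols)
  if (length(polys) == 0L)
    return(categorical_raster(grid, codes, legend = c(none = 0L),
                              nodata_code = -1L))
  ids <- vapply(polys, function(p) as.integer(p$id), 1L)
  if (any(ids <= 0L)) stop("rasterize_polygons: ids must be positive")
  if (anyDuplicated(ids)) stop("rasterize_polygons: duplicate polygon ids")
  cc <- cell_centres(grid)
  overlap_hit <- FALSE
  # visit in decreasing id order so the smallest id overwrites last
  for (p in polys[order(ids, decreasing = TRUE)]) {
    inside <- point_in_polygon(as.vector(cc$x), as.vector(cc$y), p$ring)
    if (any(codes[inside] != -1L)) overlap_hit <- TRUE
    codes[inside] <- as.integer(p$id)
  }
  if (overlap_hit) {
    bf_log("warn", "rasterize_polygons: overlapping polygons; smallest id kept")
    warning("rasterize_polygons: overlapping polygons cover a shared cell ",
            "centre; smallest id wins")
  }
  nm <- vapply(polys, function(p) p$name %||% as.character(p$id), "")
  categorical_raster(grid, codes, legend = setNames(ids, nm), nodata_code = -1L)
}
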