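#' Per-species rarity-weighted richness
#'
#' For one species, each cell's RWR is the ratio of the species' range area
#' inside the cell to its global range area, zeroed where the cell's
#' elevation lies outside the species' envelope (elevation filtering of the
#' range). Ranges are cell-aligned masks, so the within-cell range area is
#' the full cell area on range cells.
#'
#' @param species A `synthetic_species` (see [synthetic_species()]).
#' @param dem Elevation raster (m) on `grid`.
#' @param grid The shared [grid_spec()].
#' @return [continuous_raster()] of per-cell RWR (unitless, >= 0).
#' @export
species_rwr <- function(species, dem, grid) {
  check_same_grid(grid, dem)
  if (species$global_range_area <= 0)
    stop("species_rwr: global_range_area must be > 0")
  v <- matrix(0, grid$n_rows, grid$n_cols)
  cells <- species$cells
  z <- dem$values[cells]
  ok <- !is.na(z) & z >= species$elevation_min & z <= species$elevation_max
  v[cells[ok]] <- cell_area_ha(grid) / species$global_range_area
  v[is.na(dem$values)] <- NA_real_
  continuous_raster(grid, v)
}

#' Aggregate RWR over species
#'
#' Cell-wise sum of per-species RWR rasters.
#' @param rwr_list List of [continuous_raster()]s on one grid.
#' @return [continuous_raster()] of aggregated RWR.
#' @export
aggregate_rwr <- function(rwr_list) {
  stopifnot(length(rwr_list) >= 1)
  do.call(check_same_grid, rwr_list)
  acc <- rwr_list[[1L]]$values
  for (r in rwr_list[-1L]) acc <- acc + r$values
  continuous_raster(rwr_list[[1L]]$grid, acc)
}

#' Transform aggregated RWR to the rarity index
#'
#' A log transform reduces the right skew of aggregated RWR, the scores are
#' divided by their mean so an average cell scores exactly 1, and the
#' result is floored at `ri_floor` to avoid zero or negative weights.
#' Two log variants are provided:
#' * `"log1p_scaled"` (default): `t_i = ln(1 + rwr_i / rbar)` with `rbar`
#'   the mean of positive RWR — unit-free and defined at `rwr = 0`;
#' * `"raw_log"`: `t_i = ln(rwr_i)` with zeros excluded from the mean and
#'   floored after normalization — the literal reading when all cells have
#'   positive RWR.
#'
#' @param rwr_aggregated [continuous_raster()] of aggregated RWR (>= 0).
#' @param ri_floor Minimum RI (default 0.05).
#' @param method `"log1p_scaled"` or `"raw_log"`.
#' @return [continuous_raster()] of RI (>= `ri_floor`; mean of the
#'   pre-floor scores over valid cells is 1).
#' @export
rwr_to_ri <- function(rwr_aggregated, ri_floor = 0.05,
                      method = c("log1p_scaled", "raw_log")) {
  method <- match.arg(method)
  stopifnot(ri_floor > 0)
  v <- rwr_aggregated$values
  valid <- !is.na(v)
  if (any(v[valid] < 0)) stop("rwr_to_ri: negative aggregated RWR")
  out <- matrix(NA_real_, nrow(v), ncol(v))
  pos <- valid & v > 0
  if (!any(pos)) {
    warning("rwr_to_ri: aggregated RWR is zero everywhere; RI = floor")
    out[valid] <- ri_floor
    return(continuous_raster(rwr_aggregated$grid, out))
  }
  if (method == "log1p_scaled") {
    rbar <- mean(v[pos])
    t_ <- log1p(v / rbar)
  } else {
    t_ <- suppressWarnings(log(v))
    t_[valid & v == 0] <- NA_real_  # raw log undefined at 0; floored below
  }
  s <- t_ / mean(t_[valid & !is.na(t_)])
  out[valid] <- pmax(s[valid], ri_floor)
  out[valid & is.na(s)] <- ri_floor
  continuous_raster(rwr_aggregated$grid, out)
}
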