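#' Downscale national production to per-cell yields
#'
#' Yields are the national production spread over cocoa cells by relative
#' cultivation suitability:
#' `Y_i = S_i * PD / (sum_j S_j * A_j * year)` on cocoa cells, 0 elsewhere,
#' in t ha^-1 yr^-1, so that `sum_i Y_i * A_i * year` returns the national
#' production exactly.
#'
#' @param suitability [continuous_raster()], strictly positive on cocoa
#'   cells.
#' @param cocoa_mask 0/1 matrix of cocoa cells (at least one).
#' @param total_production National production `PD` (t, > 0).
#' @param years Land-occupation time matching `PD` (default 1 season).
#' @return [continuous_raster()] of yields.
#' @export
downscale_yield <- function(suitability, cocoa_mask, total_production,
                            years = 1) {
  stopifnot(total_production > 0, years > 0)
  g <- suitability$grid
  ci <- which(cocoa_mask == 1L)
  if (!length(ci)) stop("downscale_yield: empty cocoa mask")
  s <- suitability$values[ci]
  if (anyNA(s) || any(s <= 0))
    stop("downscale_yield: suitability must be > 0 on every cocoa cell")
  a <- cell_area_ha(g)
  denom <- sum(s * a * years)
  y <- matrix(0, g$n_rows, g$n_cols)
  y[ci] <- s * total_production / denom
  bf_audit("downscale_yield", production_t = total_production,
           cocoa_ha = length(ci) * a)
  continuous_raster(g, y)
}

#' Total land-use biodiversity impact per cell
#'
#' Cell-wise `(1 - MSA_i) * RI_i * A_i` in biodiversity-weighted hectares —
#' the intactness lost to all human pressures, weighted by how important
#' the cell's biodiversity is.
#'
#' @param msa_total [continuous_raster()] of MSA in `[0,1]`.
#' @param ri [continuous_raster()] of the rarity index.
#' @param grid Shared [grid_spec()].
#' @return List: `raster` ([continuous_raster()]) and `total` (scalar sum
#'   over valid cells).
#' @export
bim_total <- function(msa_total, ri, grid) {
  check_same_grid(grid, msa_total, ri)
  a <- cell_area_ha(grid)
  v <- (1 - msa_total$values) * ri$values * a
  total <- sum(v, na.rm = TRUE)
  bf_audit("bim_total", bim_weighted_ha = total)
  list(raster = continuous_raster(grid, v), total = total)
}

#' Cocoa-attributable biodiversity impact per cell
#'
#' Cell-wise `(MSA_nv,i - MSA_i) * RI_i * A_i` restricted to cocoa cells
#' (zero elsewhere), where the loss is the counterfactual MSA difference
#' from [msa_loss_cocoa()] (already clamped at 0).
#'
#' @param msa_loss [continuous_raster()] of clamped counterfactual loss.
#' @param ri [continuous_raster()] of the rarity index.
#' @param cocoa_mask 0/1 matrix.
#' @param grid Shared [grid_spec()].
#' @return List: `raster` and `total` as in [bim_total()].
#' @export
bim_cocoa <- function(msa_loss, ri, cocoa_mask, grid) {
  check_same_grid(grid, msa_loss, ri)
  a <- cell_area_ha(grid)
  v <- msa_loss$values * ri$values * a
  v[cocoa_mask != 1L] <- 0
  v[is.na(msa_loss$values) | is.na(ri$values)] <- NA_real_
  total <- sum(v, na.rm = TRUE)
  bf_audit("bim_cocoa", bim_weighted_ha = total)
  list(raster = continuous_raster(grid, v), total = total)
}

#' Per-cell biodiversity factor of production
#'
#' `BF_i = BIM_cocoa,i / (Y_i * A_i * year)` on cocoa cells, in
#' ha yr t^-1 — the biodiversity impact embodied in one tonne produced in
#' that cell. Zero yield on a cocoa cell is an error.
#'
#' @param bim_cocoa_raster [continuous_raster()] from [bim_cocoa()].
#' @param yield_raster [continuous_raster()] from [downscale_yield()].
#' @param cocoa_mask 0/1 matrix.
#' @param years Land-occupation time (must match [downscale_yield()]).
#' @return [continuous_raster()]: BF on cocoa cells, `NA` elsewhere.
#' @export
bf_cocoa <- function(bim_cocoa_raster, yield_raster, cocoa_mask, years = 1) {
  g <- check_same_grid(bim_cocoa_raster, yield_raster)
  ci <- which(cocoa_mask == 1L)
  if (!length(ci)) stop("bf_cocoa: empty cocoa mask")
  y <- yield_raster$values[ci]
  if (anyNA(y) || any(y <= 0)) stop("bf_cocoa: zero yield on a cocoa cell")
  a <- cell_area_ha(g)
  v <- matrix(NA_real_, g$n_rows, g$n_cols)
  v[ci] <- bim_cocoa_raster$values[ci] / (y * a * years)
  continuous_raster(g, v)
}

#' Aggregate impacts and factors by department
#'
#' Per department: production (`sum Y*A*year`), cocoa and total
#' biodiversity impacts (sums), their share, and the biodiversity factor as
#' the plain mean of cell BF over the department's cocoa cells (`bf_all`),
#' split by cultivation system (`bf_fullsun`, `bf_agro`). A
#' production-weighted factor (`bf_weighted = bim_cocoa / production`) is
#' also reported: it is the variant under which flow attribution is exactly
#' mass-consistent. Departments without cocoa get `NA` factors, not 0.
#'
#' @param departments [categorical_raster()] of department ids.
#' @param yield_raster,bf_raster,bim_cocoa_raster,bim_total_raster Layers
#'   from the impact stage.
#' @param cocoa_mask 0/1 matrix; `cocoa_type_mask` 1 = full_sun,
#'   2 = agroforestry.
#' @param cocoa_type_mask Type matrix.
#' @param years Occupation time.
#' @return `data.table`: `department_id`, `department`, `production_t`,
#'   `bf_all`, `bf_fullsun`, `bf_agro`, `bf_weighted`, `bim_cocoa`,
#'   `bim_total`, `share`.
#' @export
department_aggregate <- function(departments, yield_raster, bf_raster,
                                 bim_cocoa_raster, bim_total_raster,
                                 cocoa_mask, cocoa_type_mask, years = 1) {
  g <- check_same_grid(departments, yield_raster, bf_raster,
                       bim_cocoa_raster, bim_total_raster)
  a <- cell_area_ha(g)
  dt <- data.table::data.table(
    code = as.vector(departments$codes),
    y = as.vector(yield_raster$values),
    bf = as.vector(bf_raster$values),
    bc = as.vector(bim_cocoa_raster$values),
    bt = as.vector(bim_total_raster$values),
    cocoa = as.vector(cocoa_mask == 1L),
    agro = as.vector(cocoa_type_mask == 2L))
  dt <- dt[code != departments$nodata_code]
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  res <- dt[, {
    prod_t <- sum(y * a * years, na.rm = TRUE)
    bcs <- sum(bc, na.rm = TRUE)
    list(production_t = prod_t,
         bf_all = mean_or_na(bf[cocoa]),
         bf_fullsun = mean_or_na(bf[cocoa & !agro]),
         bf_agro = mean_or_na(bf[cocoa & agro]),
         bf_weighted = if (prod_t > 0) bcs / prod_t else NA_real_,
         bim_cocoa = bcs,
         bim_total = sum(bt, na.rm = TRUE))
  }, by = .(code)]
  res[, share := ifelse(bim_total > 0, bim_cocoa / bim_total, 0)]
  nm <- names(departments$legend)[match(res$code, departments$legend)]
  res[, department := nm]
  data.table::setnames(res, "code", "department_id")
  data.table::setorder(res, department_id)
  data.table::setcolorder(res, c("department_id", "department",
                                 "production_t", "bf_all", "bf_fullsun",
                                 "bf_agro", "bf_weighted", "bim_cocoa",
                                 "bim_total", "share"))
  res[]
}
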