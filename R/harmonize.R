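#' Nine-class land-use legend
#'
#' The harmonized legend: primary_forest, lightly_used_natural_forest,
#' secondary_forest, plantation_forest, primary_vegetation,
#' low_input_agriculture, agroforestry, pasture, built_up.
#' @return Named integer vector code per class.
#' @export
landuse_legend <- function() {
  c(primary_forest = 1L, lightly_used_natural_forest = 2L,
    secondary_forest = 3L, plantation_forest = 4L, primary_vegetation = 5L,
    low_input_agriculture = 6L, agroforestry = 7L, pasture = 8L,
    built_up = 9L)
}

#' Construct a land-use raster
#'
#' A [categorical_raster()] on the nine-class legend plus companion masks:
#' `cocoa_mask` (0/1) and `cocoa_type_mask` (full_sun/agroforestry where
#' cocoa is present). Cocoa cells always carry land-use code
#' low_input_agriculture (full-sun) or agroforestry (shaded), since those
#' are the classes cocoa is re-expressed as for intactness modelling.
#'
#' @param grid [grid_spec()].
#' @param codes Land-use code matrix.
#' @param cocoa_mask 0/1 matrix.
#' @param cocoa_type Matrix with 1 = full_sun, 2 = agroforestry on cocoa
#'   cells, nodata elsewhere.
#' @return A `landuse_raster` (also a `categorical_raster`).
#' @export
landuse_raster <- function(grid, codes, cocoa_mask, cocoa_type) {
  r <- categorical_raster(grid, codes, landuse_legend())
  leg <- landuse_legend()
  cm <- matrix(as.integer(cocoa_mask), grid$n_rows, grid$n_cols)
  ct <- matrix(as.integer(cocoa_type), grid$n_rows, grid$n_cols)
  bad <- cm == 1L & !(r$codes %in% leg[c("low_input_agriculture", "agroforestry")])
  if (any(bad))
    stop("landuse_raster: cocoa cells must be low_input_agriculture or ",
         "agroforestry")
  if (any(cm == 1L & !(ct %in% c(1L, 2L))))
    stop("landuse_raster: cocoa cells need a full_sun/agroforestry type")
  r$cocoa_mask <- cm
  r$cocoa_type_mask <- ct
  class(r) <- c("landuse_raster", class(r))
  r
}

#' Greedy pasture allocation by suitability
#'
#' Selects candidate cells in strictly decreasing suitability order
#' (ties broken by row-major cell order) until the selected area reaches
#' the budget or candidates run out. Every selected cell's suitability is
#' >= every unselected candidate's.
#'
#' @param candidate_mask Logical matrix of candidate cells
#'   (herbaceous or shrub in the base map).
#' @param suitability [continuous_raster()] defined on all candidates.
#' @param area_budget Target pasture area (ha, >= 0).
#' @param grid [grid_spec()] shared by the layers.
#' @return Integer vector of selected linear cell indices.
#' @export
allocate_pasture <- function(candidate_mask, suitability, area_budget, grid) {
  if (area_budget < 0) stop("allocate_pasture: negative area budget")
  check_same_grid(grid, suitability)
  cand <- which(candidate_mask)
  if (!length(cand) || area_budget == 0) return(integer(0))
  sv <- suitability$values[cand]
  if (anyNA(sv)) stop("allocate_pasture: suitability undefined on candidates")
  # row-major (row, col) tie-break: order by row-major rank, column-major
  # storage means computing the row-major index explicitly
  nr <- grid$n_rows
  rowmajor <- ((cand - 1L) %% nr) * grid$n_cols + ((cand - 1L) %/% nr)
  ord <- order(-sv, rowmajor)
  a <- cell_area_ha(grid)
  n_needed <- min(length(cand), ceiling(area_budget / a - 1e-12))
  sel <- cand[ord[seq_len(n_needed)]]
  got <- length(sel) * a
  if (got < area_budget)
    bf_log("warn", "allocate_pasture: budget %.6g ha exceeds candidate area %.6g ha; saturated",
           area_budget, got)
  bf_audit("allocate_pasture", budget_ha = area_budget, allocated_ha = got)
  sel
}

#' Split forest cells into the four forest land-use classes
#'
#' Management class decides first (primary -> primary_forest, plantation ->
#' plantation_forest); remaining forest splits on the integrity index:
#' `integrity >= flii_threshold` -> lightly_used_natural_forest, else
#' secondary_forest. The four masks partition the forest mask.
#'
#' @param forest_mask Logical matrix of forest base cells.
#' @param management [categorical_raster()] with classes
#'   primary/plantation/other on forest cells.
#' @param integrity [continuous_raster()], 0-10 integrity index.
#' @param flii_threshold Split point on the integrity scale.
#' @return List of logical matrices: `primary_forest`, `plantation_forest`,
#'   `lightly_used_natural_forest`, `secondary_forest`.
#' @export
classify_forest <- function(forest_mask, management, integrity, flii_threshold) {
  check_same_grid(management, integrity)
  mg <- management$codes
  pri <- forest_mask & mg == class_code(management$legend, "primary")
  pla <- forest_mask & mg == class_code(management$legend, "plantation")
  rest <- forest_mask & !pri & !pla
  iv <- integrity$values
  lightly <- rest & !is.na(iv) & iv >= flii_threshold
  secondary <- rest & !lightly
  list(primary_forest = pri, plantation_forest = pla,
       lightly_used_natural_forest = lightly, secondary_forest = secondary)
}

#' Harmonize a landscape bundle into the nine-class land-use raster
#'
#' Priority-ordered allocation; later steps never overwrite earlier ones:
#' 1. cocoa cells (highest priority), typed full-sun -> low_input_agriculture
#'    or agroforestry -> agroforestry by the shade hint;
#' 2. remaining agriculture base cells -> low_input_agriculture or
#'    agroforestry (shade hint where defined, low-input otherwise);
#' 3. pasture on herbaceous/shrub cells, greedy by livestock-derived
#'    suitability up to the national area budget;
#' 4. forest cells via [classify_forest()];
#' 5. remaining vegetated cells -> primary_vegetation;
#' 6. bare/infrastructure -> built_up.
#' Water cells are nodata in the output and excluded from every budget.
#'
#' @param bundle A `landscape_bundle` from [generate_landscape()] (or an
#'   equivalent read from disk).
#' @param cfg Run configuration from [load_config()]; uses
#'   `pasture_area_budget` and `flii_threshold`.
#' @return A [landuse_raster()].
#' @export
harmonize <- function(bundle, cfg = default_config()) {
  g <- check_same_grid(bundle$base_landcover, bundle$cocoa_presence,
                       bundle$cocoa_shade_hint, bundle$forest_management,
                       bundle$forest_integrity, bundle$livestock_density,
                       bundle$pnv, bundle$suitability, bundle$dem)
  bl <- base_legend(); lu <- landuse_legend()
  base <- bundle$base_landcover$codes
  out <- matrix(-1L, g$n_rows, g$n_cols)
  water <- base == bl[["water"]] | base == bundle$base_landcover$nodata_code
  unalloc <- function() out == -1L & !water

  # 1. cocoa, highest priority
  cocoa <- bundle$cocoa_presence$codes == 1L & !water
  shade <- bundle$cocoa_shade_hint$codes
  out[cocoa & shade == 2L] <- lu[["agroforestry"]]
  out[cocoa & shade != 2L] <- lu[["low_input_agriculture"]]
  cocoa_mask <- ifelse(cocoa, 1L, 0L)
  cocoa_type <- matrix(-1L, g$n_rows, g$n_cols)
  cocoa_type[cocoa] <- ifelse(shade[cocoa] == 2L, 2L, 1L)

  # 2. other agriculture
  ag <- unalloc() & base == bl[["agriculture"]]
  out[ag & shade == 2L] <- lu[["agroforestry"]]
  out[ag & shade != 2L] <- lu[["low_input_agriculture"]]

  # 3. pasture (herbaceous/shrub candidates, greedy on suitability)
  cand <- unalloc() & (base == bl[["herbaceous"]] | base == bl[["shrub"]])
  sel <- allocate_pasture(cand, bundle$livestock_density,
                          cfg$pasture_area_budget, g)
  out[sel] <- lu[["pasture"]]
  # PNV attribution of pasture, logged only (no separate MSA classes)
  if (length(sel)) {
    pnv_forest <- sum(bundle$pnv$codes[sel] ==
                        class_code(bundle$pnv$legend, "forest"))
    bf_audit("pasture_pnv_split",
             on_forest_pnv_ha = pnv_forest * cell_area_ha(g),
             on_grassland_pnv_ha = (length(sel) - pnv_forest) * cell_area_ha(g))
  }

  # 4. forest classes
  fmask <- unalloc() & base == bl[["forest"]]
  fparts <- classify_forest(fmask, bundle$forest_management,
                            bundle$forest_integrity, cfg$flii_threshold)
  for (cls in names(fparts)) out[fparts[[cls]]] <- lu[[cls]]

  # 5. residual vegetation
  veg <- unalloc() & (base %in% bl[c("herbaceous", "shrub", "forest")])
  out[veg] <- lu[["primary_vegetation"]]

  # 6. bare / infrastructure
  built <- unalloc() & (base %in% bl[c("bare", "infrastructure")])
  out[built] <- lu[["built_up"]]

  if (any(unalloc()))
    stop("harmonize: unallocated valid cells remain (allocation must partition)")

  a <- cell_area_ha(g)
  counts <- table(factor(out[!water], levels = lu, labels = names(lu)))
  do.call(bf_audit, c(list(step = "harmonize"),
                      as.list(setNames(as.numeric(counts) * a,
                                       paste0(names(counts), "_ha")))))
  landuse_raster(g, out, cocoa_mask, cocoa_type)
}
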