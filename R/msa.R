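#' Default MSA pressure-response parameters
#'
#' Config-driven cause-effect tables with a GLOBIO-style multiplicative
#' structure. These defaults are documented package configuration informed
#' by published GLOBIO-class tables — not a bit-exact GLOBIO-InVEST
#' parameter set — and every entry can be overridden via [msa_params()] or
#' a JSON parameter file.
#'
#' * `msa_lu`: land-use response in `[0,1]` per harmonized class
#'   (primary forest and primary vegetation 1.0; agroforestry 0.5 scored
#'   above low-input agriculture 0.3, reflecting shade-system benefits).
#' * `road_bands`: distance-banded infrastructure multipliers
#'   `(max_distance m, multiplier)`, 1.0 beyond the last band; applied to
#'   non-built-up cells (built-up impact already sits in `msa_lu`).
#' * `frag_response`: `(patch_area ha, multiplier)` breakpoints for natural
#'   habitat patches, piecewise-linear in log10(area), saturating at 1.
#'   Global GLOBIO-class curves saturate near 1e6 ha, which collapses to a
#'   constant on the desk-scale grids this package targets; the shipped
#'   curve keeps the documented shape but saturates at 1e4 ha so patch
#'   size is informative at those extents (override for continental runs).
#' * `natural_classes`: classes whose patches take the fragmentation
#'   response.
#'
#' @return An `msa_params` list.
#' @export
default_msa_params <- function() {
  msa_params(
    msa_lu = c(primary_forest = 1.0, lightly_used_natural_forest = 0.7,
               secondary_forest = 0.5, plantation_forest = 0.2,
               primary_vegetation = 1.0, low_input_agriculture = 0.3,
               agroforestry = 0.5, pasture = 0.3, built_up = 0.05),
    road_bands = list(c(500, 0.80), c(1500, 0.90), c(5000, 0.95)),
    frag_response = list(c(1, 0.45), c(10, 0.55), c(100, 0.70),
                         c(1000, 0.90), c(10000, 1.0)),
    natural_classes = c("primary_forest", "lightly_used_natural_forest",
                        "secondary_forest", "primary_vegetation"))
}

#' Construct and validate MSA parameters
#'
#' @param msa_lu Named vector, land-use class -> MSA in `[0,1]`;
#'   `primary_forest` must be 1 (the intact reference).
#' @param road_bands List of `c(max_distance_m, multiplier)` with strictly
#'   increasing distances and non-decreasing multipliers in `[0,1]`.
#' @param frag_response List of `c(patch_area_ha, multiplier)` breakpoints,
#'   non-decreasing multiplier in area.
#' @param natural_classes Character vector of fragmentation-eligible classes.
#' @return Validated `msa_params` list.
#' @export
msa_params <- function(msa_lu, road_bands, frag_response, natural_classes) {
  stopifnot(all(msa_lu >= 0 & msa_lu <= 1))
  if (!isTRUE(msa_lu[["primary_forest"]] == 1))
    stop("msa_params: msa_lu[primary_forest] must be 1 (reference state)")
  rd <- vapply(road_bands, `[`, 0, 1); rm_ <- vapply(road_bands, `[`, 0, 2)
  if (length(rd) && (any(diff(rd) <= 0) || any(rm_ < 0 | rm_ > 1) ||
                     any(diff(rm_) < 0)))
    stop("msa_params: road_bands need strictly increasing distances and ",
         "non-decreasing multipliers in [0,1]")
  fa <- vapply(frag_response, `[`, 0, 1); fm <- vapply(frag_response, `[`, 0, 2)
  if (any(diff(fa) <= 0) || any(fm < 0 | fm > 1) || any(diff(fm) < 0))
    stop("msa_params: frag_response must be non-decreasing in area, in [0,1]")
  if (!length(natural_classes)) stop("msa_params: natural_classes empty")
  structure(list(msa_lu = msa_lu, road_bands = road_bands,
                 frag_response = frag_response,
                 natural_classes = natural_classes),
            class = "msa_params")
}

#' Read/write MSA parameters as JSON
#' @param path JSON file.
#' @return [msa_params()] object (read) or `path` (write).
#' @export
read_msa_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  msa_params(msa_lu = unlist(p$msa_lu),
             road_bands = lapply(seq_len(nrow(p$road_bands)),
                                 function(i) as.numeric(p$road_bands[i, ])),
             frag_response = lapply(seq_len(nrow(p$frag_response)),
                                    function(i) as.numeric(p$frag_response[i, ])),
             natural_classes = p$natural_classes)
}

#' @rdname read_msa_params
#' @param params [msa_params()] to serialize.
#' @export
write_msa_params <- function(params, path) {
  jsonlite::write_json(
    list(msa_lu = as.list(params$msa_lu),
         road_bands = do.call(rbind, params$road_bands),
         frag_response = do.call(rbind, params$frag_response),
         natural_classes = params$natural_classes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Land-use MSA response
#'
#' Pure per-cell table lookup of `msa_lu` by land-use class.
#' @param landuse A [landuse_raster()].
#' @param params [msa_params()].
#' @return [continuous_raster()] in `[0,1]`; nodata outside the map.
#' @export
msa_landuse <- function(landuse, params = default_msa_params()) {
  leg <- landuse$legend
  present <- unique(landuse$codes[landuse$codes != landuse$nodata_code])
  unknown <- setdiff(names(leg)[match(present, leg)], names(params$msa_lu))
  if (length(unknown) || anyNA(match(present, leg)))
    stop("msa_landuse: land-use code without an msa_lu entry: ",
         paste(unknown, collapse = ", "))
  lut <- params$msa_lu[names(leg)]
  v <- matrix(NA_real_, landuse$grid$n_rows, landuse$grid$n_cols)
  idx <- match(landuse$codes, leg)
  ok <- !is.na(idx)
  v[ok] <- lut[idx[ok]]
  continuous_raster(landuse$grid, v)
}

# minimum distance from points to a set of polyline segments (brute force,
# vectorized over points per segment)
min_segment_distance <- function(px, py, roads) {
  d2 <- rep(Inf, length(px))
  for (line in roads) {
    for (k in seq_len(nrow(line) - 1L)) {
      ax <- line[k, 1]; ay <- line[k, 2]
      bx <- line[k + 1L, 1]; by <- line[k + 1L, 2]
      vx <- bx - ax; vy <- by - ay
      L2 <- vx * vx + vy * vy
      t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
      dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
      d2 <- pmin(d2, dx * dx + dy * dy)
    }
  }
  sqrt(d2)
}

#' Infrastructure (road-proximity) MSA response
#'
#' Per cell, the Euclidean distance from the cell centre to the nearest
#' road segment is banded: the multiplier of the first band whose
#' `max_distance >= distance` applies; beyond the last band the response is
#' 1. Built-up cells get 1 (their impact is already in the land-use term).
#' An empty road set yields 1 everywhere.
#'
#' @param landuse [landuse_raster()].
#' @param roads List of polyline coordinate matrices in the grid CRS.
#' @param params [msa_params()].
#' @return [continuous_raster()] in `[0,1]`.
#' @export
msa_infrastructure <- function(landuse, roads, params = default_msa_params()) {
  g <- landuse$grid
  v <- matrix(1, g$n_rows, g$n_cols)
  if (length(roads) && length(params$road_bands)) {
    cc <- cell_centres(g)
    d <- min_segment_distance(as.vector(cc$x), as.vector(cc$y), roads)
    dmax <- vapply(params$road_bands, `[`, 0, 1)
    mult <- vapply(params$road_bands, `[`, 0, 2)
    band <- findInterval(d, dmax, left.open = TRUE) + 1L  # first band with dmax >= d
    vv <- ifelse(band > length(mult), 1, mult[pmin(band, length(mult))])
    v <- matrix(vv, g$n_rows, g$n_cols)
  }
  v[landuse$codes == landuse$legend[["built_up"]]] <- 1
  v[landuse$codes == landuse$nodata_code] <- NA_real_
  continuous_raster(g, v)
}

# connected components (4-connectivity) of a logical matrix; returns an
# integer matrix of component labels (0 outside the mask)
label_patches <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  pos <- match(seq_len(nr * nc), idx)  # cell -> vertex id in subgraph
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  # edges to the southern and eastern neighbour when both are in the mask
  e_s <- idx[r < nr][mask[idx[r < nr] + 1L]]
  e_e <- idx[cc < nc][mask[idx[cc < nc] + nr]]
  edges <- rbind(cbind(pos[e_s], pos[e_s + 1L]),
                 cbind(pos[e_e], pos[e_e + nr]))
  gph <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges)) gph <- igraph::add_edges(gph, t(edges))
  comp <- igraph::components(gph)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# piecewise-linear fragmentation response in log10(patch area), clamped to
# the first multiplier below the first breakpoint and saturating at the last
frag_multiplier <- function(area_ha, frag_response) {
  fa <- log10(vapply(frag_response, `[`, 0, 1))
  fm <- vapply(frag_response, `[`, 0, 2)
  approx(fa, fm, xout = log10(pmax(area_ha, 1e-12)), rule = 2)$y
}

#' Fragmentation MSA response
#'
#' Natural-habitat cells (classes in `natural_classes`) are grouped into
#' 4-connected patches; each cell takes the piecewise-linear (in log10
#' patch area) fragmentation multiplier of its patch. Non-natural cells
#' get 1.
#'
#' @param landuse [landuse_raster()].
#' @param params [msa_params()].
#' @return [continuous_raster()] in `[0,1]`.
#' @export
msa_fragmentation <- function(landuse, params = default_msa_params()) {
  g <- landuse$grid
  nat_codes <- landuse$legend[params$natural_classes]
  mask <- matrix(landuse$codes %in% nat_codes, g$n_rows, g$n_cols)
  v <- matrix(1, g$n_rows, g$n_cols)
  if (any(mask)) {
    lab <- label_patches(mask)
    sizes <- tabulate(lab[mask])
    mult <- frag_multiplier(sizes * cell_area_ha(g), params$frag_response)
    v[mask] <- mult[lab[mask]]
  }
  v[landuse$codes == landuse$nodata_code] <- NA_real_
  continuous_raster(g, v)
}

#' Compute all MSA layers
#'
#' `msa_total` is the cell-wise product of the land-use, infrastructure and
#' fragmentation responses (GLOBIO's multiplicative integration of
#' pressures), so it never exceeds any component.
#'
#' @param landuse [landuse_raster()].
#' @param roads Road polylines.
#' @param params [msa_params()].
#' @return List of [continuous_raster()]s: `msa_lu`, `msa_infra`,
#'   `msa_frag`, `msa_total`.
#' @export
compute_msa <- function(landuse, roads, params = default_msa_params()) {
  lu <- msa_landuse(landuse, params)
  inf <- msa_infrastructure(landuse, roads, params)
  fr <- msa_fragmentation(landuse, params)
  tot <- continuous_raster(landuse$grid, lu$values * inf$values * fr$values)
  structure(list(msa_lu = lu, msa_infra = inf, msa_frag = fr,
                 msa_total = tot), class = "msa_layers")
}

#' Pre-cultivation counterfactual land use
#'
#' Replaces every cocoa cell by primary forest (the reference
#' pre-cultivation condition); all other cells are untouched and the
#' output's cocoa mask is empty. Roads are retained downstream — only land
#' use changes in the counterfactual.
#'
#' @param landuse [landuse_raster()].
#' @return [landuse_raster()] with no cocoa.
#' @export
counterfactual_landuse <- function(landuse) {
  codes <- landuse$codes
  codes[landuse$cocoa_mask == 1L] <- landuse$legend[["primary_forest"]]
  empty <- matrix(0L, landuse$grid$n_rows, landuse$grid$n_cols)
  none <- matrix(-1L, landuse$grid$n_rows, landuse$grid$n_cols)
  landuse_raster(landuse$grid, codes, empty, none)
}

#' MSA loss attributable to cocoa cultivation
#'
#' Computes MSA under the actual land use and under the pre-cultivation
#' counterfactual ([counterfactual_landuse()]) and returns their difference
#' `MSA_nv - MSA`, clamped below at 0. The loss is reported on all cells —
#' removing cocoa also changes the fragmentation of neighbouring natural
#' patches — and the restriction to cocoa cells happens downstream in the
#' impact metric. Clamped cells are counted in the audit log.
#'
#' @param landuse [landuse_raster()].
#' @param roads Road polylines.
#' @param params [msa_params()].
#' @return List: `loss` ([continuous_raster()]), `msa` and `msa_nv`
#'   (the two `msa_layers` objects), `n_clamped`.
#' @export
msa_loss_cocoa <- function(landuse, roads, params = default_msa_params()) {
  msa <- compute_msa(landuse, roads, params)
  msa_nv <- compute_msa(counterfactual_landuse(landuse), roads, params)
  raw <- msa_nv$msa_total$values - msa$msa_total$values
  n_clamped <- sum(raw < 0, na.rm = TRUE)
  if (n_clamped > 0)
    bf_log("info", "msa_loss_cocoa: clamped %d negative-loss cells to 0",
           n_clamped)
  loss <- continuous_raster(landuse$grid, pmax(raw, 0))
  list(loss = loss, msa = msa, msa_nv = msa_nv, n_clamped = n_clamped)
}
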