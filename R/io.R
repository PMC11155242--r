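#' @import data.table
#' @importFrom stats approx quantile rgamma rnorm runif setNames convolve
#' @importFrom utils head tail
NULL

# ---- structured logging --------------------------------------------------

.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set pipeline log level
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @export
bf_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  options(biofoot.log_level = level)
  invisible(level)
}

bf_log <- function(level, fmt, ...) {
  current <- getOption("biofoot.log_level", "info")
  if (.log_levels[[level]] < .log_levels[[current]]) return(invisible(NULL))
  message(sprintf("[biofoot %s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

# audit line: every allocation/aggregation step reports hectares in and out
bf_audit <- function(step, ...) {
  kv <- list(...)
  body <- paste(sprintf("%s=%.6g", names(kv), unlist(kv)), collapse = " ")
  bf_log("info", "%s %s", step, body)
  invisible(data.table::data.table(step = step, as.data.table(kv)))
}

# ---- raster IO: ESRI ASCII grid + JSON sidecar ---------------------------

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Write a raster to disk
#'
#' Rasters are stored as single-band ESRI ASCII grids (`.asc`, plain text,
#' lower-left-corner georeferencing) with a JSON sidecar
#' (`<path>.meta.json`) carrying the CRS identifier, the raster kind and,
#' for categorical layers, the legend. The pair round-trips losslessly.
#'
#' @param r A [categorical_raster()] or [continuous_raster()].
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  g <- r$grid
  is_cat <- inherits(r, "categorical_raster")
  if (!is_cat && !inherits(r, "continuous_raster"))
    stop("write_raster: not a raster object")
  nodata <- if (is_cat) r$nodata_code else r$nodata_sentinel
  vals <- if (is_cat) r$codes else { v <- r$values; v[is.na(v)] <- nodata; v }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$n_cols),
               sprintf("nrows %d", g$n_rows),
               sprintf("xllcorner %.10g", g$origin_x),
               sprintf("yllcorner %.10g", g$origin_y - g$n_rows * g$cell_size),
               sprintf("cellsize %.10g", g$cell_size),
               sprintf("NODATA_value %.10g", nodata)), con)
  # row 1 of the matrix is the northernmost row, matching the ASC convention
  write.table(format(vals, digits = 17, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(crs_id = g$crs_id,
               kind = if (is_cat) "categorical" else "continuous")
  if (is_cat) meta$legend <- as.list(r$legend)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a raster from disk
#'
#' @param path Path to an `.asc` raster written by [write_raster()] (or any
#'   single-band ESRI ASCII grid with a biofoot JSON sidecar).
#' @param expected_kind `"categorical"` or `"continuous"`; mismatch with the
#'   sidecar is an error, never a silent coercion.
#' @return A [categorical_raster()] or [continuous_raster()].
#' @export
read_raster <- function(path, expected_kind = c("categorical", "continuous")) {
  expected_kind <- match.arg(expected_kind)
  if (!file.exists(path)) stop("read_raster: no such file: ", path)
  if (!file.exists(sidecar_path(path)))
    stop("read_raster: missing sidecar (CRS/legend) for ", path,
         "; refusing to guess metadata")
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (is.null(meta$crs_id) || !nzchar(meta$crs_id))
    stop("read_raster: unreadable CRS in sidecar of ", path)
  if (!identical(meta$kind, expected_kind))
    stop("read_raster: file is ", meta$kind, ", expected ", expected_kind)
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  hv <- setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                 tolower(vapply(kv, `[`, "", 1)))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hv)))
    stop("read_raster: malformed ASC header in ", path)
  g <- grid_spec(hv[["nrows"]], hv[["ncols"]], hv[["cellsize"]],
                 origin_x = hv[["xllcorner"]],
                 origin_y = hv[["yllcorner"]] + hv[["nrows"]] * hv[["cellsize"]],
                 crs_id = meta$crs_id)
  body <- scan(path, skip = 6L, quiet = TRUE)
  if (length(body) != g$n_rows * g$n_cols)
    stop("read_raster: expected ", g$n_rows * g$n_cols, " cells, got ",
         length(body), " (multi-band input is unsupported)")
  m <- matrix(body, g$n_rows, g$n_cols, byrow = TRUE)
  if (expected_kind == "categorical") {
    categorical_raster(g, m, legend = unlist(meta$legend),
                       nodata_code = hv[["nodata_value"]])
  } else {
    m[m == hv[["nodata_value"]]] <- NA_real_
    continuous_raster(g, m, nodata_sentinel = hv[["nodata_value"]])
  }
}

# ---- vector IO: GeoJSON via jsonlite -------------------------------------

#' Write road polylines to GeoJSON
#' @param roads List of two-column (x, y) coordinate matrices, one per line.
#' @param path Output path.
#' @param crs_id CRS identifier recorded as a foreign member.
#' @export
write_roads_geojson <- function(roads, path, crs_id = "EPSG:32630") {
  feats <- lapply(seq_along(roads), function(i) {
    m <- roads[[i]]
    list(type = "Feature", properties = list(id = i),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(m)),
                                              function(k) unname(m[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", crs_id = crs_id,
                            features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read road polylines from GeoJSON
#' @param path GeoJSON file of LineString features.
#' @return List of coordinate matrices (columns x, y).
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    co <- f$geometry$coordinates
    do.call(rbind, lapply(co, function(p) c(p[[1]], p[[2]])))
  })
}

#' Write polygons (departments) to GeoJSON
#' @param polys List of features, each `list(id=, name=, ring=)` where `ring`
#'   is a closed or open two-column (x, y) matrix of the outer boundary.
#' @param path Output path.
#' @param crs_id CRS identifier.
#' @export
write_polygons_geojson <- function(polys, path, crs_id = "EPSG:32630") {
  feats <- lapply(polys, function(p) {
    ring <- p$ring
    if (!isTRUE(all(ring[1, ] == ring[nrow(ring), ])))
      ring <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(id = p$id, name = p$name %||% as.character(p$id)),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) unname(ring[k, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", crs_id = crs_id,
                            features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#' @param path GeoJSON file of Polygon features with `id` (and `name`)
#'   properties.
#' @return List of `list(id, name, ring)` features.
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    list(id = as.integer(f$properties$id),
         name = f$properties$name %||% as.character(f$properties$id),
         ring = ring)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- species IO ----------------------------------------------------------

#' Write species ranges to GeoJSON
#'
#' Each species becomes one MultiPolygon feature (cell-aligned rectangles,
#' merged along row runs) with properties `id`, `elevation_min`,
#' `elevation_max`, `global_range_area` (ha).
#'
#' @param species List of species objects from [generate_species()].
#' @param grid The shared [grid_spec()].
#' @param path Output path.
#' @export
write_species_geojson <- function(species, grid, path) {
  s <- grid$cell_size
  feats <- lapply(species, function(sp) {
    mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
    mask[sp$cells] <- TRUE
    rects <- list()
    for (r in seq_len(grid$n_rows)) {
      run <- rle(mask[r, ])
      ends <- cumsum(run$lengths); starts <- ends - run$lengths + 1L
      for (k in which(run$values)) {
        x0 <- grid$origin_x + (starts[k] - 1L) * s
        x1 <- grid$origin_x + ends[k] * s
        y1 <- grid$origin_y - (r - 1L) * s
        y0 <- grid$origin_y - r * s
        rects[[length(rects) + 1L]] <-
          list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
      }
    }
    list(type = "Feature",
         properties = list(id = sp$species_id,
                           elevation_min = sp$elevation_min,
                           elevation_max = sp$elevation_max,
                           global_range_area = sp$global_range_area),
         geometry = list(type = "MultiPolygon", coordinates = rects))
  })
  jsonlite::write_json(list(type = "FeatureCollection", crs_id = grid$crs_id,
                            features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read species ranges from GeoJSON onto a grid
#'
#' Cells are assigned to a range by centre-point containment, so ranges
#' written by [write_species_geojson()] round-trip exactly.
#'
#' @param path GeoJSON written by [write_species_geojson()].
#' @param grid Target [grid_spec()].
#' @return List of species objects (see [generate_species()]).
#' @export
read_species_geojson <- function(path, grid) {
  gj <- jsonlite::read_json(path)
  cc <- cell_centres(grid)
  lapply(gj$features, function(f) {
    inside <- rep(FALSE, grid$n_rows * grid$n_cols)
    for (poly in f$geometry$coordinates) {
      ring <- do.call(rbind, lapply(poly[[1]], function(p) c(p[[1]], p[[2]])))
      inside <- inside | point_in_polygon(as.vector(cc$x), as.vector(cc$y), ring)
    }
    p <- f$properties
    synthetic_species(species_id = p$id, cells = which(inside),
                      elevation_min = p$elevation_min,
                      elevation_max = p$elevation_max,
                      global_range_area = p$global_range_area)
  })
}

# ---- tables & config -----------------------------------------------------

#' Write a table to CSV (UTF-8, "." decimal, header)
#' @param x A data.frame/data.table.
#' @param path Output path.
#' @export
write_table_csv <- function(x, path) {
  data.table::fwrite(as.data.table(x), path)
  invisible(path)
}

#' Read a CSV table
#' @param path CSV with header.
#' @return A data.table.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("read_table_csv: no such file: ", path)
  data.table::fread(path)
}

#' Load a run configuration
#'
#' Configuration is a JSON file; [default_config()] documents every field.
#' Unknown fields are an error (typo safety); missing fields take defaults.
#'
#' @param path JSON config file, or `NULL` for the full default.
#' @return A named list of validated run parameters.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("load_config: no such file: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("load_config: unknown config fields: ",
                          paste(bad, collapse = ", "))
    for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  }
  validate_config(cfg)
  cfg
}

#' Default run configuration
#'
#' @return Named list: `seed`; grid shape (`n_rows`, `n_cols`, `cell_size` m);
#'   `class_mix` (base land-cover proportions incl. a `cocoa` carve-out);
#'   `n_species`, `n_departments`, `n_exporters`, `n_importers`;
#'   `export_fraction` and `untraced_fraction` of export volume;
#'   `ri_floor` (0.05), `flii_threshold` (0-10 scale),
#'   `pasture_area_budget` (ha), `national_production` (t),
#'   `occupation_years` (1 = one season).
#' @export
default_config <- function() {
  list(seed = 1L,
       n_rows = 128L, n_cols = 128L, cell_size = 100,
       crs_id = "EPSG:32630",
       class_mix = c(forest = 0.35, herbaceous = 0.10, shrub = 0.08,
                     agriculture = 0.20, cocoa = 0.17, bare = 0.03,
                     infrastructure = 0.02, water = 0.05),
       n_species = 50L, n_departments = 12L,
       n_exporters = 10L, n_importers = 10L,
       export_fraction = 0.8, untraced_fraction = 0.544,
       ri_floor = 0.05, flii_threshold = 6,
       pasture_area_budget = 800, national_production = 2.2e6,
       occupation_years = 1)
}

validate_config <- function(cfg) {
  stopifnot(cfg$ri_floor > 0, cfg$pasture_area_budget >= 0,
            cfg$national_production > 0, cfg$occupation_years > 0,
            cfg$export_fraction >= 0, cfg$export_fraction <= 1,
            cfg$untraced_fraction >= 0, cfg$untraced_fraction <= 1)
  if (abs(sum(cfg$class_mix) - 1) > 1e-9)
    stop("validate_config: class_mix must sum to 1")
  invisible(cfg)
}
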