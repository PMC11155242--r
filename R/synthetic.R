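# ---- seeded randomness ---------------------------------------------------

# evaluate expr under a local RNG state; never clobbers the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage substream seed
#'
#' One global seed is fanned out by stage name so editing one stage's
#' parameters never perturbs another stage's randomness. The result is a
#' deterministic 31-bit integer.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character).
#' @return Integer seed < 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# ---- smoothed Gaussian noise fields --------------------------------------

# spatially autocorrelated field: white noise smoothed by a separable
# Gaussian kernel (edge-renormalized), then rank-standardized to U(0,1)
smooth_noise <- function(n_rows, n_cols, sigma = 6) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  band <- function(n) {
    m <- matrix(0, n, n)
    for (d in -half:half) {
      if (abs(d) >= n) next
      idx <- seq_len(n - abs(d))
      if (d >= 0) m[cbind(idx, idx + d)] <- k[d + half + 1L]
      else m[cbind(idx - d, idx)] <- k[d + half + 1L]
    }
    m / rowSums(m)
  }
  sm <- band(n_rows) %*% z %*% t(band(n_cols))
  # rank-standardize so quantile thresholds control class proportions exactly
  matrix(rank(sm, ties.method = "first") / (n_rows * n_cols), n_rows, n_cols)
}

# ---- landscape bundle ----------------------------------------------------

base_legend <- function() {
  c(forest = 1L, herbaceous = 2L, shrub = 3L, agriculture = 4L,
    bare = 5L, infrastructure = 6L, water = 7L)
}

#' Generate a synthetic landscape bundle
#'
#' Produces every raster, vector and support layer the pipeline consumes,
#' with the statistical structure the analysis assumes: spatially
#' autocorrelated class patches (smoothed-noise thresholding, not i.i.d.
#' cells), cocoa only on agriculture or forest base cells (encroachment),
#' strictly positive cultivation suitability on cocoa cells, and forest
#' integrity higher in large-patch interiors than at edges.
#'
#' @param seed Integer seed; a fixed seed reproduces the bundle bit-for-bit.
#' @param grid A [grid_spec()].
#' @param class_mix Named proportions over
#'   `forest, herbaceous, shrub, agriculture, cocoa, bare, infrastructure,
#'   water` summing to 1. `cocoa` is a carve-out overlaid on agriculture or
#'   forest base cells.
#' @param n_departments Number of administrative departments (jittered
#'   rectangular mosaic).
#' @param n_roads Number of road polylines crossing the domain.
#' @param agroforestry_share Share of cocoa cells hinted as agroforestry
#'   (remainder full-sun; full-sun dominates Ivorian cocoa).
#' @return A `landscape_bundle`: base_landcover, cocoa_presence,
#'   cocoa_shade_hint, forest_management, forest_integrity,
#'   livestock_density, pnv, suitability, dem (rasters); roads (polylines);
#'   departments (polygons).
#' @export
generate_landscape <- function(seed, grid,
                               class_mix = default_config()$class_mix,
                               n_departments = 12L, n_roads = 6L,
                               agroforestry_share = 0.35) {
  stopifnot(inherits(grid, "grid_spec"))
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("generate_landscape: class_mix must sum to 1 (got ", sum(class_mix), ")")
  known <- c(names(base_legend()), "cocoa")
  if (length(setdiff(names(class_mix), known)))
    stop("generate_landscape: unknown classes: ",
         paste(setdiff(names(class_mix), known), collapse = ", "))
  p <- setNames(numeric(length(known)), known)
  p[names(class_mix)] <- class_mix
  # cocoa encroaches on an existing agricultural/forest matrix; require that
  # matrix to be at least as large as the cocoa overlay
  if (p[["cocoa"]] > p[["agriculture"]] + p[["forest"]])
    stop("generate_landscape: cocoa proportion exceeds agriculture+forest")

  with_seed(seed, {
    nr <- grid$n_rows; nc <- grid$n_cols; n <- nr * nc
    leg <- base_legend()

    # base map: one autocorrelated field cut at cumulative quantiles, class
    # order chosen so ecologically adjacent classes share patch boundaries.
    # cocoa cells sit on agriculture (70%) or forest (30%) base cells, so
    # those base shares grow by the matching cocoa portion.
    cocoa_ag_share <- 0.7
    base_p <- p[names(leg)]
    base_p[["agriculture"]] <- base_p[["agriculture"]] +
      cocoa_ag_share * p[["cocoa"]]
    base_p[["forest"]] <- base_p[["forest"]] +
      (1 - cocoa_ag_share) * p[["cocoa"]]
    ord <- c("water", "forest", "shrub", "herbaceous", "agriculture",
             "bare", "infrastructure")
    f_base <- smooth_noise(nr, nc, sigma = max(3, round(min(nr, nc) / 24)))
    cuts <- cumsum(base_p[ord])
    codes <- matrix(leg[[ord[1L]]], nr, nc)
    for (k in seq_along(ord)[-1L])
      codes[f_base > cuts[k - 1L]] <- leg[[ord[k]]]
    base <- categorical_raster(grid, codes, leg)

    # cocoa overlay: top cells of its own field among candidates,
    # agriculture before forest (encroachment comes second)
    n_cocoa <- round(p[["cocoa"]] * n)
    f_cocoa <- smooth_noise(nr, nc, sigma = max(2, round(min(nr, nc) / 32)))
    cocoa <- matrix(0L, nr, nc)
    if (n_cocoa > 0) {
      cand_ag <- which(codes == leg[["agriculture"]])
      cand_fo <- which(codes == leg[["forest"]])
      take_ag <- cand_ag[order(f_cocoa[cand_ag], decreasing = TRUE)]
      take_ag <- take_ag[seq_len(min(length(take_ag),
                                     round(cocoa_ag_share * n_cocoa)))]
      left <- n_cocoa - length(take_ag)
      take_fo <- cand_fo[order(f_cocoa[cand_fo], decreasing = TRUE)]
      take_fo <- take_fo[seq_len(min(length(take_fo), left))]
      still <- n_cocoa - length(take_ag) - length(take_fo)
      if (still > 0) {
        extra <- setdiff(cand_ag, take_ag)
        extra <- extra[order(f_cocoa[extra], decreasing = TRUE)]
        take_ag <- c(take_ag, extra[seq_len(min(length(extra), still))])
      }
      cocoa[c(take_ag, take_fo)] <- 1L
    }
    cocoa_presence <- categorical_raster(grid, cocoa,
                                         c(absent = 0L, present = 1L))

    # shade-system hint on cocoa cells only
    f_shade <- smooth_noise(nr, nc, sigma = max(2, round(min(nr, nc) / 16)))
    shade <- matrix(-1L, nr, nc)
    ci <- which(cocoa == 1L)
    if (length(ci)) {
      n_agro <- round(agroforestry_share * length(ci))
      agro <- ci[order(f_shade[ci], decreasing = TRUE)][seq_len(n_agro)]
      shade[ci] <- 1L
      shade[agro] <- 2L
    }
    cocoa_shade_hint <- categorical_raster(
      grid, shade, c(full_sun = 1L, agroforestry = 2L))

    # forest management: blobs of primary / plantation / other within forest
    f_mgmt <- smooth_noise(nr, nc, sigma = max(3, round(min(nr, nc) / 20)))
    mgmt <- matrix(-1L, nr, nc)
    fi <- which(codes == leg[["forest"]])
    if (length(fi)) {
      qs <- quantile(f_mgmt[fi], c(0.75, 0.9))
      mgmt[fi] <- 3L                        # other
      mgmt[fi][f_mgmt[fi] >= qs[1]] <- 1L   # primary: top quartile
      mgmt[fi][f_mgmt[fi] >= qs[2]] <- 2L   # plantation: top decile
    }
    forest_management <- categorical_raster(
      grid, mgmt, c(primary = 1L, plantation = 2L, other = 3L))

    # forest integrity (0-10): saturating in distance-to-edge of forest
    # patches, so interiors of large patches score high
    d_edge <- chamfer_distance(codes == leg[["forest"]])
    flii <- 10 * (1 - exp(-d_edge / 3)) + 0.3 * matrix(runif(n), nr, nc)
    flii <- pmin(pmax(flii, 0), 10)
    flii[codes != leg[["forest"]]] <- 0
    forest_integrity <- continuous_raster(grid, flii)

    livestock_density <- continuous_raster(
      grid, 50 * smooth_noise(nr, nc, sigma = max(3, round(min(nr, nc) / 16)))^2)

    f_pnv <- smooth_noise(nr, nc, sigma = max(4, round(min(nr, nc) / 12)))
    pnv <- categorical_raster(grid, ifelse(f_pnv > 0.4, 1L, 2L),
                              c(forest = 1L, grassland = 2L))

    # strictly positive everywhere: every cocoa cell has usable suitability
    suitability <- continuous_raster(
      grid, 0.2 + 0.8 * smooth_noise(nr, nc, sigma = max(3, round(min(nr, nc) / 16))))

    dem <- continuous_raster(
      grid, 50 + 850 * smooth_noise(nr, nc, sigma = max(4, round(min(nr, nc) / 10))))

    roads <- generate_roads(grid, n_roads)
    departments <- generate_departments(grid, n_departments)

    bf_audit("generate_landscape",
             total_ha = n * cell_area_ha(grid),
             cocoa_ha = sum(cocoa) * cell_area_ha(grid),
             forest_ha = sum(codes == leg[["forest"]]) * cell_area_ha(grid))

    structure(list(base_landcover = base, cocoa_presence = cocoa_presence,
                   cocoa_shade_hint = cocoa_shade_hint,
                   forest_management = forest_management,
                   forest_integrity = forest_integrity,
                   livestock_density = livestock_density, pnv = pnv,
                   suitability = suitability, dem = dem,
                   roads = roads, departments = departments),
              class = "landscape_bundle")
  })
}

# two-pass 3-4 chamfer approximation of distance-to-edge (in cells) inside
# a logical mask; 0 outside and at mask boundary cells
chamfer_distance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  inf <- nr + nc + 1
  d <- matrix(ifelse(mask, inf, 0), nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (d[r, cc] == 0) next
    up <- if (r > 1) d[r - 1, cc] + 1 else 1
    lf <- if (cc > 1) d[r, cc - 1] + 1 else 1
    d[r, cc] <- min(d[r, cc], up, lf)
  }
  for (r in rev(seq_len(nr))) for (cc in rev(seq_len(nc))) {
    if (d[r, cc] == 0) next
    dn <- if (r < nr) d[r + 1, cc] + 1 else 1
    rt <- if (cc < nc) d[r, cc + 1] + 1 else 1
    d[r, cc] <- min(d[r, cc], dn, rt)
  }
  d
}

generate_roads <- function(grid, n_roads) {
  if (n_roads == 0L) return(list())
  x0 <- grid$origin_x; x1 <- grid$origin_x + grid$n_cols * grid$cell_size
  y1 <- grid$origin_y; y0 <- grid$origin_y - grid$n_rows * grid$cell_size
  lapply(seq_len(n_roads), function(i) {
    if (runif(1) < 0.5) {  # west-east
      ya <- runif(1, y0, y1); yb <- runif(1, y0, y1)
      mid <- c(runif(1, x0, x1), runif(1, y0, y1))
      rbind(c(x0, ya), mid, c(x1, yb))
    } else {               # north-south
      xa <- runif(1, x0, x1); xb <- runif(1, x0, x1)
      mid <- c(runif(1, x0, x1), runif(1, y0, y1))
      rbind(c(xa, y1), mid, c(xb, y0))
    }
  })
}

# jittered rectangular mosaic covering the domain exactly: ky row bands,
# band b holding its own jittered column split, counts summing to n
generate_departments <- function(grid, n_departments) {
  n_departments <- as.integer(n_departments)
  stopifnot(n_departments >= 1L)
  ky <- max(1L, as.integer(floor(sqrt(n_departments))))
  per_band <- rep(n_departments %/% ky, ky)
  rem <- n_departments %% ky
  if (rem > 0) per_band[seq_len(rem)] <- per_band[seq_len(rem)] + 1L
  s <- grid$cell_size
  x0 <- grid$origin_x; y1 <- grid$origin_y
  w <- grid$n_cols * s; h <- grid$n_rows * s
  jitter_cuts <- function(k, total) {
    if (k == 1L) return(c(0, total))
    cuts <- total * (seq_len(k - 1L) / k + runif(k - 1L, -0.25, 0.25) / k)
    # snap to cell edges so boundaries align with the grid, keep monotone
    cuts <- pmin(pmax(round(cuts / s) * s, s), total - s)
    c(0, sort(cuts), total)
  }
  yc <- jitter_cuts(ky, h)
  polys <- list(); id <- 0L
  for (b in seq_len(ky)) {
    xc <- jitter_cuts(per_band[b], w)
    ya <- y1 - yc[b + 1L]; yb <- y1 - yc[b]
    for (ix in seq_len(per_band[b])) {
      id <- id + 1L
      xa <- x0 + xc[ix]; xb <- x0 + xc[ix + 1L]
      polys[[id]] <- list(id = id, name = sprintf("DEPT_%02d", id),
                          ring = rbind(c(xa, ya), c(xb, ya),
                                       c(xb, yb), c(xa, yb)))
    }
  }
  polys
}

# ---- species -------------------------------------------------------------

#' Construct a synthetic species
#'
#' @param species_id Identifier.
#' @param cells Integer vector of linear cell indices of the range mask.
#' @param elevation_min,elevation_max Elevation envelope (m),
#'   `elevation_min < elevation_max`.
#' @param global_range_area Global range area (ha), at least the in-domain
#'   range area.
#' @return A `synthetic_species` object.
#' @export
synthetic_species <- function(species_id, cells, elevation_min, elevation_max,
                              global_range_area) {
  if (!(elevation_min < elevation_max))
    stop("synthetic_species: elevation_min must be < elevation_max")
  if (global_range_area <= 0)
    stop("synthetic_species: global_range_area must be > 0")
  structure(list(species_id = as.character(species_id),
                 cells = as.integer(cells),
                 elevation_min = as.numeric(elevation_min),
                 elevation_max = as.numeric(elevation_max),
                 global_range_area = as.numeric(global_range_area)),
            class = "synthetic_species")
}

#' Generate synthetic species ranges
#'
#' Ranges are connected blobs (seeded region growth) whose sizes follow a
#' right-skewed log-normal, so the aggregated rarity-weighted richness
#' surface is right-skewed like real range-map stacks. By default each
#' species' global range area equals its in-domain range area, making the
#' per-species RWR mass exactly 1 — the conservation testing hook; set
#' `global_inflation > 1` to emulate partially in-country ranges. Elevation
#' envelopes cover the range's elevations for most species; a fraction are
#' truncated so elevation filtering has bite.
#'
#' @param seed Integer seed.
#' @param n_species Number of species (>= 1).
#' @param grid A [grid_spec()].
#' @param dem Elevation raster on `grid` (m).
#' @param median_range_cells Median range size in cells of the log-normal.
#' @param sdlog Log-scale sd of the range-size distribution.
#' @param truncated_fraction Fraction of species whose elevation envelope
#'   clips part of their range.
#' @param global_inflation Multiplier (>= 1) on global range area.
#' @return List of `synthetic_species`.
#' @export
generate_species <- function(seed, n_species, grid, dem,
                             median_range_cells = NULL, sdlog = 1.1,
                             truncated_fraction = 0.1, global_inflation = 1) {
  stopifnot(n_species >= 1, global_inflation >= 1)
  check_same_grid(grid, dem)
  n <- grid$n_rows * grid$n_cols
  if (is.null(median_range_cells)) median_range_cells <- max(8, round(0.015 * n))
  with_seed(seed, {
    sizes <- pmax(1L, pmin(n, as.integer(round(
      exp(rnorm(n_species, log(median_range_cells), sdlog))))))
    truncated <- runif(n_species) < truncated_fraction
    lapply(seq_len(n_species), function(k) {
      cells <- grow_blob(grid$n_rows, grid$n_cols, sizes[k])
      zv <- dem$values[cells]
      if (truncated[k] && length(cells) > 4 && diff(range(zv)) > 1) {
        # envelope clips the top ~20% of the range's elevations
        emin <- min(zv) - 10
        emax <- as.numeric(quantile(zv, 0.8))
        if (emax <= emin) emax <- emin + 1
      } else {
        emin <- min(zv) - 10; emax <- max(zv) + 10
      }
      area <- length(cells) * cell_area_ha(grid) * global_inflation
      synthetic_species(sprintf("SP_%03d", k), cells, emin, emax, area)
    })
  })
}

# connected blob by uniform frontier growth from a random seed cell
grow_blob <- function(nr, nc, size) {
  n <- nr * nc
  start <- sample.int(n, 1L)
  in_blob <- logical(n)
  in_blob[start] <- TRUE
  frontier <- neighbours4(start, nr, nc)
  taken <- 1L
  while (taken < size && length(frontier)) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    if (!in_blob[pick]) {
      in_blob[pick] <- TRUE
      taken <- taken + 1L
      frontier <- c(frontier, neighbours4(pick, nr, nc))
    }
    frontier <- frontier[!in_blob[frontier]]
  }
  which(in_blob)
}

neighbours4 <- function(idx, nr, nc) {
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  out <- c(if (r > 1L) idx - 1L, if (r < nr) idx + 1L,
           if (cc > 1L) idx - nr, if (cc < nc) idx + nr)
  out
}

# ---- trade ---------------------------------------------------------------

#' Generate a synthetic subnational trade table
#'
#' Splits each department's production into traced export rows
#' (department known), untraced export rows (department `UNKNOWN`) and a
#' domestic remainder, conserving tonnes exactly. The untraced tonnage is
#' drawn proportionally from every department, mirroring indirect sourcing
#' through intermediaries; volumes across exporter x importer pairs follow
#' a seeded Dirichlet split.
#'
#' @param seed Integer seed.
#' @param dept_production Named numeric vector, department id -> tonnes
#'   (all >= 0).
#' @param spec List with `n_exporters`, `n_importers`,
#'   `untraced_fraction` and `export_fraction` (both in `[0, 1]`;
#'   default untraced share 0.544 of export volume).
#' @return A `data.table` with columns `department_id` (character id or
#'   `"UNKNOWN"`), `exporter`, `importer` (`"DOMESTIC"` for unexported
#'   volume), `volume_t`.
#' @export
generate_trade <- function(seed, dept_production,
                           spec = list(n_exporters = 10L, n_importers = 10L,
                                       untraced_fraction = 0.544,
                                       export_fraction = 0.8)) {
  if (any(dept_production < 0)) stop("generate_trade: negative production")
  u <- spec$untraced_fraction; ef <- spec$export_fraction
  if (u < 0 || u > 1) stop("generate_trade: untraced_fraction outside [0,1]")
  if (ef < 0 || ef > 1) stop("generate_trade: export_fraction outside [0,1]")
  exporters <- sprintf("EXP_%02d", seq_len(spec$n_exporters))
  importers <- sprintf("IMP_%02d", seq_len(spec$n_importers))
  with_seed(seed, {
    rows <- list()
    dirichlet <- function(k) { g <- rgamma(k, 1.2); g / sum(g) }
    for (d in names(dept_production)) {
      traced <- (1 - u) * ef * dept_production[[d]]
      if (traced > 0) {
        k <- min(4L, spec$n_exporters * spec$n_importers)
        pair_e <- sample(exporters, k, replace = TRUE)
        pair_i <- sample(importers, k, replace = TRUE)
        w <- dirichlet(k)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          department_id = d, exporter = pair_e, importer = pair_i,
          volume_t = traced * w)
      }
      domestic <- (1 - ef) * dept_production[[d]]
      if (domestic > 0)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          department_id = d, exporter = "DOMESTIC", importer = "DOMESTIC",
          volume_t = domestic)
    }
    untraced_total <- u * ef * sum(dept_production)
    if (untraced_total > 0) {
      k <- min(max(4L, spec$n_exporters), spec$n_exporters * spec$n_importers)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        department_id = "UNKNOWN",
        exporter = sample(exporters, k, replace = TRUE),
        importer = sample(importers, k, replace = TRUE),
        volume_t = untraced_total * dirichlet(k))
    }
    out <- data.table::rbindlist(rows)
    bf_audit("generate_trade", total_t = sum(out$volume_t),
             untraced_t = sum(out$volume_t[out$department_id == "UNKNOWN"]))
    out[]
  })
}
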