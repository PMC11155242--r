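# shared fixtures and independent oracles, built in code
options(biofoot.log_level = "error")

tiny_grid <- function(n = 4L, cell = 100) grid_spec(n, n, cell)

# uniform single-class land-use raster with optional cocoa cells
uniform_landuse <- function(grid, class, cocoa_cells = integer(0),
                            cocoa_type = 1L) {
  leg <- landuse_legend()
  codes <- matrix(leg[[class]], grid$n_rows, grid$n_cols)
  cm <- matrix(0L, grid$n_rows, grid$n_cols)
  ct <- matrix(-1L, grid$n_rows, grid$n_cols)
  if (length(cocoa_cells)) {
    codes[cocoa_cells] <- if (cocoa_type == 2L) leg[["agroforestry"]]
                          else leg[["low_input_agriculture"]]
    cm[cocoa_cells] <- 1L
    ct[cocoa_cells] <- cocoa_type
  }
  landuse_raster(grid, codes, cm, ct)
}

# hand-assemble a landscape bundle from explicit matrices (deterministic)
manual_bundle <- function(grid, base, cocoa = 0L, shade = -1L, mgmt = -1L,
                          flii = 0, livestock = 0, pnv = 2L, suit = 1,
                          dem = 100, roads = list(), departments = NULL) {
  m <- function(x) matrix(x, grid$n_rows, grid$n_cols)
  if (is.null(departments)) {
    w <- grid$n_cols * grid$cell_size; h <- grid$n_rows * grid$cell_size
    departments <- list(list(
      id = 1L, name = "DEPT_01",
      ring = rbind(c(grid$origin_x, grid$origin_y - h),
                   c(grid$origin_x + w, grid$origin_y - h),
                   c(grid$origin_x + w, grid$origin_y),
                   c(grid$origin_x, grid$origin_y))))
  }
  structure(list(
    base_landcover = categorical_raster(grid, m(base), biofoot:::base_legend()),
    cocoa_presence = categorical_raster(grid, m(cocoa),
                                        c(absent = 0L, present = 1L)),
    cocoa_shade_hint = categorical_raster(grid, m(shade),
                                          c(full_sun = 1L, agroforestry = 2L)),
    forest_management = categorical_raster(grid, m(mgmt),
                                           c(primary = 1L, plantation = 2L,
                                             other = 3L)),
    forest_integrity = continuous_raster(grid, m(flii)),
    livestock_density = continuous_raster(grid, m(livestock)),
    pnv = categorical_raster(grid, m(pnv), c(forest = 1L, grassland = 2L)),
    suitability = continuous_raster(grid, m(suit)),
    dem = continuous_raster(grid, m(dem)),
    roads = roads, departments = departments), class = "landscape_bundle")
}

# MSA params with fragmentation saturated (response identically 1) and/or
# no road effect, for isolating single pressures
params_no_frag <- function(params = default_msa_params()) {
  params$frag_response <- list(c(1, 1), c(10, 1))
  params
}
params_no_roads <- function(params = default_msa_params()) {
  params$road_bands <- list()
  params
}

# --- independent oracles --------------------------------------------------

# brute-force min distance from one point to polyline set
oracle_point_road_distance <- function(x, y, roads) {
  best <- Inf
  for (line in roads) for (k in seq_len(nrow(line) - 1L)) {
    a <- line[k, ]; b <- line[k + 1L, ]
    v <- b - a; L2 <- sum(v^2)
    t <- if (L2 == 0) 0 else max(0, min(1, sum((c(x, y) - a) * v) / L2))
    p <- a + t * v
    best <- min(best, sqrt(sum((c(x, y) - p)^2)))
  }
  best
}

# recursive-free flood fill labelling (4-connectivity), independent of
# the package's igraph-based labelling
oracle_flood_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[cur] != 0L) next
      lab[cur] <- nxt
      r <- ((cur - 1L) %% nr) + 1L; cc <- ((cur - 1L) %/% nr) + 1L
      for (nb in c(if (r > 1L) cur - 1L, if (r < nr) cur + 1L,
                   if (cc > 1L) cur - nr, if (cc < nc) cur + nr))
        if (mask[nb] && lab[nb] == 0L) stack <- c(stack, nb)
    }
  }
  lab
}

# third standardized moment (skewness), plain moment formula
oracle_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

expect_same_matrix <- function(a, b, tol = 0) {
  if (tol == 0) expect_identical(a, b) else expect_equal(a, b, tolerance = tol)
}
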