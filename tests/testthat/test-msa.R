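leg <- landuse_legend()

test_that("msa_landuse is a pure table lookup", {
  g <- tiny_grid(4)
  p <- default_msa_params()
  r1 <- msa_landuse(uniform_landuse(g, "primary_forest"), p)
  expect_true(all(r1$values == 1))
  r2 <- msa_landuse(uniform_landuse(g, "built_up"), p)
  expect_true(all(r2$values == 0.05))
  # mixed map vs dictionary-lookup loop oracle
  set.seed(2)
  codes <- matrix(sample(leg, 16, TRUE), 4, 4)
  lu <- landuse_raster(g, codes, matrix(0L, 4, 4), matrix(-1L, 4, 4))
  got <- msa_landuse(lu, p)
  for (i in 1:16) {
    cls <- names(leg)[match(codes[i], leg)]
    expect_identical(got$values[i], unname(p$msa_lu[[cls]]))
  }
  # unknown code errors
  p2 <- p; p2$msa_lu <- p$msa_lu[-3]
  expect_error(msa_landuse(lu, p2), "without an msa_lu entry")
})

test_that("msa_infrastructure bands distance to the nearest road", {
  g <- grid_spec(10, 10, 100)  # 1 km x 1 km
  lu <- uniform_landuse(g, "secondary_forest")
  p <- default_msa_params()
  expect_true(all(msa_infrastructure(lu, list(), p)$values == 1))
  # vertical road at x=0; distances are cell-centre x-coordinates
  road <- list(rbind(c(0, -1e4), c(0, 1e4)))
  p$road_bands <- list(c(500, 0.8), c(1500, 0.9))
  got <- msa_infrastructure(lu, road, p)
  cc <- cell_centres(g)
  expect_true(all(got$values[cc$x < 500] == 0.8))
  expect_true(all(got$values[cc$x > 500 & cc$x < 1500] == 0.9))
  # a built_up cell is exempt
  lu2 <- uniform_landuse(g, "built_up")
  expect_true(all(msa_infrastructure(lu2, road, p)$values == 1))
})

test_that("spec band example: 300/1000/2000 m from a straight road", {
  g <- grid_spec(1, 3, 200, origin_x = 0, origin_y = 200)
  # centres at x = 100, 300, 500 -> shift road so distances are 300/1000/2000
  lu <- uniform_landuse(g, "pasture")
  p <- default_msa_params()
  p$road_bands <- list(c(500, 0.8), c(1500, 0.9))
  d_of <- function(dist) {
    road <- list(rbind(c(100 + dist, -1e6), c(100 + dist, 1e6)))
    msa_infrastructure(lu, road, p)$values[1, 1]
  }
  expect_identical(d_of(300), 0.8)
  expect_identical(d_of(1000), 0.9)
  expect_identical(d_of(2000), 1)
})

test_that("msa_infrastructure matches the exhaustive distance oracle", {
  g <- grid_spec(32, 32, 100)
  lu <- uniform_landuse(g, "primary_vegetation")
  set.seed(5)
  roads <- lapply(1:4, function(i)
    matrix(runif(6, 0, 3200), 3, 2))
  p <- default_msa_params()
  got <- msa_infrastructure(lu, roads, p)
  cc <- cell_centres(g)
  dmax <- vapply(p$road_bands, `[`, 0, 1)
  mult <- vapply(p$road_bands, `[`, 0, 2)
  idx <- sample(1024, 60)  # spot-check a sample of cells
  for (i in idx) {
    d <- oracle_point_road_distance(cc$x[i], cc$y[i], roads)
    k <- which(dmax >= d)
    expected <- if (length(k)) mult[min(k)] else 1
    expect_equal(got$values[i], expected)
  }
})

test_that("msa_fragmentation follows patch size via the flood-fill oracle", {
  g <- grid_spec(20, 20, 100)  # 1 ha cells
  p <- default_msa_params()
  # no natural cells -> all 1
  expect_true(all(msa_fragmentation(uniform_landuse(g, "built_up"), p)$values == 1))
  # one giant natural patch above saturation -> its cells are penalized by
  # its own area; with a saturated table they are exactly 1
  big <- uniform_landuse(g, "primary_forest")
  expect_true(all(msa_fragmentation(big, params_no_frag())$values == 1))
  # two patches, 3 and 300 cells, embedded in non-natural matrix
  codes <- matrix(leg[["low_input_agriculture"]], 20, 20)
  codes[1, 1:3] <- leg[["secondary_forest"]]            # 3-cell patch
  codes[6:20, 1:20] <- leg[["primary_forest"]]          # 300-cell patch
  lu <- landuse_raster(g, codes, matrix(0L, 20, 20), matrix(-1L, 20, 20))
  got <- msa_fragmentation(lu, p)
  # oracle: independent flood fill + linear interpolation in log10(area)
  nat <- matrix(codes %in% leg[c("primary_forest", "secondary_forest",
                                 "lightly_used_natural_forest",
                                 "primary_vegetation")], 20, 20)
  lab <- oracle_flood_fill(nat)
  fa <- log10(vapply(p$frag_response, `[`, 0, 1))
  fm <- vapply(p$frag_response, `[`, 0, 2)
  for (i in which(nat)) {
    area <- sum(lab == lab[i]) * cell_area_ha(g)
    expected <- stats::approx(fa, fm, xout = log10(area), rule = 2)$y
    expect_equal(got$values[i], expected, tolerance = 1e-12)
  }
  expect_true(all(got$values[!nat] == 1))
  # the small patch is penalized more than the big one
  expect_lt(got$values[1, 1], got$values[10, 10])
})

test_that("enlarging a natural patch never decreases msa_frag on it", {
  g <- grid_spec(12, 12, 100)
  codes <- matrix(leg[["pasture"]], 12, 12)
  codes[4:6, 4:6] <- leg[["primary_forest"]]
  lu1 <- landuse_raster(g, codes, matrix(0L, 12, 12), matrix(-1L, 12, 12))
  f1 <- msa_fragmentation(lu1, default_msa_params())
  codes2 <- codes; codes2[4:9, 4:9] <- leg[["primary_forest"]]
  lu2 <- landuse_raster(g, codes2, matrix(0L, 12, 12), matrix(-1L, 12, 12))
  f2 <- msa_fragmentation(lu2, default_msa_params())
  patch1 <- codes == leg[["primary_forest"]]
  expect_true(all(f2$values[patch1] >= f1$values[patch1]))
})

test_that("compute_msa multiplies components and recovers parameters", {
  g <- grid_spec(8, 8, 100)
  # pristine: all primary forest, no roads, frag saturated
  pr <- compute_msa(uniform_landuse(g, "primary_forest"), list(),
                    params_no_frag())
  expect_true(all(pr$msa_total$values == 1))
  # parameter recovery: single class, no roads, saturated fragmentation
  for (cls in c("secondary_forest", "pasture", "agroforestry")) {
    m <- compute_msa(uniform_landuse(g, cls), list(), params_no_frag())
    expect_true(all(m$msa_total$values ==
                      default_msa_params()$msa_lu[[cls]]))
  }
  # product structure on a full synthetic landscape (per-cell oracle)
  b <- generate_landscape(21, grid_spec(24, 24, 100), n_departments = 2)
  lu <- harmonize(b, default_config())
  m <- compute_msa(lu, b$roads)
  prod_oracle <- m$msa_lu$values * m$msa_infra$values * m$msa_frag$values
  expect_equal(m$msa_total$values, prod_oracle, tolerance = 1e-15)
  expect_true(all(m$msa_total$values <= m$msa_lu$values + 1e-15, na.rm = TRUE))
  expect_true(all(m$msa_total$values <= m$msa_infra$values + 1e-15, na.rm = TRUE))
  expect_true(all(m$msa_total$values <= m$msa_frag$values + 1e-15, na.rm = TRUE))
  for (layer in m) {
    v <- layer$values
    expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  }
})

test_that("counterfactual replaces exactly the cocoa cells with primary forest", {
  g <- tiny_grid(6)
  lu0 <- uniform_landuse(g, "secondary_forest")
  expect_identical(counterfactual_landuse(lu0)$codes, lu0$codes)
  lu_all <- uniform_landuse(g, "low_input_agriculture",
                            cocoa_cells = 1:36, cocoa_type = 1L)
  cf <- counterfactual_landuse(lu_all)
  expect_true(all(cf$codes == leg[["primary_forest"]]))
  expect_identical(sum(cf$cocoa_mask), 0L)
  ci <- c(3L, 17L, 30L)
  lu_mix <- uniform_landuse(g, "lightly_used_natural_forest",
                            cocoa_cells = ci, cocoa_type = 2L)
  cf2 <- counterfactual_landuse(lu_mix)
  diff_cells <- which(cf2$codes != lu_mix$codes)
  expect_identical(diff_cells, ci)
})

test_that("msa_loss_cocoa equals an explicit double evaluation", {
  g <- grid_spec(9, 9, 100)
  # isolated cocoa cell in a large primary forest, no roads
  ci <- 41L  # centre
  lu <- uniform_landuse(g, "primary_forest", cocoa_cells = ci, cocoa_type = 1L)
  p <- params_no_frag()
  lr <- msa_loss_cocoa(lu, list(), p)
  expect_equal(lr$loss$values[ci], 1 - p$msa_lu[["low_input_agriculture"]],
               tolerance = 1e-15)
  expect_true(all(lr$loss$values[-ci] == 0))
  # double-evaluation oracle under active fragmentation
  p2 <- default_msa_params()
  lr2 <- msa_loss_cocoa(lu, list(), p2)
  msa_a <- compute_msa(lu, list(), p2)
  msa_b <- compute_msa(counterfactual_landuse(lu), list(), p2)
  oracle <- pmax(msa_b$msa_total$values - msa_a$msa_total$values, 0)
  expect_equal(lr2$loss$values, oracle, tolerance = 1e-15)
  # zero cocoa -> zero loss
  expect_true(all(msa_loss_cocoa(uniform_landuse(g, "pasture"), list(),
                                 p2)$loss$values == 0))
})

test_that("a cocoa strip bisecting forest leaks loss into neighbours", {
  g <- grid_spec(11, 11, 100)
  codes <- matrix(leg[["primary_forest"]], 11, 11)
  cm <- matrix(0L, 11, 11); ct <- matrix(-1L, 11, 11)
  codes[6, ] <- leg[["low_input_agriculture"]]
  cm[6, ] <- 1L; ct[6, ] <- 1L
  lu <- landuse_raster(g, codes, cm, ct)
  lr <- msa_loss_cocoa(lu, list(), default_msa_params())
  # neighbouring forest cells (rows 5 and 7) gain from patch reunification
  expect_true(all(lr$loss$values[5, ] > 0))
  expect_true(all(lr$loss$values[7, ] > 0))
  # and the oracle agrees
  msa_a <- compute_msa(lu, list(), default_msa_params())
  msa_b <- compute_msa(counterfactual_landuse(lu), list(),
                       default_msa_params())
  expect_equal(lr$loss$values,
               pmax(msa_b$msa_total$values - msa_a$msa_total$values, 0),
               tolerance = 1e-15)
})

test_that("adding a road never increases msa_total anywhere", {
  g <- grid_spec(16, 16, 100)
  b <- generate_landscape(23, g, n_departments = 2)
  lu <- harmonize(b, default_config())
  set.seed(99)
  base_roads <- list(rbind(c(0, 800), c(1600, 800)))
  m0 <- compute_msa(lu, base_roads)$msa_total$values
  for (rep in 1:10) {
    extra <- matrix(runif(4, 0, 1600), 2, 2)
    m1 <- compute_msa(lu, c(base_roads, list(extra)))$msa_total$values
    expect_true(all(m1 <= m0 + 1e-15, na.rm = TRUE))
  }
})

test_that("msa params validate and serialize", {
  p <- default_msa_params()
  f <- tempfile(fileext = ".json")
  write_msa_params(p, f)
  p2 <- read_msa_params(f)
  expect_equal(p2$msa_lu, p$msa_lu)
  expect_equal(p2$road_bands, p$road_bands)
  expect_equal(p2$frag_response, p$frag_response)
  expect_error(msa_params(c(primary_forest = 0.9), list(), list(c(1, 1)),
                          "x"),
               "primary_forest")
  bad <- p; bad$road_bands <- list(c(500, 0.9), c(400, 0.8))
  expect_error(do.call(msa_params, unclass(bad)), "road_bands")
})
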