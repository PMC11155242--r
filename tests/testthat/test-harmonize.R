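leg <- landuse_legend()
bl <- biofoot:::base_legend()

test_that("all-forest bundle yields forest classes + primary_vegetation only", {
  g <- tiny_grid(6)
  b <- manual_bundle(g, base = bl[["forest"]], mgmt = 3L, flii = 5)
  cfg <- default_config(); cfg$pasture_area_budget <- 0; cfg$flii_threshold <- 6
  lu <- harmonize(b, cfg)
  expect_identical(sum(lu$cocoa_mask), 0L)
  got <- unique(as.vector(lu$codes))
  expect_true(all(got %in% leg[c("primary_forest", "plantation_forest",
                                 "lightly_used_natural_forest",
                                 "secondary_forest", "primary_vegetation")]))
  # mgmt=other, flii below threshold -> all secondary forest here
  expect_true(all(lu$codes == leg[["secondary_forest"]]))
})

test_that("cocoa has highest priority, even inside forest", {
  g <- tiny_grid(4)
  base <- matrix(bl[["forest"]], 4, 4)
  cocoa <- matrix(0L, 4, 4); cocoa[2, 2] <- 1L; cocoa[3, 3] <- 1L
  shade <- matrix(-1L, 4, 4); shade[2, 2] <- 1L; shade[3, 3] <- 2L
  b <- manual_bundle(g, base = base, cocoa = cocoa, shade = shade,
                     mgmt = 1L, flii = 9)
  lu <- harmonize(b, default_config())
  expect_identical(lu$codes[2, 2], unname(leg[["low_input_agriculture"]]))
  expect_identical(lu$codes[3, 3], unname(leg[["agroforestry"]]))
  expect_identical(lu$cocoa_type_mask[2, 2], 1L)
  expect_identical(lu$cocoa_type_mask[3, 3], 2L)
  # everything else stayed forest
  expect_identical(sum(lu$codes == leg[["primary_forest"]]), 14L)
})

test_that("6x6 hand-built bundle walks all six allocation steps", {
  g <- tiny_grid(6)  # 1 ha cells
  # rows: 1 forest(primary mgmt), 2 forest(other, flii hi/lo), 3 agriculture,
  # 4 herbaceous, 5 shrub, 6 bare|infrastructure|water
  base <- matrix(bl[["forest"]], 6, 6)
  base[3, ] <- bl[["agriculture"]]
  base[4, ] <- bl[["herbaceous"]]
  base[5, ] <- bl[["shrub"]]
  base[6, 1:2] <- bl[["bare"]]; base[6, 3:4] <- bl[["infrastructure"]]
  base[6, 5:6] <- bl[["water"]]
  cocoa <- matrix(0L, 6, 6); cocoa[1, 1] <- 1L; cocoa[3, 1] <- 1L
  shade <- matrix(-1L, 6, 6); shade[1, 1] <- 2L; shade[3, 1] <- 1L
  shade[3, 4] <- 2L  # non-cocoa agriculture cell hinted agroforestry
  mgmt <- matrix(3L, 6, 6); mgmt[1, ] <- 1L; mgmt[2, 6] <- 2L
  flii <- matrix(2, 6, 6); flii[2, 1:3] <- 9
  live <- matrix(0, 6, 6); live[4, ] <- c(5, 3, 2, 1, 8, 9); live[5, ] <- 0.5
  cfg <- default_config()
  cfg$pasture_area_budget <- 3      # -> 3 best cells: (4,6)=9,(4,5)=8,(4,1)=5
  cfg$flii_threshold <- 6
  b <- manual_bundle(g, base = base, cocoa = cocoa, shade = shade,
                     mgmt = mgmt, flii = flii, livestock = live)
  lu <- harmonize(b, cfg)
  expected <- matrix(NA_integer_, 6, 6)
  expected[1, ] <- leg[["primary_forest"]]; expected[1, 1] <- leg[["agroforestry"]]
  expected[2, ] <- leg[["secondary_forest"]]
  expected[2, 1:3] <- leg[["lightly_used_natural_forest"]]
  expected[2, 6] <- leg[["plantation_forest"]]
  expected[3, ] <- leg[["low_input_agriculture"]]
  expected[3, 4] <- leg[["agroforestry"]]
  expected[4, ] <- leg[["primary_vegetation"]]
  expected[4, c(1, 5, 6)] <- leg[["pasture"]]
  expected[5, ] <- leg[["primary_vegetation"]]
  expected[6, ] <- c(rep(leg[["built_up"]], 2), rep(leg[["built_up"]], 2),
                     rep(-1L, 2))
  expect_identical(unname(lu$codes), unname(matrix(expected, 6, 6)))
  expect_identical(which(lu$cocoa_mask == 1L), which(cocoa == 1L))
})

test_that("allocate_pasture is greedy by suitability with budget saturation", {
  g <- tiny_grid(2)  # 4 cells of 1 ha
  suit <- continuous_raster(g, matrix(c(5, 3, 2, 1), 2, 2))
  cand <- matrix(TRUE, 2, 2)
  expect_identical(allocate_pasture(cand, suit, 0, g), integer(0))
  sel <- allocate_pasture(cand, suit, 2, g)
  expect_setequal(sel, which(suit$values >= 3))
  expect_error(allocate_pasture(cand, suit, -1, g), "negative")
  # saturation: budget above candidate area selects everything
  expect_setequal(allocate_pasture(cand, suit, 10, g), 1:4)
})

test_that("greedy pasture equals sorting oracle on random instances", {
  set.seed(42)
  g <- grid_spec(10, 10, 100)
  for (rep in 1:5) {
    cand <- matrix(runif(100) < 0.9, 10, 10)
    suit <- continuous_raster(g, matrix(runif(100), 10, 10))
    budget <- 37
    sel <- allocate_pasture(cand, suit, budget, g)
    # independent full-sort oracle
    cand_idx <- which(cand)
    oracle <- cand_idx[order(suit$values[cand_idx], decreasing = TRUE)][1:37]
    expect_setequal(sel, oracle)
    expect_identical(length(sel), 37L)
    # selected suitabilities dominate unselected candidates
    expect_gte(min(suit$values[sel]),
               max(suit$values[setdiff(cand_idx, sel)]))
  }
})

test_that("greedy pasture matches exhaustive top-k on all small instances", {
  g <- grid_spec(4, 5, 100)
  set.seed(7)
  for (rep in 1:20) {
    n_cand <- sample(0:20, 1)
    cand <- matrix(FALSE, 4, 5)
    cand[sample(20, n_cand)] <- TRUE
    suit <- continuous_raster(g, matrix(sample(100, 20), 4, 5))
    budget <- sample(0:20, 1)
    sel <- allocate_pasture(cand, suit, budget, g)
    k <- min(n_cand, budget)
    # exhaustive oracle: the k-subset maximizing total suitability is the
    # top-k by value (values distinct here); enumerate to confirm
    idx <- which(cand)
    if (k > 0 && n_cand <= 12) {
      combs <- matrix(idx[utils::combn(seq_along(idx), k)], nrow = k)
      sums <- colSums(matrix(suit$values[as.vector(combs)], nrow = k))
      best <- combs[, which.max(sums)]
      expect_setequal(sel, best)
    } else {
      expect_setequal(sel, idx[order(suit$values[idx],
                                     decreasing = TRUE)][seq_len(k)])
    }
  }
})

test_that("pasture ties break by row-major order", {
  g <- tiny_grid(2)
  suit <- continuous_raster(g, matrix(1, 2, 2))
  sel <- allocate_pasture(matrix(TRUE, 2, 2), suit, 2, g)
  # cells (1,1) and (1,2): linear indices 1 and 3 in column-major storage
  expect_setequal(sel, c(1L, 3L))
})

test_that("classify_forest partitions the forest mask per-cell", {
  g <- grid_spec(5, 5, 100)
  fmask <- matrix(TRUE, 5, 5)
  mgmt_all_primary <- categorical_raster(g, matrix(1L, 5, 5),
                                         c(primary = 1L, plantation = 2L,
                                           other = 3L))
  integ <- continuous_raster(g, matrix(5, 5, 5))
  p <- classify_forest(fmask, mgmt_all_primary, integ, 6)
  expect_true(all(p$primary_forest))
  expect_false(any(p$secondary_forest | p$lightly_used_natural_forest |
                     p$plantation_forest))

  mgmt_other <- categorical_raster(g, matrix(3L, 5, 5),
                                   c(primary = 1L, plantation = 2L, other = 3L))
  p2 <- classify_forest(fmask, mgmt_other, integ, 6)
  expect_true(all(p2$secondary_forest))

  set.seed(1)
  mgmt_mix <- categorical_raster(g, matrix(sample(1:3, 25, TRUE), 5, 5),
                                 c(primary = 1L, plantation = 2L, other = 3L))
  integ_mix <- continuous_raster(g, matrix(runif(25, 0, 10), 5, 5))
  p3 <- classify_forest(fmask, mgmt_mix, integ_mix, 6)
  # per-cell decision oracle
  for (i in 1:25) {
    expected <- if (mgmt_mix$codes[i] == 1L) "primary_forest"
      else if (mgmt_mix$codes[i] == 2L) "plantation_forest"
      else if (integ_mix$values[i] >= 6) "lightly_used_natural_forest"
      else "secondary_forest"
    hit <- vapply(p3, `[`, TRUE, i)
    expect_identical(names(which(hit)), expected)
  }
  # the four masks partition the forest mask
  expect_true(all(p3$primary_forest + p3$plantation_forest +
                    p3$lightly_used_natural_forest + p3$secondary_forest == 1))
})

test_that("harmonize partitions every valid base cell and logs budgets", {
  g <- grid_spec(32, 32, 100)
  b <- generate_landscape(11, g, n_departments = 2)
  lu <- harmonize(b, default_config())
  water <- b$base_landcover$codes == bl[["water"]]
  expect_identical(sum(lu$codes != lu$nodata_code), sum(!water))
  expect_true(all((lu$codes == lu$nodata_code) == water))
  # partition: class counts sum to valid count
  counts <- table(lu$codes[lu$codes != lu$nodata_code])
  expect_identical(sum(counts), sum(!water))
})

test_that("adding a cocoa cell never changes another cell's class", {
  g <- grid_spec(16, 16, 100)
  b <- generate_landscape(13, g, n_departments = 2)
  lu1 <- harmonize(b, default_config())
  # flag one extra non-cocoa agriculture-or-forest cell as cocoa
  cand <- which(b$base_landcover$codes %in% bl[c("agriculture", "forest")] &
                  b$cocoa_presence$codes == 0L)
  pick <- cand[1]
  b2 <- b
  b2$cocoa_presence$codes[pick] <- 1L
  lu2 <- harmonize(b2, default_config())
  changed <- which(lu1$codes != lu2$codes)
  expect_true(all(changed %in% pick))  # only the flipped cell may change
  expect_identical(lu2$cocoa_mask[pick], 1L)
})

test_that("harmonizing an already-harmonized landscape keeps cocoa and forest", {
  g <- grid_spec(24, 24, 100)
  b <- generate_landscape(17, g, n_departments = 2)
  lu1 <- harmonize(b, default_config())
  # re-express the land-use map as a bundle: forest classes -> forest base,
  # cocoa/agriculture -> agriculture base, management/integrity consistent
  forest_classes <- leg[c("primary_forest", "lightly_used_natural_forest",
                          "secondary_forest", "plantation_forest")]
  base2 <- matrix(bl[["herbaceous"]], 24, 24)
  base2[lu1$codes %in% forest_classes] <- bl[["forest"]]
  base2[lu1$codes %in% leg[c("low_input_agriculture", "agroforestry")]] <-
    bl[["agriculture"]]
  base2[lu1$codes == leg[["built_up"]]] <- bl[["bare"]]
  base2[lu1$codes == lu1$nodata_code] <- bl[["water"]]
  mgmt2 <- matrix(3L, 24, 24)
  mgmt2[lu1$codes == leg[["primary_forest"]]] <- 1L
  mgmt2[lu1$codes == leg[["plantation_forest"]]] <- 2L
  flii2 <- matrix(0, 24, 24)
  flii2[lu1$codes == leg[["lightly_used_natural_forest"]]] <- 10
  shade2 <- matrix(-1L, 24, 24)
  shade2[lu1$codes == leg[["agroforestry"]]] <- 2L
  shade2[lu1$codes == leg[["low_input_agriculture"]]] <- 1L
  cfg <- default_config(); cfg$pasture_area_budget <- 0
  b2 <- manual_bundle(g, base = base2, cocoa = lu1$cocoa_mask,
                      shade = shade2, mgmt = mgmt2, flii = flii2)
  lu2 <- harmonize(b2, cfg)
  expect_identical(lu2$cocoa_mask, lu1$cocoa_mask)
  expect_identical(lu2$cocoa_type_mask, lu1$cocoa_type_mask)
  keep <- lu1$codes %in% c(forest_classes,
                           leg[c("low_input_agriculture", "agroforestry")])
  expect_identical(lu2$codes[keep], lu1$codes[keep])
})
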