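test_that("zonal edge fractions match hand counts and flag empty zones", {
  zones <- matrix(rep(1:2, each = 8), 4, 4)
  forest <- matrix(FALSE, 4, 4)
  forest[, 1:2] <- TRUE              # zone 1 fully forest, zone 2 empty
  forest[1, 1] <- TRUE
  edge <- matrix(FALSE, 4, 4)
  edge[1:2, 1] <- TRUE               # 2 edge pixels of 8 forest
  zf <- zonal_edge_fraction(edge, forest, zones)
  expect_equal(zf$edge_fraction[zf$zone == 1], 2 / 8)
  expect_true(is.na(zf$edge_fraction[zf$zone == 2]))

  set.seed(31)
  ls <- generate_landscape(small_scenario(n_plots = 10), 30, 30, n_zones = 4)
  forest2 <- ls$land_cover == "forest"
  edge2 <- detect_anthropogenic_edges(ls$land_cover)
  zf2 <- zonal_edge_fraction(edge2, forest2, ls$zones)
  for (z in zf2$zone) {
    inz <- ls$zones == z
    expect_equal(zf2$n_forest[zf2$zone == z], sum(forest2 & inz))
    expect_equal(zf2$n_edge[zf2$zone == z], sum(edge2 & forest2 & inz))
  }
})

test_that("zone composition converts pixel counts to hectares exactly", {
  ft <- matrix(NA_character_, 10, 10)
  ft[1:10, 1:5] <- "Oak-Hickory"     # 50 pixels
  ft[1:10, 6:7] <- "Spruce-Fir"      # 20 pixels
  zones <- matrix(1L, 10, 10)
  comp <- zone_composition(ft, zones, pixel_area_ha = 0.09)
  expect_equal(comp$area_ha[comp$forest_type_group == "Oak-Hickory"], 4.5)
  expect_equal(sum(comp$area_ha), 70 * 0.09)
  # 100 pixels of one group equal 9 ha
  one <- matrix("Oak-Pine", 10, 10)
  expect_equal(zone_composition(one, zones)$area_ha, 9)
  # group mapping and unmapped codes
  raw <- matrix(c("oh1", "oh2", NA, "sf"), 2, 2)
  comp2 <- zone_composition(raw, matrix(1L, 2, 2),
                            group_map = c(oh1 = "Oak-Hickory",
                                          oh2 = "Oak-Hickory",
                                          sf = "Spruce-Fir"))
  expect_equal(sum(comp2$area_ha), 3 * 0.09)
  expect_error(zone_composition(raw, matrix(1L, 2, 2),
                                group_map = c(oh1 = "Oak-Hickory")), "oh2")
})

test_that("zone scaling combines fit, composition and edge fraction", {
  # a fit with known means: interior 1.0, edge 1.2, no covariates
  d <- tibble::tibble(
    y = rep(c(1.0, 1.2), each = 40) + rep(c(-1e-9, 1e-9), 40),
    edge = factor(rep(c("interior", "edge"), each = 40),
                  levels = c("interior", "edge")),
    forest_type_group = factor(rep(c("Oak-Hickory", "Spruce-Fir"), 40)))
  fit <- fit_edge_glm(d, response = "y", rhs = ~ edge)
  comp <- tibble::tibble(zone = c(1L, 1L, 2L),
                         forest_type_group = c("Oak-Hickory", "Spruce-Fir",
                                               "Oak-Hickory"),
                         area_ha = c(3, 1, 2))
  covm <- tibble::tibble(zone = 1:2)
  ef <- tibble::tibble(zone = 1:2, edge_fraction = c(0.5, 0))
  out <- scale_zone_bai(fit, comp, covm, ef)
  expect_equal(out$bai_interior, c(1, 1), tolerance = 1e-6)
  expect_equal(out$bai_edge, c(1.2, 1.2), tolerance = 1e-6)
  # f = 0.5, 20% edge uplift -> 10% zone increase; f = 0 -> 0
  expect_equal(out$pct_increase, c(10, 0), tolerance = 1e-5)
  # alternative denominator: delta as share of the realized total
  alt <- scale_zone_bai(fit, comp, covm, ef, denominator = "realized")
  expect_equal(alt$pct_increase[1], 100 * 0.5 * 0.2 / 1.1, tolerance = 1e-5)
})

test_that("types absent from the fit are dropped with renormalized weights", {
  set.seed(14)
  d <- tibble::tibble(
    y = c(stats::rgamma(80, 20, 20), stats::rgamma(80, 20, 16)),
    edge = factor(rep(c("interior", "edge"), each = 80),
                  levels = c("interior", "edge")),
    forest_type_group = factor(rep(c("Oak-Hickory", "Spruce-Fir"), 80)))
  fit <- fit_edge_glm(d, response = "y",
                      rhs = ~ edge + forest_type_group)
  comp <- tibble::tibble(zone = 1L,
                         forest_type_group = c("Oak-Hickory", "Palmland"),
                         area_ha = c(1, 5))
  covm <- tibble::tibble(zone = 1L)
  ef <- tibble::tibble(zone = 1L, edge_fraction = 0.2)
  expect_warning(out <- scale_zone_bai(fit, comp, covm, ef), "Palmland")
  expect_equal(nrow(out), 1)
  expect_true(is.finite(out$pct_increase))
})

test_that("two types with 3:1 areas give the hand-computed weighted means", {
  set.seed(9)
  d <- simulate_glm_data(1500, edge_pct = 30, n_types = 2)
  fit <- fit_edge_glm(d, response = "y",
                      rhs = ~ edge + forest_type_group + light_limit +
                        water_limit + temp_limit + n_dep)
  types <- levels(factor(d$forest_type_group))
  comp <- tibble::tibble(zone = 1L, forest_type_group = types,
                         area_ha = c(3, 1))
  covm <- tibble::tibble(zone = 1L, light_limit = 0.5, water_limit = 0.5,
                         temp_limit = 0.5, n_dep = 6)
  ef <- tibble::tibble(zone = 1L, edge_fraction = 0.3)
  out <- scale_zone_bai(fit, comp, covm, ef)
  # hand-compute from the coefficient vector
  beta <- fit$coefficients
  nd <- expand.grid(edge = c("interior", "edge"), forest_type_group = types)
  nd <- dplyr::bind_cols(nd, covm[rep(1, 4), -1])
  nd$edge <- factor(nd$edge, levels = c("interior", "edge"))
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit$fit)),
                           nd, xlev = fit$fit$xlevels)
  mu <- 1 / drop(X %*% beta)
  w <- c(0.75, 0.25)
  expect_equal(out$bai_interior,
               sum(w * mu[nd$edge == "interior"]), tolerance = 1e-8)
  expect_equal(out$bai_edge, sum(w * mu[nd$edge == "edge"]),
               tolerance = 1e-8)
})
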