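test_that("queen's-rule anthropogenic edge detection matches hand cases", {
  # 1x3 row: forest, developed, forest -> both forest pixels are edge
  row <- matrix(c("forest", "developed", "forest"), nrow = 1)
  e <- detect_anthropogenic_edges(row)
  expect_equal(as.vector(e), c(TRUE, FALSE, TRUE))

  all_forest <- matrix("forest", 6, 6)
  expect_equal(sum(detect_anthropogenic_edges(all_forest)), 0)

  # water adjacency is not anthropogenic
  m <- matrix("forest", 3, 3); m[2, 2] <- "water"
  expect_equal(sum(detect_anthropogenic_edges(m)), 0)
  m[2, 2] <- "cultivated"
  expect_equal(sum(detect_anthropogenic_edges(m)), 8)

  expect_error(detect_anthropogenic_edges(matrix("swamp", 2, 2)), "swamp")
})

test_that("any-edge detection: checkerboard and interior block hand counts", {
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2 == 0)
  e <- detect_any_edges(cb)
  expect_true(all(e[cb]))           # every forest pixel is edge

  sea <- matrix(FALSE, 9, 9)
  sea[3:7, 3:7] <- TRUE             # solid 5x5 block
  e2 <- detect_any_edges(sea)
  expect_equal(sum(e2), 16)         # perimeter
  expect_equal(sum(sea & !e2), 9)   # 3x3 interior

  # grid border does not create edge
  expect_equal(sum(detect_any_edges(matrix(TRUE, 4, 4))), 0)
})

test_that("edge masks equal the brute-force double loop on random rasters", {
  set.seed(99)
  for (i in 1:5) {
    m <- matrix(sample(c("forest", "developed", "cultivated", "water",
                         "other"), 50 * 50, replace = TRUE,
                       prob = c(0.5, 0.15, 0.15, 0.1, 0.1)), 50, 50)
    forest <- m == "forest"
    anthro <- matrix(m %in% c("developed", "cultivated"), 50, 50)
    expect_identical(detect_anthropogenic_edges(m),
                     brute_force_edges(forest, anthro))
    expect_identical(detect_any_edges(forest), brute_force_edges(forest))
  }
})

test_that("canopy threshold is inclusive and monotone", {
  expect_true(forest_mask(matrix(10), tau = 10)[1, 1])
  expect_false(forest_mask(matrix(9.9), tau = 10)[1, 1])
  set.seed(4)
  canopy <- matrix(stats::runif(400, 0, 100), 20)
  a10 <- sum(forest_mask(canopy, 10))
  a30 <- sum(forest_mask(canopy, 30))
  expect_lte(a30, a10)
  expect_error(forest_mask(matrix(120)), "0, 100")
})

test_that("gap filling takes the nearest valid cell, ties row-major", {
  m <- matrix(0.5, 5, 5)
  expect_identical(fill_covariate_gaps(m), m)   # no gaps: identity
  m[3, 3] <- NA
  expect_equal(fill_covariate_gaps(m)[3, 3], 0.5)

  # tie between (1,2) [row-major 2] and (2,1) [row-major 4]: first wins
  tie <- matrix(NA_real_, 2, 2)
  tie[1, 2] <- 7; tie[2, 1] <- 9
  expect_equal(fill_covariate_gaps(tie)[1, 1], 7)

  set.seed(12)
  r <- matrix(stats::runif(100), 10)
  r[sample(100, 20)] <- NA
  filled <- fill_covariate_gaps(r)
  expect_false(anyNA(filled))
  # brute-force oracle for every gap
  valid <- which(!is.na(r), arr.ind = TRUE)
  for (idx in which(is.na(r))) {
    rr <- (idx - 1) %% 10 + 1; cc <- (idx - 1) %/% 10 + 1
    d2 <- (valid[, 1] - rr)^2 + (valid[, 2] - cc)^2
    best <- which(d2 == min(d2))
    vals <- r[valid[best, , drop = FALSE]]
    expect_true(filled[rr, cc] %in% vals)
  }
})

test_that("generated landscapes are deterministic, bounded and consistent", {
  cfg <- small_scenario(n_plots = 10)
  ls1 <- generate_landscape(cfg, nrow = 40, ncol = 40)
  ls2 <- generate_landscape(cfg, nrow = 40, ncol = 40)
  expect_identical(ls1$land_cover, ls2$land_cover)
  expect_identical(ls1$canopy, ls2$canopy)
  for (v in c("light_limit", "water_limit", "temp_limit")) {
    expect_true(all(ls1$covariates[[v]] >= 0 & ls1$covariates[[v]] <= 1))
  }
  # canopy consistent with land cover under the default threshold
  expect_true(all(ls1$canopy[ls1$land_cover == "forest"] >= 10))
  expect_true(all(ls1$canopy[ls1$land_cover != "forest"] < 10))
  expect_true(all(is.na(ls1$forest_type[ls1$land_cover != "forest"])))
  expect_error(generate_landscape(cfg, nrow = 2, ncol = 5), "3 x 3")
})

test_that("50% developed checkerboard makes every forest pixel an edge", {
  n <- 8
  lc <- matrix(ifelse(outer(1:n, 1:n, "+") %% 2 == 0, "forest",
                      "developed"), n, n)
  e <- detect_anthropogenic_edges(lc)
  expect_true(all(e[lc == "forest"]))
  # exhaustive neighborhood check
  expect_identical(e, brute_force_edges(lc == "forest", lc == "developed"))
})
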