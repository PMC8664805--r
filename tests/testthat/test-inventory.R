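make_subplots <- function(plot_id = 1L, n = 4L) {
  tibble::tibble(subplot_id = plot_id * 10L + seq_len(n), plot_id = plot_id,
                 is_central = seq_len(n) == 1L, area_m2 = 168.7)
}

cond_row <- function(id, cycle, class, prop) {
  tibble::tibble(subplot_id = id, cycle = cycle, class = class,
                 proportion = prop)
}

fully_forested <- function(ids) {
  dplyr::bind_rows(cond_row(ids, 1L, "forest", 1),
                   cond_row(ids, 2L, "forest", 1))
}

test_that("fully forested subplots on fully forested plots are interior", {
  sp <- make_subplots()
  cls <- classify_subplots(fully_forested(sp$subplot_id), sp)
  expect_true(all(cls$edge_class == "interior"))
  expect_equal(cls$forested_area_m2, rep(168.7, 4))
})

test_that("forest plus developed condition is an anthropogenic edge", {
  sp <- make_subplots()
  conds <- dplyr::bind_rows(
    fully_forested(sp$subplot_id[-1]),
    cond_row(11L, 1L, "forest", 0.6), cond_row(11L, 1L, "developed", 0.4),
    cond_row(11L, 2L, "forest", 0.6), cond_row(11L, 2L, "developed", 0.4))
  cls <- classify_subplots(conds, sp)
  expect_equal(cls$edge_class[cls$subplot_id == 11], "edge_anthropogenic")
  expect_equal(cls$forested_area_m2[cls$subplot_id == 11], 0.6 * 168.7)
  # siblings are edge-proximate, not interior
  expect_true(all(cls$edge_class[cls$subplot_id != 11] == "edge_proximate"))
})

test_that("unknown-cover edges, condition loss and missing forest are handled", {
  sp <- make_subplots()
  conds <- dplyr::bind_rows(
    cond_row(11L, 1L, "forest", 0.7), cond_row(11L, 1L, "wetland", 0.3),
    cond_row(11L, 2L, "forest", 0.7), cond_row(11L, 2L, "wetland", 0.3),
    cond_row(12L, 1L, "forest", 0.5), cond_row(12L, 1L, "developed", 0.5),
    cond_row(12L, 2L, "developed", 1),          # forest lost by cycle 2
    cond_row(13L, 1L, "water", 1),              # no forest in cycle 1
    cond_row(13L, 2L, "forest", 1),
    fully_forested(14L))
  cls <- classify_subplots(conds, sp)
  lut <- setNames(cls$edge_class, cls$subplot_id)
  expect_equal(unname(lut["11"]), "edge_unknown")
  expect_equal(unname(lut["12"]), "excluded_forest_loss")
  expect_equal(unname(lut["13"]), "excluded_no_forest")
  expect_equal(unname(lut["14"]), "edge_proximate")
})

test_that("overlapping proportions and unknown codes raise errors", {
  sp <- make_subplots(n = 1L)
  bad <- dplyr::bind_rows(cond_row(11L, 1L, "forest", 0.8),
                          cond_row(11L, 1L, "developed", 0.4),
                          cond_row(11L, 2L, "forest", 1))
  expect_error(classify_subplots(bad, sp), "100%")
  odd <- dplyr::bind_rows(cond_row(11L, 1L, "forest", 0.5),
                          cond_row(11L, 1L, "lava", 0.5),
                          cond_row(11L, 2L, "forest", 0.5),
                          cond_row(11L, 2L, "lava", 0.5))
  expect_error(classify_subplots(odd, sp), "lava")
  cls <- classify_subplots(odd, sp, on_unknown_code = "unknown")
  expect_equal(cls$edge_class, "edge_unknown")
  missing <- cond_row(11L, 1L, "forest", 1)
  expect_error(classify_subplots(missing, sp), "missing a condition")
})

test_that("classification is independent of condition row order", {
  inv <- local_inventory()
  shuffled <- inv$conditions[sample(nrow(inv$conditions)), ]
  a <- classify_subplots(inv$conditions, inv$subplots)
  b <- classify_subplots(shuffled, inv$subplots)
  expect_equal(a, b[match(a$subplot_id, b$subplot_id), ])
})

tree <- function(dbh1, dbh2, status = "live", yrs = 5L) {
  tibble::tibble(dbh_t1_cm = dbh1, dbh_t2_cm = dbh2, status_t2 = status,
                 years_between = yrs)
}

test_that("basal area follows the stem formula with the inclusive threshold", {
  expect_equal(compute_ba(tree(numeric(0), numeric(0)), 168.7), 0)
  # one stem exactly at the 12.7 cm threshold on a full subplot
  expect_equal(compute_ba(tree(NA, 12.7), 168.7),
               pi * (0.127 / 2)^2 / (168.7 / 1e4))
  expect_equal(round(compute_ba(tree(NA, 12.7), 168.7), 4), 0.7509)
  # below threshold contributes nothing; dead stems excluded
  expect_equal(compute_ba(tree(NA, 12.0), 168.7), 0)
  expect_equal(compute_ba(tree(30, 30, status = "dead_biogenic"), 168.7), 0)
  expect_error(compute_ba(tree(NA, 20), 0), "> 0")
})

test_that("basal area increment annualizes per-tree growth", {
  area_ha <- 168.7 / 1e4
  expect_equal(compute_bai(tree(20, 20), 168.7), 0)
  expect_equal(compute_bai(tree(20, 25), 168.7),
               (pi * 0.125^2 - pi * 0.100^2) / 5 / area_ha)
  # the per-tree increment before area normalization is ~0.003534 m2/yr
  expect_equal((pi * 0.125^2 - pi * 0.100^2) / 5, 0.0035343, tolerance = 1e-4)
  # ingrowth without recorded prior is measured from the threshold
  expect_equal(compute_bai(tree(NA_real_, 15), 168.7),
               (pi * 0.075^2 - pi * (0.127 / 2)^2) / 5 / area_ha)
  # negative increments are retained
  expect_lt(compute_bai(tree(30, 25), 168.7), 0)
})

test_that("density and diameter summaries follow counts and means", {
  t3 <- tree(c(18, 19, 20), c(20, 20, 20))
  dd <- compute_density_diameter(t3, 168.7)
  expect_equal(dd$stems_ha, 3 / (168.7 / 1e4))
  expect_equal(round(dd$stems_ha, 1), 177.8)
  expect_equal(dd$mean_dbh_cm, 20)
  empty <- compute_density_diameter(tree(numeric(0), numeric(0)), 168.7)
  expect_equal(empty$stems_ha, 0)
  expect_true(is.na(empty$mean_dbh_cm))
})

test_that("per-hectare normalization scales inversely with forested area", {
  tl <- tree(c(15, 20), c(18, 26))
  expect_equal(compute_ba(tl, 80), 2 * compute_ba(tl, 160))
  expect_equal(compute_bai(tl, 80), 2 * compute_bai(tl, 160))
})
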