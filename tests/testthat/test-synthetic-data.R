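test_that("every plot has exactly four subplots and valid condition rows", {
  inv <- local_inventory()
  counts <- table(inv$subplots$plot_id)
  expect_true(all(counts == 4))
  tot <- dplyr::count(inv$conditions, subplot_id, cycle,
                      wt = proportion, name = "total")
  expect_true(all(abs(tot$total - 1) < 1e-8))
  expect_true(all(inv$trees$dbh_t2_cm > 0, na.rm = TRUE))
})

test_that("identical seed and config give byte-identical tables", {
  cfg <- small_scenario(seed = 42, n_plots = 60)
  a <- generate_inventory(cfg)
  b <- generate_inventory(cfg)
  expect_identical(a$trees, b$trees)
  expect_identical(a$conditions, b$conditions)
  expect_identical(a$plots, b$plots)
})

test_that("adding plots does not perturb existing plot-level draws", {
  a <- generate_inventory(small_scenario(seed = 9, n_plots = 50))
  b <- generate_inventory(small_scenario(seed = 9, n_plots = 80))
  expect_identical(a$plots, b$plots[seq_len(50), ])
})

test_that("inventory responses reproduce the generator's clean truth exactly", {
  inv <- local_inventory()
  raw <- build_analysis_data(inv)
  joined <- dplyr::inner_join(raw, inv$truth,
                              by = c("subplot_id", "plot_id"))
  clean <- joined[!joined$bai_error & !joined$ba_error, ]
  expect_gt(nrow(clean), 500)
  expect_equal(clean$ba_m2_ha, clean$ba_true, tolerance = 1e-10)
  expect_equal(clean$bai_m2_ha_yr, clean$bai_true, tolerance = 1e-10)
  expect_equal(clean$stems_ha, clean$stems_true, tolerance = 1e-10)
})

test_that("null-effect scenario yields edge/interior mean ratios near one", {
  cov <- edgegrowth:::default_covariates()
  cov$mean_edge <- cov$mean_interior  # no confounding under the null
  cfg <- edge_scenario(n_plots = 1500, seed = 31,
                       bai_pct_anthro = 0, bai_pct_all = 0,
                       ba_pct_anthro = 0, ba_pct_all = 0,
                       density_anthro = 0, density_all = 0,
                       covariates = cov)
  inv <- generate_inventory(cfg)
  tr <- inv$truth[inv$truth$gen_class != "none", ]
  m_edge <- mean(tr$bai_true[tr$gen_class != "interior"])
  m_int <- mean(tr$bai_true[tr$gen_class == "interior"])
  se <- sqrt(stats::var(tr$bai_true) *
               (1 / sum(tr$gen_class != "interior") +
                  1 / sum(tr$gen_class == "interior")))
  expect_lt(abs(m_edge - m_int), 3 * se)
})

test_that("empirical BAI gamma shape is within 15% of the configured dispersion", {
  inv <- generate_inventory(small_scenario(seed = 77, n_plots = 600))
  tr <- inv$truth[inv$truth$gen_class != "none", ]
  expect_gt(nrow(tr), 2000)
  # standardized residual u = y * eta ~ Gamma(shape, rate = shape)
  u <- tr$bai_true * tr$eta_bai
  shape_hat <- 1 / stats::var(u)      # mean 1, var 1/shape
  expect_lt(abs(shape_hat - 25) / 25, 0.15)
})

test_that("generated effect-size structure matches the configured truths", {
  inv <- generate_inventory(edge_scenario(n_plots = 4000, seed = 13))
  tr <- inv$truth[inv$truth$gen_class != "none", ]
  # mean ratios at fixed covariates: standardize by the interior-scale eta
  # (removes covariate and type structure, keeps the class multiplier)
  # eta already includes the class effect, so y*eta is mean-1 noise in
  # every class; the multiplier is recovered from eta itself
  mult_bai <- mean(1 / tr$eta_bai[tr$gen_class == "anthropogenic"]) /
    mean(1 / tr$eta_bai[tr$gen_class == "interior"])
  expect_gt(mult_bai, 1.2)  # effect present with confounding on top
  # density contrast (unconfounded) within 3 Monte-Carlo SEs of truth
  d <- tr$stems_true[tr$gen_class == "anthropogenic"]
  i <- tr$stems_true[tr$gen_class == "interior"]
  se <- sqrt(stats::var(d) / length(d) + stats::var(i) / length(i))
  expect_lt(abs((mean(d) - mean(i)) - 82.6), 3 * se)
})

test_that("ingrowth stems are generated and exercised both ways", {
  inv <- local_inventory()
  tr <- inv$trees
  ingrowth <- tr[tr$ingrowth & tr$status_t2 == "live", ]
  expect_gt(nrow(ingrowth), 10)
  expect_gt(sum(is.na(ingrowth$dbh_t1_cm)), 0)       # missing-prior branch
  expect_gt(sum(!is.na(ingrowth$dbh_t1_cm)), 0)      # recorded-prior branch
  rec <- ingrowth[!is.na(ingrowth$dbh_t1_cm), ]
  err_sub <- inv$truth$subplot_id[inv$truth$bai_error | inv$truth$ba_error]
  rec_clean <- rec[!rec$subplot_id %in% err_sub, ]
  expect_true(all(rec_clean$dbh_t1_cm < 12.7))
})

test_that("an infeasible configuration fails with a named parameter", {
  expect_error(edge_scenario(stem_density_base = -5), "stem_density_base")
  expect_error(
    generate_inventory(edge_scenario(n_plots = 10,
                                     stem_density_base = 2500)),
    "threshold|stem_density_base")
})
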