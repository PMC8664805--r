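test_that("mahalanobis distance matches hand calculations", {
  S2 <- diag(2)
  expect_equal(mahalanobis_dist(c(1, 2), c(1, 2), S2), 0)
  expect_equal(mahalanobis_dist(c(3, 4), c(0, 0), S2), 5)
  expect_equal(mahalanobis_dist(c(2, 1), c(0, 0), diag(c(4, 1))), sqrt(2))
  expect_error(mahalanobis_dist(c(1, 2, 3), c(1, 2), S2), "dimension")
  # singular covariance falls back to the Moore-Penrose pseudo-inverse
  S_sing <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(mahalanobis_dist(c(1, 1), c(0, 0), S_sing), 1,
               tolerance = 1e-8)
})

match_fixture <- function(treated_cov, control_cov, types = NULL) {
  nt <- nrow(treated_cov); nc <- nrow(control_cov)
  tibble::tibble(
    subplot_id = seq_len(nt + nc),
    plot_id = seq_len(nt + nc),
    edge_class = rep(c("edge_anthropogenic", "interior"), c(nt, nc)),
    forest_type_group = types %||% "Oak-Hickory",
    light_limit = c(treated_cov[, 1], control_cov[, 1]),
    water_limit = c(treated_cov[, 2], control_cov[, 2]),
    temp_limit = c(treated_cov[, 3], control_cov[, 3]),
    n_dep = c(treated_cov[, 4], control_cov[, 4])
  )
}

test_that("an identical control is matched and ties go to the lowest id", {
  tr <- matrix(c(0.5, 0.5, 0.5, 5), 1)
  ct <- rbind(c(0.5, 0.5, 0.5, 5), c(0.9, 0.9, 0.9, 9))
  m <- match_subplots(match_fixture(tr, ct),
                      treat_classes = "edge_anthropogenic")
  expect_equal(m$pairs$control_id, 2L)   # the identical control
  # two equidistant controls: lowest id wins
  ct2 <- rbind(c(0.6, 0.5, 0.5, 5), c(0.6, 0.5, 0.5, 5))
  m2 <- match_subplots(match_fixture(tr, ct2),
                       treat_classes = "edge_anthropogenic")
  expect_equal(m2$pairs$control_id, 2L)
})

test_that("matching is 1:1 without replacement and reports balance", {
  set.seed(3)
  tr <- matrix(stats::runif(10 * 4), 10)
  ct <- matrix(stats::runif(25 * 4), 25)
  m <- match_subplots(match_fixture(tr, ct),
                      treat_classes = "edge_anthropogenic")
  expect_equal(nrow(m$pairs), 10)
  expect_equal(anyDuplicated(m$pairs$control_id), 0L)
  expect_equal(nrow(m$balance), 4)
  expect_true(all(c("smd_pre", "smd_post") %in% names(m$balance)))
  md <- matched_data(m)
  expect_equal(nrow(md), 20)
  expect_equal(levels(md$edge), c("interior", "edge"))
})

test_that("insufficient controls in a stratum fail naming the stratum", {
  tr <- matrix(stats::runif(3 * 4), 3)
  ct <- matrix(stats::runif(2 * 4), 2)
  d <- match_fixture(tr, ct, types = "Spruce-Fir")
  expect_error(match_subplots(d, treat_classes = "edge_anthropogenic"),
               "Spruce-Fir")
})

test_that("greedy matching equals the sequential nearest-neighbor oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    nt <- sample(5:40, 1); nc <- nt + sample(5:40, 1)
    tr <- matrix(stats::rnorm(nt * 4), nt)
    ct <- matrix(stats::rnorm(nc * 4), nc)
    d <- match_fixture(tr, ct)
    m <- match_subplots(d, treat_classes = "edge_anthropogenic")
    S <- stats::cov(rbind(tr, ct))
    oracle <- oracle_match(tr, ct, ids_c = nt + seq_len(nc), S = S)
    expect_equal(m$pairs$control_id, nt + oracle)
  }
})

test_that("three units on a line: greedy equals exhaustive assignment", {
  tr <- cbind(c(0, 1, 2), 0, 0, 0)
  ct <- cbind(c(0.1, 1.1, 2.1), 0, 0, 0)
  d <- match_fixture(tr, ct)
  m <- match_subplots(d, treat_classes = "edge_anthropogenic")
  S <- stats::cov(rbind(tr, ct))
  Si <- MASS::ginv(S)
  dist2 <- function(a, b) drop(t(a - b) %*% Si %*% (a - b))
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  costs <- vapply(perms, function(p)
    sum(vapply(1:3, function(i) dist2(tr[i, ], ct[p[i], ]), 0)), 0)
  best <- perms[[which.min(costs)]]
  expect_equal(m$pairs$control_id, 3 + best)
})

test_that("matching is invariant to affine rescaling of one covariate", {
  set.seed(11)
  tr <- matrix(stats::runif(15 * 4), 15)
  ct <- matrix(stats::runif(40 * 4), 40)
  d1 <- match_fixture(tr, ct)
  d2 <- d1
  d2$n_dep <- d2$n_dep * 37 + 5
  m1 <- match_subplots(d1, treat_classes = "edge_anthropogenic")
  m2 <- match_subplots(d2, treat_classes = "edge_anthropogenic")
  expect_equal(m1$pairs$control_id, m2$pairs$control_id)
})

test_that("balance SMDs follow their definition and improve on matchable data", {
  set.seed(23)
  d <- tibble::tibble(
    subplot_id = 1:60, plot_id = 1:60,
    edge_class = rep(c("edge_anthropogenic", "interior"), c(20, 40)),
    forest_type_group = "Oak-Hickory",
    light_limit = stats::rnorm(60, rep(c(0.6, 0.4), c(20, 40)), 0.1),
    water_limit = 0.5, temp_limit = stats::runif(60), n_dep = 5)
  m <- match_subplots(d, treat_classes = "edge_anthropogenic")
  b <- m$balance
  treated <- d$edge_class != "interior"
  smd_ref <- (mean(d$light_limit[treated]) - mean(d$light_limit[!treated])) /
    sqrt((stats::var(d$light_limit[treated]) +
            stats::var(d$light_limit[!treated])) / 2)
  expect_equal(b$smd_pre[b$covariate == "light_limit"], smd_ref)
  # zero-variance covariate with equal means reports SMD 0
  expect_equal(b$smd_pre[b$covariate == "water_limit"], 0)

  # overlapping synthetic data: post-match SMD no worse than pre-match
  filtered <- local_filtered()
  mm <- match_subplots(filtered, treat_classes = "edge_anthropogenic")
  expect_true(all(abs(mm$balance$smd_post) <= abs(mm$balance$smd_pre) + 0.02))
})

test_that("separate matching runs share no state", {
  filtered <- local_filtered()
  m_all_1 <- match_subplots(filtered)
  m_anthro <- match_subplots(filtered, treat_classes = "edge_anthropogenic")
  m_all_2 <- match_subplots(filtered)
  expect_identical(m_all_1$pairs, m_all_2$pairs)
  expect_gt(nrow(m_all_1$pairs), nrow(m_anthro$pairs))
})
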