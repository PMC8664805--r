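#' Stem density and mean diameter contrasts between edge classes
#'
#' Welch two-sided t-tests of per-subplot stem density (stems ha^-1) and
#' mean tree diameter (cm) between interior forest, all edges pooled, and
#' the anthropogenic edge subset, with a Bonferroni adjustment (raw p
#' multiplied by the number of comparisons per response, capped at 1).
#'
#' @param data Analysis dataset with `edge_class`, `stems_ha`,
#'   `mean_dbh_cm`.
#' @return A tibble with one row per variable x group pair: group means,
#'   difference, Welch statistic, raw and adjusted p.
#' @export
density_diameter_tests <- function(data) {
  assert_columns(data, c("edge_class", "stems_ha", "mean_dbh_cm"))
  groups <- list(
    interior = data$edge_class == "interior",
    all_edges = data$edge_class != "interior",
    anthropogenic = data$edge_class == "edge_anthropogenic"
  )
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  vars <- c("stems_ha", "mean_dbh_cm")
  out <- purrr::map_dfr(vars, function(v) {
    purrr::map_dfr(pairs, function(p) {
      x <- data[[v]][groups[[p[1]]]]
      y <- data[[v]][groups[[p[2]]]]
      x <- x[is.finite(x)]
      y <- y[is.finite(y)]
      tt <- tryCatch(stats::t.test(y, x, alternative = "two.sided"),
                     error = function(e) NULL)  # essentially constant data
      tibble::tibble(variable = v, group1 = p[1], group2 = p[2],
                     mean1 = mean(x), mean2 = mean(y),
                     difference = mean(y) - mean(x),
                     statistic = if (is.null(tt)) NA_real_ else
                       unname(tt$statistic),
                     df = if (is.null(tt)) NA_real_ else
                       unname(tt$parameter),
                     p_value = if (is.null(tt)) {
                       if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
                     } else tt$p.value)
    }) |>
      dplyr::mutate(p_adjusted = pmin(.data$p_value * length(pairs), 1))
  })
  out
}

#' Empirical semivariogram of model residuals
#'
#' Spatial diagnostic for residual autocorrelation:
#' `gamma(h) = mean((r_i - r_j)^2) / 2` over point pairs whose separation
#' falls in each distance bin. Flat semivariance indicates spatially
#' independent residuals.
#'
#' @param fit An `edge_glm`, or a numeric vector of residuals.
#' @param coords Two-column matrix or data frame of coordinates (same
#'   length as the residuals).
#' @param breaks Distance bin edges.
#' @param max_pairs Optional cap on points used (random subsample, seeded)
#'   to bound memory on large datasets.
#' @param seed Seed for the subsample when `max_pairs` binds.
#' @return A tibble with `dist_low`, `dist_high`, `dist_mid`, `gamma`,
#'   `n_pairs`.
#' @export
residual_semivariogram <- function(fit, coords, breaks, max_pairs = 3000,
                                   seed = 1L) {
  r <- if (inherits(fit, "edge_glm")) {
    stats::residuals(fit$fit, type = "deviance")
  } else {
    as.numeric(fit)
  }
  coords <- as.matrix(coords)
  if (nrow(coords) != length(r)) {
    stop_ef("coords must have one row per residual")
  }
  if (length(r) > max_pairs) {
    set.seed(seed)
    i <- sample(length(r), max_pairs)
    r <- r[i]
    coords <- coords[i, , drop = FALSE]
  }
  dmat <- as.matrix(stats::dist(coords))
  sq <- outer(r, r, "-")^2
  keep <- upper.tri(dmat)
  d <- dmat[keep]
  s <- sq[keep]
  bin <- cut(d, breaks = breaks, include.lowest = TRUE)
  tibble::tibble(
    dist_low = utils::head(breaks, -1),
    dist_high = breaks[-1],
    dist_mid = (utils::head(breaks, -1) + breaks[-1]) / 2,
    gamma = as.numeric(tapply(s, bin, mean)) / 2,
    n_pairs = as.integer(tapply(s, bin, length))
  ) |>
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L))
}

#' Simulate subplot-level gamma responses from a known model
#'
#' Direct response-level simulator for statistical calibration studies
#' (Wald type-I error, confidence-interval coverage): covariates and forest
#' types are drawn, the linear predictor `eta` is formed with per-type
#' intercepts, an edge offset implying the requested percent effect, and
#' covariate slopes, and the response is drawn from
#' `Gamma(shape, mean = 1/eta)`. Unlike [generate_inventory()] there is no
#' tree-level structure, filtering or matching: the model is exactly
#' correctly specified.
#'
#' @param n Number of records.
#' @param edge_pct True marginal percent difference of edge vs interior.
#' @param edge_prob Proportion of edge records.
#' @param n_types Number of forest type groups.
#' @param shape Gamma shape.
#' @param base_mean Interior mean response for the first type (others are
#'   scaled steps).
#' @param slopes Named covariate slopes on the `eta` scale.
#' @return A tibble with `y`, `edge` (factor), `forest_type_group`, and
#'   the four abiotic covariates; the true `eta` is kept in the `"eta"`
#'   attribute.
#' @export
simulate_glm_data <- function(n, edge_pct = 0, edge_prob = 0.4, n_types = 4,
                              shape = 25, base_mean = 0.5,
                              slopes = c(light_limit = 0.5,
                                         water_limit = 0.4,
                                         temp_limit = 0.45,
                                         n_dep = -0.035)) {
  types <- forest_type_groups()[seq_len(n_types)]
  edge <- factor(ifelse(stats::runif(n) < edge_prob, "edge", "interior"),
                 levels = c("interior", "edge"))
  ftg <- sample(types, n, replace = TRUE)
  X <- tibble::tibble(
    light_limit = stats::runif(n, 0.1, 0.9),
    water_limit = stats::runif(n, 0.1, 0.9),
    temp_limit = stats::runif(n, 0.1, 0.9),
    n_dep = stats::runif(n, 1, 11)
  )
  mult <- 1 + edge_pct / 100
  base <- base_mean * (1 + 0.25 * (match(ftg, types) - 1))
  xbar <- c(light_limit = 0.5, water_limit = 0.5, temp_limit = 0.5,
            n_dep = 6)
  shift <- sum(slopes * xbar[names(slopes)])
  a <- 1 / base - shift
  eta0 <- a + drop(as.matrix(X[, names(slopes)]) %*% slopes)
  d <- (1 / base) * (1 / mult - 1)
  eta <- eta0 + ifelse(edge == "edge", d, 0)
  if (any(eta <= 0)) stop_ef("simulated linear predictor non-positive; ",
                             "reduce slopes or effect size")
  y <- stats::rgamma(n, shape = shape, rate = shape * eta)
  out <- dplyr::bind_cols(tibble::tibble(y = y, edge = edge,
                                         forest_type_group = ftg), X)
  attr(out, "eta") <- eta
  out
}
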