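#' Marginal edge effects at within-type covariate means
#'
#' Model-predicted mean response for every edge level within every forest
#' type group, with the continuous covariates held at their within-type
#' means over the supplied dataset. Confidence intervals come from the
#' delta method on the linear-predictor scale, transformed through the
#' inverse link (monotone on the admissible region). Percent differences vs
#' the interior level are computed per type and, weighted by type
#' frequency, overall; their significance comes from Wald tests on the
#' corresponding coefficient contrasts.
#'
#' @param fit An `edge_glm`.
#' @param data Dataset defining the covariate means and type weights;
#'   defaults to the fitting data (the matched dataset).
#' @param level Confidence level.
#' @return An object of class `edge_effects`: a tibble with one row per
#'   edge level x forest type (columns `edge`, `forest_type_group`, `mean`,
#'   `ci_low`, `ci_high`, `pct_diff`, `pct_low`, `pct_high`, `p_wald`),
#'   with attributes `overall` (pooled percent difference with CI and Wald
#'   p), `covariate_settings`, and `level`. See [overall_effect()].
#' @export
marginal_effects <- function(fit, data = fit$data, level = 0.95) {
  stopifnot(inherits(fit, "edge_glm"))
  data <- ensure_edge_factor(data)
  z <- stats::qnorm(1 - (1 - level) / 2)
  beta <- fit$coefficients
  V <- fit$vcov

  covs <- intersect(c("light_limit", "water_limit", "temp_limit", "n_dep"),
                    names(data))
  has_type <- "forest_type_group" %in% all.vars(fit$formula)
  if (has_type) {
    groups <- fit$fit$xlevels[["forest_type_group"]] %||%
      sort(unique(data$forest_type_group))
  } else {
    groups <- "all"
  }
  edge_levels <- fit$fit$xlevels[["edge"]] %||% levels(data$edge) %||%
    c("interior", "edge")

  settings <- purrr::map_dfr(groups, function(g) {
    rows <- if (has_type) data$forest_type_group == g else TRUE
    out <- tibble::tibble(forest_type_group = g,
                          weight = mean(if (has_type) rows else 1))
    for (v in covs) out[[v]] <- mean(data[[v]][rows])
    out
  })

  grid <- tidyr::expand_grid(edge = edge_levels,
                             forest_type_group = groups) |>
    dplyr::left_join(settings, by = "forest_type_group")
  nd <- grid
  nd$edge <- factor(nd$edge, levels = edge_levels)
  if (has_type) {
    nd$forest_type_group <- factor(nd$forest_type_group, levels =
                                     fit$fit$xlevels[["forest_type_group"]])
  }
  Terms <- stats::delete.response(stats::terms(fit$fit))
  X <- stats::model.matrix(Terms, nd, xlev = fit$fit$xlevels)
  eta <- drop(X %*% beta)
  if (any(eta <= 0)) {
    stop_ef("inadmissible evaluation point: linear predictor <= 0 gives a ",
            "non-positive mean under the inverse link")
  }
  se_eta <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  mu <- 1 / eta
  ci_low <- 1 / (eta + z * se_eta)
  hi_den <- eta - z * se_eta
  ci_high <- ifelse(hi_den > 0, 1 / hi_den, Inf)

  res <- grid |>
    dplyr::mutate(mean = mu, ci_low = ci_low, ci_high = ci_high,
                  eta = eta)

  # percent difference vs interior, per type, delta method on eta_i/eta_e
  interior_lv <- edge_levels[1]
  pct <- purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(setdiff(edge_levels, interior_lv), function(lv) {
      i_row <- which(grid$edge == interior_lv & grid$forest_type_group == g)
      e_row <- which(grid$edge == lv & grid$forest_type_group == g)
      xi <- X[i_row, ]; xe <- X[e_row, ]
      r <- eta[i_row] / eta[e_row]
      gr <- xi / eta[e_row] - (eta[i_row] / eta[e_row]^2) * xe
      se <- sqrt(max(drop(t(gr) %*% V %*% gr), 0))
      zstat <- (r - 1) / se
      tibble::tibble(edge = lv, forest_type_group = g,
                     pct_diff = 100 * (r - 1),
                     pct_low = 100 * (r - z * se - 1),
                     pct_high = 100 * (r + z * se - 1),
                     p_wald = 2 * stats::pnorm(-abs(zstat)))
    })
  })
  res <- res |>
    dplyr::left_join(pct, by = c("edge", "forest_type_group"))

  # overall contrast: type-frequency-weighted mean edge vs interior response
  overall <- purrr::map_dfr(setdiff(edge_levels, interior_lv), function(lv) {
    wi <- settings$weight / sum(settings$weight)
    i_rows <- match(paste(interior_lv, groups),
                    paste(grid$edge, grid$forest_type_group))
    e_rows <- match(paste(lv, groups), paste(grid$edge,
                                             grid$forest_type_group))
    num <- sum(wi * mu[e_rows])
    den <- sum(wi * mu[i_rows])
    R <- num / den
    dmu <- -X / eta^2            # d mu / d beta, row-wise
    g_num <- colSums(wi * dmu[e_rows, , drop = FALSE])
    g_den <- colSums(wi * dmu[i_rows, , drop = FALSE])
    gr <- g_num / den - (num / den^2) * g_den
    se <- sqrt(max(drop(t(gr) %*% V %*% gr), 0))
    tibble::tibble(edge = lv,
                   pct_diff = 100 * (R - 1),
                   pct_low = 100 * (R - z * se - 1),
                   pct_high = 100 * (R + z * se - 1),
                   se_pct = 100 * se,
                   p_wald = 2 * stats::pnorm(-abs((R - 1) / se)))
  })

  out <- res |> dplyr::select(-"eta", -"weight")
  attr(out, "overall") <- overall
  attr(out, "covariate_settings") <- settings
  attr(out, "level") <- level
  class(out) <- c("edge_effects", class(out))
  out
}

#' Overall (type-weighted) percent edge effect
#'
#' @param x An `edge_effects` table.
#' @return A one-row tibble per non-interior edge level: `pct_diff`,
#'   `pct_low`, `pct_high`, `se_pct`, `p_wald`.
#' @export
overall_effect <- function(x) {
  ov <- attr(x, "overall")
  if (is.null(ov)) stop_ef("no overall effect attached")
  ov
}

#' @export
print.edge_effects <- function(x, ...) {
  ov <- attr(x, "overall")
  cat("<edge_effects>\n")
  print(tibble::as_tibble(x), n = 6)
  cat("overall percent difference vs interior:\n")
  print(ov)
  invisible(x)
}

#' Plot marginal edge effects
#'
#' Point-range display of the marginal mean response per forest type and
#' edge level, with the delta-method confidence intervals.
#'
#' @param object An `edge_effects` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.edge_effects <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$forest_type_group,
                                   y = .data$mean,
                                   colour = .data$edge)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "marginal mean response",
                  colour = "edge status") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
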