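#' Edge-class mortality analysis with a two-part model
#'
#' Annualized dead basal area per hectare contains many exact zeros
#' (subplots with no mortality in the remeasurement window), so each
#' component (biogenic, harvest, and their total) is modelled in two parts
#' with edge state as the only predictor: a binomial GLM (logit) for the
#' occurrence of any mortality and a gamma GLM (inverse link) for its
#' positive magnitude. The combined class mean is `p * mu`; uncertainty
#' comes from a seeded nonparametric bootstrap over subplots within class.
#'
#' @param data Analysis dataset with `mort_biogenic_m2_ha_yr`,
#'   `mort_harvest_m2_ha_yr` and `edge_class` (or `edge`) columns.
#' @param n_boot Bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return A tibble with one row per component x edge level: occurrence
#'   probability, positive-part mean, combined mean with bootstrap CI, and
#'   the difference vs interior with its bootstrap CI and a `significant`
#'   flag (CI excluding zero). Components with no positive observations in
#'   a class are flagged `degenerate` with mean 0.
#' @export
mortality_analysis <- function(data, n_boot = 1000, level = 0.95,
                               seed = 1L) {
  data <- ensure_edge_factor(data)
  assert_columns(data, c("mort_biogenic_m2_ha_yr", "mort_harvest_m2_ha_yr",
                         "edge"))
  data$mort_total_m2_ha_yr <- data$mort_biogenic_m2_ha_yr +
    data$mort_harvest_m2_ha_yr
  comps <- c(biogenic = "mort_biogenic_m2_ha_yr",
             harvest = "mort_harvest_m2_ha_yr",
             total = "mort_total_m2_ha_yr")
  alpha <- (1 - level) / 2
  set.seed(seed)
  lv <- levels(data$edge)

  purrr::imap_dfr(comps, function(col, comp) {
    y <- data[[col]]
    occ_fit <- suppressWarnings(
      stats::glm((y > 0) ~ edge, data = data, family = stats::binomial()))
    pos <- y > 0
    mag_fit <- if (any(pos)) {
      suppressWarnings(
        stats::glm(y ~ edge, data = data, subset = pos,
                   family = stats::Gamma(link = "inverse")))
    } else NULL
    purrr::map_dfr(lv, function(cl) {
      rows <- data$edge == cl
      nd <- data.frame(edge = factor(cl, levels = lv))
      p_occ <- stats::predict(occ_fit, nd, type = "response")
      degenerate <- !any(pos & rows)
      mu_pos <- if (degenerate || is.null(mag_fit)) 0 else
        stats::predict(mag_fit, nd, type = "response")
      boots <- replicate(n_boot, {
        i <- sample(which(rows), sum(rows), replace = TRUE)
        mean(y[i])
      })
      tibble::tibble(component = comp, edge = cl,
                     p_occurrence = unname(p_occ),
                     mu_positive = unname(mu_pos),
                     mean = mean(y[rows]),
                     ci_low = stats::quantile(boots, alpha, names = FALSE),
                     ci_high = stats::quantile(boots, 1 - alpha,
                                               names = FALSE),
                     degenerate = degenerate,
                     boots = list(boots))
    })
  }) |>
    (\(tab) {
      # difference vs interior per component from the paired bootstrap draws
      tab |>
        dplyr::group_by(.data$component) |>
        dplyr::group_modify(function(g, key) {
          b0 <- g$boots[[which(g$edge == lv[1])]]
          m0 <- g$mean[g$edge == lv[1]]
          g$diff_vs_interior <- g$mean - m0
          g$diff_low <- vapply(g$boots, function(b)
            stats::quantile(b - b0, alpha, names = FALSE), 0)
          g$diff_high <- vapply(g$boots, function(b)
            stats::quantile(b - b0, 1 - alpha, names = FALSE), 0)
          g$significant <- g$edge != lv[1] &
            (g$diff_low > 0 | g$diff_high < 0)
          g$boots <- NULL
          g
        }) |>
        dplyr::ungroup()
    })()
}

#' Robustness of edge effects to timber harvest
#'
#' Re-runs matching, model fitting and marginal effects after withholding
#' every subplot on a plot with any record of anthropogenic removals, and
#' reports the overall percent differences side by side with the full-data
#' analysis.
#'
#' @param data Filtered analysis dataset (pre-matching).
#' @param trees Tree table used to locate plots with harvested stems.
#' @param subplots Optional full subplot table passed to
#'   [plots_with_harvest()].
#' @param treat_classes Edge classes forming the treated group.
#' @param response Response column.
#' @param rhs Model right-hand side (defaults to the full interaction +
#'   covariates model).
#' @return A list with `full` and `withheld` `edge_effects` objects, the
#'   number of withheld subplots, and a `comparison` tibble of overall
#'   percent differences.
#' @export
harvest_robustness <- function(data, trees, subplots = NULL,
                               treat_classes = c("edge_anthropogenic",
                                                 "edge_unknown"),
                               response = "bai_m2_ha_yr",
                               rhs = ~ edge * forest_type_group +
                                 light_limit + water_limit + temp_limit +
                                 n_dep) {
  harvested_plots <- plots_with_harvest(data, trees, subplots)
  subset <- data |> dplyr::filter(!.data$plot_id %in% harvested_plots)
  if (nrow(subset) == 0) {
    stop_ef("withholding harvested plots leaves an empty dataset")
  }
  run <- function(d) {
    m <- match_subplots(d, treat_classes = treat_classes)
    fit <- fit_edge_glm(matched_data(m), response = response, rhs = rhs)
    marginal_effects(fit)
  }
  full <- run(data)
  withheld <- run(subset)
  comparison <- dplyr::bind_rows(
    overall_effect(full) |> dplyr::mutate(dataset = "full", .before = 1),
    overall_effect(withheld) |> dplyr::mutate(dataset = "harvest_withheld",
                                              .before = 1))
  list(full = full, withheld = withheld,
       n_withheld = nrow(data) - nrow(subset), comparison = comparison)
}

#' Plots containing a record of anthropogenic removals
#'
#' A harvested stem anywhere on the plot (any of its subplots) marks the
#' whole plot.
#'
#' @param data Analysis dataset (maps retained subplots to plots).
#' @param trees Tree table with `status_t2`.
#' @param subplots Optional full subplot table (`subplot_id`, `plot_id`)
#'   so removals on non-retained subplots of the same plot also count.
#' @return Vector of plot ids with at least one harvested stem.
#' @export
plots_with_harvest <- function(data, trees, subplots = NULL) {
  harv_sub <- unique(trees$subplot_id[trees$status_t2 == "harvested"])
  map <- dplyr::bind_rows(
    tibble::tibble(subplot_id = data$subplot_id, plot_id = data$plot_id),
    if (!is.null(subplots))
      tibble::tibble(subplot_id = subplots$subplot_id,
                     plot_id = subplots$plot_id)) |>
    dplyr::distinct()
  plot_of <- map$plot_id[match(harv_sub, map$subplot_id)]
  unique(plot_of[!is.na(plot_of)])
}
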