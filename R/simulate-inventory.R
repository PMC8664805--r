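#' Generate a synthetic forest inventory with known ground truth
#'
#' Produces plot, subplot, condition and tree tables with the structure of a
#' national forest inventory (four fixed-area subplots per plot, condition
#' mapping with land-cover classes, two measurement cycles 5-7 years apart,
#' stems measured above a minimum diameter) and with generative edge effects
#' set by the scenario, so every downstream stage of the analysis can be
#' validated against known truth.
#'
#' Subplot responses follow the inverse-link structure `mu = 1/eta` with
#' per-type intercepts, multiplicative per-class edge effects and abiotic
#' covariate terms. Stem counts come from randomized rounding of
#' density x area (so the configured stem-density contrasts are exact);
#' tree diameters are i.i.d. draws from a threshold-shifted gamma whose
#' mean carries the BA structure, making subplot BA gamma-distributed
#' given the count with the configured mean, and leaving mean tree
#' diameter free of any built-in edge effect. Subplot BAI is drawn from a
#' gamma on the inverse-link structure and realized exactly by
#' back-computing prior diameters. Ingrowth stems (prior diameter below
#' the measurement threshold) arise naturally and a configured fraction of
#' them lack a recorded prior diameter. A configured share of subplots
#' receives gross dbh measurement errors (inflating or deflating one
#' response), emulating the field errors that the downstream quantile trim
#' removes.
#'
#' Each table is drawn from its own named random substream, so enlarging
#' `n_plots` extends the tables without perturbing existing rows.
#'
#' @param cfg An [edge_scenario()].
#' @return An object of class `edge_inventory`: a list with tibbles `plots`,
#'   `subplots`, `conditions`, `trees`, a generator bookkeeping table
#'   `truth` (one row per subplot: generated class, clean BA/BAI/stem
#'   density, error flags), and the `config` used.
#' @examples
#' inv <- generate_inventory(edge_scenario(n_plots = 50, seed = 7))
#' nrow(inv$subplots) / nrow(inv$plots)  # always 4 subplots per plot
#' @export
generate_inventory <- function(cfg) {
  stopifnot(inherits(cfg, "edge_scenario"))
  validate_scenario(cfg)
  n <- cfg$n_plots
  ss <- function(stream) substream_seed(cfg$seed, stream)
  yr_lo <- cfg$remeasure_years_range[1]
  yr_hi <- cfg$remeasure_years_range[2]

  ## ---- plots -------------------------------------------------------------
  set.seed(ss("plot_x"))
  plots <- tibble::tibble(plot_id = seq_len(n),
                          x_km = stats::runif(n, 0, 500))
  set.seed(ss("plot_y"))
  plots$y_km <- stats::runif(n, 0, 500)
  set.seed(ss("plot_years"))
  plots$years_between <- sample(seq(yr_lo, yr_hi), n, replace = TRUE)
  set.seed(ss("plot_type"))
  plots$forest_type_group <- sample(cfg$type_effects$forest_type_group, n,
                                    replace = TRUE,
                                    prob = cfg$type_effects$weight)
  set.seed(ss("plot_edge"))
  plots$is_edge_plot <- stats::runif(n) < cfg$edge_fraction
  set.seed(ss("plot_edge2"))
  plots$has_second_edge <- plots$is_edge_plot &
    stats::runif(n) < cfg$two_edge_prob

  cov <- cfg$covariates
  for (v in names(cov$sd)) {
    set.seed(ss(paste0("cov_", v)))
    mu <- ifelse(plots$is_edge_plot, cov$mean_edge[[v]],
                 cov$mean_interior[[v]])
    plots[[v]] <- clamp(stats::rnorm(n, mu, cov$sd[[v]]),
                        cov$lower[[v]], cov$upper[[v]])
  }

  ## ---- subplots ----------------------------------------------------------
  subplots <- tidyr::expand_grid(plot_id = plots$plot_id,
                                 subplot_index = 1:4) |>
    dplyr::mutate(subplot_id = .data$plot_id * 10L + .data$subplot_index,
                  is_central = .data$subplot_index == 1L,
                  area_m2 = cfg$subplot_area_m2)

  set.seed(ss("edge_subplot_idx"))
  e1 <- ceiling(stats::runif(n) * 4)          # primary edge subplot index
  set.seed(ss("edge_subplot_idx2"))
  e2 <- (e1 - 1 + ceiling(stats::runif(n) * 3)) %% 4 + 1  # distinct second
  edge_idx <- tibble::tibble(
    plot_id = plots$plot_id,
    idx1 = ifelse(plots$is_edge_plot, e1, NA_integer_),
    idx2 = ifelse(plots$has_second_edge, e2, NA_integer_)
  )
  subplots <- subplots |>
    dplyr::left_join(edge_idx, by = "plot_id") |>
    dplyr::mutate(
      is_edge_subplot = !is.na(.data$idx1) &
        (.data$subplot_index == .data$idx1 |
           (!is.na(.data$idx2) & .data$subplot_index == .data$idx2))
    ) |>
    dplyr::select(-"idx1", -"idx2")

  ## ---- conditions --------------------------------------------------------
  ns <- nrow(subplots)
  set.seed(ss("forest_prop"))
  p2 <- ifelse(subplots$is_edge_subplot,
               stats::runif(ns, cfg$forest_prop_range[1],
                            cfg$forest_prop_range[2]), 1)
  set.seed(ss("nonforest_class"))
  u_cls <- stats::runif(ns)
  set.seed(ss("nonforest_class_pick"))
  u_pick <- stats::runif(ns)
  anthro_pool <- c("developed", "cultivated", "road")
  unknown_pool <- c("unrecorded", "wetland", "water")
  nf_class <- ifelse(u_cls < cfg$anthropogenic_share,
                     anthro_pool[ceiling(u_pick * 3)],
                     unknown_pool[ceiling(u_pick * 3)])
  nf_class[!subplots$is_edge_subplot] <- NA_character_

  # special fates for a small share of edge subplots: condition lost to
  # non-forest by cycle 2, or no forest condition in cycle 1
  set.seed(ss("condition_fate"))
  u_fate <- stats::runif(ns)
  fate <- rep("normal", ns)
  fate[subplots$is_edge_subplot & u_fate < cfg$forest_loss_rate] <- "loss"
  fate[subplots$is_edge_subplot & u_fate >= cfg$forest_loss_rate &
         u_fate < cfg$forest_loss_rate + cfg$no_forest_rate] <- "no_t1"

  sub_cond <- tibble::tibble(
    subplot_id = subplots$subplot_id,
    p1 = ifelse(fate == "no_t1", 0, p2),
    p2 = ifelse(fate == "loss", 0, p2),
    nf_class = nf_class
  )
  cond_rows <- function(cycle, p) {
    forest <- tibble::tibble(subplot_id = sub_cond$subplot_id, cycle = cycle,
                             class = "forest", proportion = p)[p > 0, ]
    nonfor <- tibble::tibble(
      subplot_id = sub_cond$subplot_id, cycle = cycle,
      class = dplyr::coalesce(sub_cond$nf_class, "unrecorded"),
      proportion = 1 - p)[p < 1, ]
    dplyr::bind_rows(forest, nonfor)
  }
  conditions <- dplyr::bind_rows(cond_rows(1L, sub_cond$p1),
                                 cond_rows(2L, sub_cond$p2)) |>
    dplyr::arrange(.data$subplot_id, .data$cycle, .data$class)

  ## ---- subplot-level generative responses -------------------------------
  coefs <- scenario_coefficients(cfg)
  sub <- subplots |>
    dplyr::left_join(plots, by = "plot_id") |>
    dplyr::mutate(
      forested_prop = sub_cond$p2,
      area_ha = .data$forested_prop * cfg$subplot_area_m2 / M2_PER_HA,
      gen_class = dplyr::case_when(
        !.data$is_edge_subplot ~ "interior",
        nf_class %in% anthro_pool ~ "anthropogenic",
        TRUE ~ "unknown"
      )
    )
  x_mat <- as.matrix(sub[, names(cfg$covariate_slopes$bai)])
  eta_of <- function(resp) {
    co <- coefs[[resp]][match(sub$forest_type_group,
                              coefs[[resp]]$forest_type_group), ]
    m <- dplyr::case_when(sub$gen_class == "anthropogenic" ~ co$m_anthro,
                          sub$gen_class == "unknown" ~ co$m_unknown,
                          TRUE ~ 1)
    (co$a + drop(x_mat %*% cfg$covariate_slopes[[resp]])) / m
  }
  eta_ba <- eta_of("ba")
  eta_bai <- eta_of("bai")
  shape <- cfg$dispersion
  set.seed(ss("bai_draw"))
  bai_target <- stats::rgamma(ns, shape = shape, rate = shape * eta_bai)

  # stem counts first: expected density is the configured base plus the
  # class offset, unconfounded by covariates, so the raw density contrasts
  # are exact ground truth (randomized rounding keeps E[stems/ha] on
  # target). BA then follows as count x an exogenous mean-tree-size draw
  # whose distribution is identical across edge classes wherever the
  # density and BA effects are proportional, so mean diameter carries no
  # built-in edge effect; conditional on the count, BA is gamma with mean
  # on the inverse-link structure.
  dens <- cfg$stem_density_base +
    dplyr::case_when(sub$gen_class == "anthropogenic" ~
                       cfg$density_offset[["anthropogenic"]],
                     sub$gen_class == "unknown" ~
                       cfg$density_offset[["unknown"]],
                     TRUE ~ 0)
  lambda <- dens * sub$area_ha
  set.seed(ss("stem_count"))
  n_live <- floor(lambda) + (stats::runif(ns) < lambda %% 1)

  has_forest <- sub$forested_prop > 0
  n_live[!has_forest] <- 0L

  # tree sizes are i.i.d. from a threshold-shifted gamma whose mean carries
  # the BA structure: E[BA/ha] = density * mean tree BA = mu on the
  # inverse-link scale, and conditional on the count the subplot BA is
  # exactly gamma. The per-tree shape is anchored so a representative
  # (half-forested) edge subplot has the configured BA dispersion; smaller
  # subplots are noisier, fully forested ones tighter, as in aggregated
  # field data.
  ba_min_tree <- ba_from_dbh(cfg$dbh_min_cm)
  s_mean <- 1 / (eta_ba * dens)          # mean tree BA (m^2)
  if (any(s_mean[has_forest] <= ba_min_tree * 1.05)) {
    stop_ef("infeasible configuration: implied mean tree basal area is at ",
            "or below the measurement threshold; check stem_density_base ",
            "against the BA baselines")
  }
  lambda_anchor <- cfg$stem_density_base * cfg$subplot_area_m2 /
    M2_PER_HA / 2
  k_tree <- cfg$dispersion * ((s_mean - ba_min_tree) / s_mean)^2 /
    lambda_anchor

  ## ---- live tree synthesis ----------------------------------------------
  live <- synthesize_live_trees(sub, n_live, s_mean, k_tree, bai_target,
                                cfg, ss)
  n_live <- live$n_live

  ## ---- mortality trees ---------------------------------------------------
  rates <- cfg$mortality_rates
  edge_any <- sub$gen_class != "interior"
  lam_dead <- rates[["biogenic_interior"]] * (1 - edge_any) * n_live *
    sub$years_between +
    rates[["biogenic_edge"]] * edge_any * n_live * sub$years_between
  lam_harv <- ifelse(edge_any, rates[["harvest_edge"]],
                     rates[["harvest_interior"]]) * n_live * sub$years_between
  set.seed(ss("mortality_count"))
  n_dead <- stats::rpois(ns, lam_dead)
  set.seed(ss("harvest_count"))
  n_harv <- stats::rpois(ns, lam_harv)
  set.seed(ss("mortality_dbh"))
  mort <- tibble::tibble(
    row = rep(seq_len(ns), n_dead + n_harv),
    status_t2 = unlist(purrr::map2(n_dead, n_harv, function(d, h)
      rep(c("dead_biogenic", "harvested"), c(d, h))), use.names = FALSE)
  )
  if (nrow(mort) > 0) {
    g_mort <- stats::rgamma(nrow(mort), shape = 1.3, rate = 1)
    gbar <- live$g_mean[mort$row]
    gbar[is.na(gbar) | gbar <= 0] <- 400
    mort <- mort |>
      dplyr::mutate(
        subplot_id = sub$subplot_id[.data$row],
        dbh_t1_cm = sqrt(cfg$dbh_min_cm^2 + g_mort * gbar / 1.3),
        dbh_t2_cm = NA_real_,
        status_t2 = .data$status_t2,
        years_between = sub$years_between[.data$row],
        ingrowth = FALSE
      ) |>
      dplyr::select(-"row")
  } else {
    mort <- tibble::tibble(subplot_id = integer(), dbh_t1_cm = double(),
                           dbh_t2_cm = double(), status_t2 = character(),
                           years_between = integer(), ingrowth = logical())
  }

  trees <- dplyr::bind_rows(live$trees, mort) |>
    dplyr::arrange(.data$subplot_id) |>
    dplyr::mutate(tree_id = dplyr::row_number(), .before = 1)

  ## ---- measurement errors ------------------------------------------------
  set.seed(ss("errors"))
  u_err <- stats::runif(ns)
  set.seed(ss("errors_dir"))
  u_dir <- stats::runif(ns)
  set.seed(ss("errors_mag"))
  u_mag <- stats::runif(ns)
  r <- cfg$measurement_error_rate
  err <- tibble::tibble(
    subplot_id = sub$subplot_id,
    bai_error = u_err < r & has_forest,
    ba_error = u_err >= r & u_err < 2 * r & has_forest,
    error_up = u_dir < 0.5
  )
  # dbh measurement errors with magnitudes continuous on the log scale,
  # from mild mis-reads to decade-scale (unit/transcription) blunders.
  # BAI errors corrupt recorded prior diameters (a shrunken prior inflates
  # growth, an inflated prior makes it strongly negative); BA errors
  # rescale current diameters, compensating the prior so the increment of
  # squared diameters is preserved
  f_bai <- 10^((0.02 + 0.98 * u_mag) * ifelse(err$error_up, -1, 1) * 0.5)
  f_ba <- 10^((0.1 + 1.9 * u_mag) * ifelse(err$error_up, 1, -1))
  trees <- trees |>
    dplyr::left_join(err, by = "subplot_id") |>
    dplyr::mutate(
      live = .data$status_t2 == "live",
      f1 = f_bai[match(.data$subplot_id, err$subplot_id)],
      f2 = f_ba[match(.data$subplot_id, err$subplot_id)],
      dbh_t1_cm = dplyr::if_else(.data$bai_error & .data$live,
                                 .data$dbh_t1_cm * .data$f1, .data$dbh_t1_cm),
      dbh_t1_new = dplyr::if_else(
        .data$ba_error & .data$live & !is.na(.data$dbh_t1_cm),
        sqrt(pmax(.data$dbh_t1_cm^2 + (.data$f2 - 1) * .data$dbh_t2_cm^2, 1)),
        .data$dbh_t1_cm),
      dbh_t2_cm = dplyr::if_else(.data$ba_error & .data$live,
                                 sqrt(.data$f2) * .data$dbh_t2_cm,
                                 .data$dbh_t2_cm),
      dbh_t1_cm = .data$dbh_t1_new
    ) |>
    dplyr::select("tree_id", "subplot_id", "dbh_t1_cm", "dbh_t2_cm",
                  "status_t2", "years_between", "ingrowth")

  truth <- tibble::tibble(
    subplot_id = sub$subplot_id,
    plot_id = sub$plot_id,
    gen_class = ifelse(has_forest, sub$gen_class, "none"),
    eta_ba = eta_ba, eta_bai = eta_bai,
    ba_true = live$ba_real / pmax(sub$area_ha, 1e-12),
    bai_true = live$bai_real / pmax(sub$area_ha, 1e-12) / sub$years_between,
    stems_true = n_live / pmax(sub$area_ha, 1e-12),
    n_live = n_live,
    bai_error = err$bai_error, ba_error = err$ba_error
  )
  truth$ba_true[!has_forest] <- NA_real_
  truth$bai_true[!has_forest] <- NA_real_
  truth$stems_true[!has_forest] <- NA_real_

  out <- list(
    plots = plots |> dplyr::select("plot_id", "x_km", "y_km",
                                   "years_between", "forest_type_group",
                                   dplyr::all_of(names(cov$sd))),
    subplots = subplots |> dplyr::select("subplot_id", "plot_id",
                                         "subplot_index", "is_central",
                                         "area_m2"),
    conditions = conditions,
    trees = trees,
    truth = truth,
    config = cfg
  )
  class(out) <- "edge_inventory"
  out
}

# draw i.i.d. tree sizes from a threshold-shifted gamma (so subplot BA is
# their sum, gamma-distributed given the count, with the configured mean
# structure) and back-compute prior diameters so the subplot BAI target is
# realized exactly under the inventory's accounting rules
synthesize_live_trees <- function(sub, n_live, s_mean, k_tree, bai_target,
                                  cfg, ss) {
  ns <- nrow(sub)
  dbh_min <- cfg$dbh_min_cm
  ba_min <- ba_from_dbh(dbh_min)
  k <- 40000 / pi                       # dbh^2 = k * ba
  target_inc <- bai_target * sub$area_ha * sub$years_between

  rows <- rep(seq_len(ns), n_live)
  m <- length(rows)
  excess_mean <- pmax(s_mean - ba_min, 1e-6)
  # size mixture: a small recruit component keeps stems near the
  # measurement threshold (the ingrowth pool) while the main component
  # carries the stand structure; the subplot mean is preserved exactly
  p_recruit <- 0.12
  m_recruit <- 0.004                    # ~14.6 cm recruits
  m_main <- pmax((excess_mean - p_recruit * m_recruit) / (1 - p_recruit),
                 1e-6)
  # main-component shape calibrated so the total mixture variance equals
  # the anchored target (the recruit component is nearly a point mass at
  # small sizes, which would otherwise inflate the size variance)
  var_target <- excess_mean^2 / k_tree
  ratio <- (var_target + excess_mean^2 - p_recruit * 2 * m_recruit^2) /
    ((1 - p_recruit) * m_main^2)
  k_main <- 1 / pmax(ratio - 1, 1 / 50)
  set.seed(ss("tree_mix"))
  is_recruit <- stats::runif(m) < p_recruit
  set.seed(ss("tree_g"))
  g_main <- stats::rgamma(m, shape = k_main[rows],
                          rate = k_main[rows] / m_main[rows])
  set.seed(ss("tree_g_recruit"))
  g <- ifelse(is_recruit, stats::rexp(m, rate = 1 / m_recruit), g_main)
  set.seed(ss("ingrowth_missing"))
  u_missing <- stats::runif(m)

  tr <- tibble::tibble(row = rows, g = g, u_missing = u_missing)
  per <- tr |>
    dplyr::group_by(.data$row) |>
    dplyr::summarise(ba_sum = sum(ba_min + .data$g), .groups = "drop")
  target_ba <- rep(0, ns)
  target_ba[per$row] <- per$ba_sum      # realized subplot BA (m^2)

  tr <- tr |>
    dplyr::mutate(
      ba2 = ba_min + .data$g,
      dbh2 = sqrt(k * .data$ba2),
      inc = (target_inc[.data$row] / pmax(target_ba[.data$row], 1e-300)) *
        .data$ba2
    )
  # cap increments so prior diameters stay physical
  ba_floor <- ba_from_dbh(2)
  tr$inc <- pmin(tr$inc, pmax(tr$ba2 - ba_floor, 0))
  tr <- tr |>
    dplyr::mutate(
      ba1 = .data$ba2 - .data$inc,
      dbh1 = sqrt(k * .data$ba1),
      ingrowth = .data$dbh1 < dbh_min,
      missing_prior = .data$ingrowth &
        .data$u_missing < cfg$ingrowth_missing_prob
    )
  # for ingrowth stems with no recorded prior the inventory rule measures
  # growth from the threshold; move the shortfall onto the subplot's largest
  # non-ingrowth stem so the realized subplot BAI stays on target
  adj <- tr |>
    dplyr::group_by(.data$row) |>
    dplyr::summarise(
      delta = sum((.data$inc - (.data$ba2 - ba_min))[.data$missing_prior]),
      has_big = any(!.data$ingrowth),
      .groups = "drop") |>
    dplyr::filter(.data$delta > 0, .data$has_big)
  if (nrow(adj) > 0) {
    tr <- tr |>
      dplyr::group_by(.data$row) |>
      dplyr::mutate(is_largest = !.data$ingrowth &
                      dplyr::row_number(dplyr::desc(.data$ba2)) == 1L) |>
      dplyr::ungroup()
    dd <- adj$delta[match(tr$row, adj$row)]
    dd[is.na(dd)] <- 0
    cand <- tr$is_largest & dd > 0
    new_ba1 <- tr$ba1 - dd
    feasible_row <- adj$row[adj$row %in% tr$row[cand & new_ba1 >= ba_min]]
    apply_big <- cand & tr$row %in% feasible_row & new_ba1 >= ba_min
    tr$ba1[apply_big] <- new_ba1[apply_big]
    tr$inc[apply_big] <- tr$ba2[apply_big] - tr$ba1[apply_big]
    tr$dbh1[apply_big] <- sqrt(k * tr$ba1[apply_big])
    # where no feasible carrier exists, keep the recorded prior instead
    tr$missing_prior[!(tr$row %in% feasible_row)] <-
      tr$missing_prior[!(tr$row %in% feasible_row)] & FALSE
    tr$is_largest <- NULL
  }

  # realized clean subplot sums under the inventory's accounting rules
  real <- tr |>
    dplyr::mutate(
      contrib = dplyr::if_else(.data$missing_prior,
                               .data$ba2 - ba_min,
                               .data$ba2 - .data$ba1)
    ) |>
    dplyr::group_by(.data$row) |>
    dplyr::summarise(ba_real = sum(.data$ba2),
                     bai_real = sum(.data$contrib),
                     g_mean = mean(40000 / pi * .data$g),
                     .groups = "drop")
  ba_real <- bai_real <- rep(0, ns)
  g_mean <- rep(NA_real_, ns)
  ba_real[real$row] <- real$ba_real
  bai_real[real$row] <- real$bai_real
  g_mean[real$row] <- real$g_mean

  trees <- tibble::tibble(
    subplot_id = sub$subplot_id[tr$row],
    dbh_t1_cm = ifelse(tr$missing_prior, NA_real_, tr$dbh1),
    dbh_t2_cm = tr$dbh2,
    status_t2 = "live",
    years_between = sub$years_between[tr$row],
    ingrowth = tr$ingrowth
  )
  list(trees = trees, ba_real = ba_real, bai_real = bai_real,
       g_mean = g_mean, n_live = n_live)
}
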