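#' Classify subplots by edge status from condition records
#'
#' Applies the edge-identification rules to the condition table: a subplot
#' holding both a forest and a non-forest condition in the most recent cycle
#' is an edge, with its non-forest land-cover class mapped to a binary
#' anthropogenic/unknown designation; a fully forested subplot on a plot
#' whose four subplots are all fully forested in both cycles is interior;
#' fully forested subplots sharing a plot with an edge subplot are
#' edge-proximate (excluded downstream); subplots that lost their forest
#' condition between cycles, or lack one in either cycle, are excluded.
#'
#' @param conditions Condition table: `subplot_id`, `cycle` (1 or 2),
#'   `class`, `proportion`.
#' @param subplots Subplot table: `subplot_id`, `plot_id`, `is_central`,
#'   `area_m2`.
#' @param anthropogenic_classes Land-cover classes mapped to the
#'   anthropogenic edge type.
#' @param known_classes All recognized non-forest classes; everything in
#'   this set that is not anthropogenic maps to the unknown edge type.
#' @param on_unknown_code `"error"` to fail on an unrecognized land-cover
#'   class, `"unknown"` to fold it into the unknown edge type.
#' @return A tibble with one row per subplot: `subplot_id`, `plot_id`,
#'   `is_central`, `edge_class` (one of `interior`, `edge_anthropogenic`,
#'   `edge_unknown`, `edge_proximate`, `excluded_forest_loss`,
#'   `excluded_no_forest`, `excluded_not_interior`), `forested_prop` and
#'   `forested_area_m2` (most recent cycle), and `nonforest_class`.
#' @export
classify_subplots <- function(conditions, subplots,
                              anthropogenic_classes = c("developed",
                                                        "cultivated", "road"),
                              known_classes = c("developed", "cultivated",
                                                "road", "unrecorded",
                                                "wetland", "water", "barren"),
                              on_unknown_code = c("error", "unknown")) {
  on_unknown_code <- match.arg(on_unknown_code)
  assert_columns(conditions, c("subplot_id", "cycle", "class", "proportion"))
  assert_columns(subplots, c("subplot_id", "plot_id", "is_central",
                             "area_m2"))

  bad_codes <- setdiff(unique(conditions$class),
                       c("forest", known_classes))
  if (length(bad_codes) > 0 && on_unknown_code == "error") {
    stop_ef("unknown land-cover class code(s): ",
            paste(bad_codes, collapse = ", "))
  }

  tot <- conditions |>
    dplyr::group_by(.data$subplot_id, .data$cycle) |>
    dplyr::summarise(total = sum(.data$proportion), .groups = "drop")
  if (any(tot$total > 1 + 1e-8)) {
    stop_ef("overlapping condition proportions exceed 100% on subplot(s): ",
            paste(utils::head(tot$subplot_id[tot$total > 1 + 1e-8], 5),
                  collapse = ", "))
  }
  missing_cycle <- subplots |>
    tidyr::expand_grid(cycle = 1:2) |>
    dplyr::anti_join(conditions, by = c("subplot_id", "cycle"))
  if (nrow(missing_cycle) > 0) {
    stop_ef("subplot(s) missing a condition record for a cycle: ",
            paste(utils::head(missing_cycle$subplot_id, 5), collapse = ", "))
  }

  per_cycle <- conditions |>
    dplyr::group_by(.data$subplot_id, .data$cycle) |>
    dplyr::summarise(
      forest_prop = sum(.data$proportion[.data$class == "forest"]),
      nonforest_prop = sum(.data$proportion[.data$class != "forest"]),
      nonforest_class = dplyr::first(
        .data$class[.data$class != "forest"][
          order(-.data$proportion[.data$class != "forest"])]),
      .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cycle",
                       values_from = c("forest_prop", "nonforest_prop",
                                       "nonforest_class"))

  cls <- subplots |>
    dplyr::left_join(per_cycle, by = "subplot_id") |>
    dplyr::mutate(
      has_forest_1 = .data$forest_prop_1 > 0,
      has_forest_2 = .data$forest_prop_2 > 0,
      fully_forested = .data$forest_prop_1 >= 1 - 1e-8 &
        .data$forest_prop_2 >= 1 - 1e-8,
      is_edge = .data$has_forest_2 & .data$nonforest_prop_2 > 0 &
        .data$has_forest_1
    )
  plot_flags <- cls |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(plot_all_forested = all(.data$fully_forested),
                     plot_has_edge = any(.data$is_edge), .groups = "drop")
  cls <- cls |>
    dplyr::left_join(plot_flags, by = "plot_id") |>
    dplyr::mutate(
      edge_class = dplyr::case_when(
        !.data$has_forest_1 ~ "excluded_no_forest",
        .data$has_forest_1 & !.data$has_forest_2 ~ "excluded_forest_loss",
        .data$is_edge & .data$nonforest_class_2 %in% anthropogenic_classes ~
          "edge_anthropogenic",
        .data$is_edge ~ "edge_unknown",
        .data$plot_all_forested ~ "interior",
        .data$plot_has_edge ~ "edge_proximate",
        TRUE ~ "excluded_not_interior"
      ),
      forested_prop = .data$forest_prop_2,
      forested_area_m2 = .data$forest_prop_2 * .data$area_m2
    ) |>
    dplyr::select("subplot_id", "plot_id", "is_central", "edge_class",
                  "forested_prop", "forested_area_m2",
                  nonforest_class = "nonforest_class_2")
  cls
}

#' Basal area of one subplot's tree list
#'
#' Summed cross-sectional area of live stems at or above the measurement
#' threshold in the most recent cycle, per hectare of forested area.
#'
#' @param trees Tree records for one subplot (`dbh_t2_cm`, `status_t2`).
#' @param forested_area_m2 Forested area of the subplot (m^2), > 0.
#' @param dbh_min_cm Measurement threshold (cm).
#' @return BA in m^2 ha^-1.
#' @export
compute_ba <- function(trees, forested_area_m2, dbh_min_cm = 12.7) {
  if (forested_area_m2 <= 0) stop_ef("forested_area_m2 must be > 0")
  keep <- trees$status_t2 == "live" & !is.na(trees$dbh_t2_cm) &
    trees$dbh_t2_cm >= dbh_min_cm
  sum(ba_from_dbh(trees$dbh_t2_cm[keep])) / (forested_area_m2 / M2_PER_HA)
}

#' Basal area increment of one subplot's tree list
#'
#' Per-tree annualized difference in basal area between the two cycles,
#' summed over live stems at or above the threshold and normalized per
#' hectare of forested area. Ingrowth stems without a recorded prior
#' diameter are measured from the threshold diameter. Negative per-tree
#' increments (field measurement error) are retained here; the dataset
#' filter removes them distributionally.
#'
#' @inheritParams compute_ba
#' @return BAI in m^2 ha^-1 yr^-1.
#' @export
compute_bai <- function(trees, forested_area_m2, dbh_min_cm = 12.7) {
  if (forested_area_m2 <= 0) stop_ef("forested_area_m2 must be > 0")
  keep <- trees$status_t2 == "live" & !is.na(trees$dbh_t2_cm) &
    trees$dbh_t2_cm >= dbh_min_cm
  t <- trees[keep, ]
  if (nrow(t) == 0) return(0)
  if (any(t$years_between <= 0)) stop_ef("years_between must be > 0")
  prior <- ifelse(is.na(t$dbh_t1_cm), ba_from_dbh(dbh_min_cm),
                  ba_from_dbh(t$dbh_t1_cm))
  sum((ba_from_dbh(t$dbh_t2_cm) - prior) / t$years_between) /
    (forested_area_m2 / M2_PER_HA)
}

#' Stem density and mean diameter of one subplot's tree list
#'
#' @inheritParams compute_ba
#' @return A list with `stems_ha` (count of qualifying live stems per
#'   hectare) and `mean_dbh_cm` (arithmetic mean diameter; `NA` when no
#'   stem qualifies).
#' @export
compute_density_diameter <- function(trees, forested_area_m2,
                                     dbh_min_cm = 12.7) {
  if (forested_area_m2 <= 0) stop_ef("forested_area_m2 must be > 0")
  keep <- trees$status_t2 == "live" & !is.na(trees$dbh_t2_cm) &
    trees$dbh_t2_cm >= dbh_min_cm
  n <- sum(keep)
  list(stems_ha = n / (forested_area_m2 / M2_PER_HA),
       mean_dbh_cm = if (n == 0) NA_real_ else mean(trees$dbh_t2_cm[keep]))
}

# vectorized per-subplot response computation over the whole tree table
subplot_responses <- function(trees, classified, dbh_min_cm = 12.7) {
  assert_columns(trees, c("subplot_id", "dbh_t1_cm", "dbh_t2_cm",
                          "status_t2", "years_between"))
  area <- classified |>
    dplyr::select("subplot_id", "forested_area_m2")
  live <- trees |>
    dplyr::filter(.data$status_t2 == "live", !is.na(.data$dbh_t2_cm),
                  .data$dbh_t2_cm >= dbh_min_cm) |>
    dplyr::mutate(
      ba2 = ba_from_dbh(.data$dbh_t2_cm),
      prior = dplyr::if_else(is.na(.data$dbh_t1_cm),
                             ba_from_dbh(dbh_min_cm),
                             ba_from_dbh(.data$dbh_t1_cm)),
      inc_yr = (.data$ba2 - .data$prior) / .data$years_between
    ) |>
    dplyr::group_by(.data$subplot_id) |>
    dplyr::summarise(ba_sum = sum(.data$ba2), bai_sum = sum(.data$inc_yr),
                     n_stems = dplyr::n(),
                     mean_dbh_cm = mean(.data$dbh_t2_cm), .groups = "drop")
  dead <- trees |>
    dplyr::filter(.data$status_t2 != "live", !is.na(.data$dbh_t1_cm),
                  .data$dbh_t1_cm >= dbh_min_cm) |>
    dplyr::mutate(ba1_yr = ba_from_dbh(.data$dbh_t1_cm) /
                    .data$years_between) |>
    dplyr::group_by(.data$subplot_id) |>
    dplyr::summarise(
      mort_bio_sum = sum(.data$ba1_yr[.data$status_t2 == "dead_biogenic"]),
      mort_harv_sum = sum(.data$ba1_yr[.data$status_t2 == "harvested"]),
      .groups = "drop")

  area |>
    dplyr::left_join(live, by = "subplot_id") |>
    dplyr::left_join(dead, by = "subplot_id") |>
    dplyr::mutate(
      area_ha = .data$forested_area_m2 / M2_PER_HA,
      ba_m2_ha = dplyr::coalesce(.data$ba_sum, 0) / pmax(.data$area_ha, 1e-12),
      bai_m2_ha_yr = dplyr::coalesce(.data$bai_sum, 0) /
        pmax(.data$area_ha, 1e-12),
      stems_ha = dplyr::coalesce(.data$n_stems, 0L) /
        pmax(.data$area_ha, 1e-12),
      mort_biogenic_m2_ha_yr = dplyr::coalesce(.data$mort_bio_sum, 0) /
        pmax(.data$area_ha, 1e-12),
      mort_harvest_m2_ha_yr = dplyr::coalesce(.data$mort_harv_sum, 0) /
        pmax(.data$area_ha, 1e-12)
    ) |>
    dplyr::select("subplot_id", "ba_m2_ha", "bai_m2_ha_yr", "stems_ha",
                  "mean_dbh_cm", "mort_biogenic_m2_ha_yr",
                  "mort_harvest_m2_ha_yr")
}

#' Assemble the per-subplot analysis table from inventory tables
#'
#' Runs [classify_subplots()], computes the per-subplot responses from the
#' tree table, joins plot-level covariates, and keeps the analyzable classes
#' (interior and edge subplots). Counts of subplots removed by each
#' classification rule are attached as the `"classification"` attribute.
#'
#' @param inv An `edge_inventory` (from [generate_inventory()]) or a list
#'   with compatible `plots`, `subplots`, `conditions`, `trees` tables.
#' @param dbh_min_cm Measurement threshold (cm).
#' @param ... Passed to [classify_subplots()].
#' @return A tibble with one row per analyzable subplot: identifiers, edge
#'   class, forest type group, covariates, coordinates and responses.
#' @export
build_analysis_data <- function(inv, dbh_min_cm = 12.7, ...) {
  cls <- classify_subplots(inv$conditions, inv$subplots, ...)
  resp <- subplot_responses(inv$trees, cls, dbh_min_cm = dbh_min_cm)
  keep_classes <- c("interior", "edge_anthropogenic", "edge_unknown")
  ledger <- cls |>
    dplyr::filter(!.data$edge_class %in% keep_classes) |>
    dplyr::count(.data$edge_class, name = "n_removed") |>
    dplyr::rename(rule = "edge_class")
  out <- cls |>
    dplyr::filter(.data$edge_class %in% keep_classes) |>
    dplyr::left_join(resp, by = "subplot_id") |>
    dplyr::left_join(inv$plots, by = "plot_id")
  attr(out, "classification") <- ledger
  out
}
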