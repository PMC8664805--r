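#' Apply the analysis-dataset filtering cascade
#'
#' Reduces the classified subplot table to the pre-matching analysis
#' dataset: (1) subplots with under `area_min_m2` of forested area are
#' dropped (small-area BA bias); (2) one subplot is kept per plot — for
#' plots with edge subplots, the edge subplot with the largest forested
#' area, for interior plots the central subplot (pseudo-replication
#' control); (3) records outside the central quantile interval of BA and,
#' separately, of BAI are dropped (both quantile pairs computed on the
#' post-selection sample, then applied jointly); (4) remaining records with
#' non-positive BA or BAI are dropped (gamma support). An exclusion ledger
#' whose counts sum exactly to the rows removed is attached as the
#' `"exclusions"` attribute (see [exclusion_ledger()]).
#'
#' @param data Analysis table from [build_analysis_data()].
#' @param area_min_m2 Minimum forested area (m^2).
#' @param trim_quantiles Lower and upper trim quantiles; linear-interpolation
#'   sample quantiles (type 7), trimming strictly outside the closed
#'   interval.
#' @return The filtered tibble with an `"exclusions"` attribute.
#' @export
filter_dataset <- function(data, area_min_m2 = 30,
                           trim_quantiles = c(0.025, 0.975)) {
  assert_columns(data, c("subplot_id", "plot_id", "edge_class", "is_central",
                         "forested_area_m2", "ba_m2_ha", "bai_m2_ha_yr"))
  ledger <- list()
  n0 <- nrow(data)

  d1 <- data |> dplyr::filter(.data$forested_area_m2 >= area_min_m2)
  ledger$area_below_minimum <- n0 - nrow(d1)

  d2 <- d1 |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::arrange(dplyr::desc(.data$forested_area_m2), .data$subplot_id,
                   .by_group = TRUE) |>
    dplyr::filter(
      if (any(.data$edge_class != "interior")) {
        dplyr::row_number() == which(.data$edge_class != "interior")[1]
      } else {
        .data$is_central
      }
    ) |>
    dplyr::ungroup()
  ledger$per_plot_selection <- nrow(d1) - nrow(d2)

  q_ba <- stats::quantile(d2$ba_m2_ha, trim_quantiles, type = 7,
                          names = FALSE)
  q_bai <- stats::quantile(d2$bai_m2_ha_yr, trim_quantiles, type = 7,
                           names = FALSE)
  in_ba <- d2$ba_m2_ha >= q_ba[1] & d2$ba_m2_ha <= q_ba[2]
  in_bai <- d2$bai_m2_ha_yr >= q_bai[1] & d2$bai_m2_ha_yr <= q_bai[2]
  ledger$ba_quantile_trim <- sum(!in_ba)
  ledger$bai_quantile_trim <- sum(in_ba & !in_bai)
  d3 <- d2[in_ba & in_bai, ]

  pos <- d3$ba_m2_ha > 0 & d3$bai_m2_ha_yr > 0
  ledger$nonpositive_response <- sum(!pos)
  d4 <- d3[pos, ]

  led <- tibble::tibble(rule = names(ledger),
                        n_removed = unlist(ledger, use.names = FALSE)) |>
    dplyr::mutate(n_remaining = n0 - cumsum(.data$n_removed))
  if (nrow(d4) == 0) {
    stop_ef("filtering removed every record; attrition by rule:\n",
            paste(sprintf("  %s: %d", led$rule, led$n_removed),
                  collapse = "\n"))
  }
  attr(d4, "exclusions") <- led
  attr(d4, "trim_bounds") <- list(ba = q_ba, bai = q_bai)
  d4
}

#' Exclusion ledger of a filtered dataset
#'
#' @param data A tibble returned by [filter_dataset()].
#' @return A tibble with columns `rule`, `n_removed`, `n_remaining`, in
#'   application order.
#' @export
exclusion_ledger <- function(data) {
  led <- attr(data, "exclusions")
  if (is.null(led)) stop_ef("no exclusion ledger attached; ",
                            "was this produced by filter_dataset()?")
  led
}

#' Write an exclusion ledger as JSON
#'
#' @param data A tibble returned by [filter_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exclusion_ledger <- function(data, path) {
  jsonlite::write_json(exclusion_ledger(data), path, digits = NA)
  invisible(path)
}
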