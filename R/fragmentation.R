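#' Biome-scale fragmentation report
#'
#' Zonal and stratum-level accounting of edge vs interior forest from a
#' forest mask and its edge mask: percent edge forest per zone, edge and
#' interior areas (ha and Mha) per biome x continent stratum, and the
#' temperate-vs-tropical edge-area comparison (ratio and percent excess,
#' `100 * (A_temperate - A_tropical) / A_tropical`).
#'
#' @param edge Logical edge mask.
#' @param forest Logical forest mask.
#' @param zones Integer zone-id matrix.
#' @param zone_info Tibble with `zone`, `biome`, `continent`.
#' @param pixel_area_ha Pixel area in hectares.
#' @param tau Canopy threshold used to build `forest` (recorded in the
#'   report).
#' @return An object of class `fragmentation_report`: list with `zones`
#'   (per-zone percent edge), `strata` (per biome x continent edge,
#'   interior and total areas), `biome_stats` (edge area per biome, the
#'   temperate:tropical ratio and percent excess), and `tau`.
#' @export
biome_summary <- function(edge, forest, zones, zone_info,
                          pixel_area_ha = 0.09, tau = NA_real_) {
  stopifnot(all(dim(edge) == dim(forest)), all(dim(edge) == dim(zones)))
  assert_columns(zone_info, c("zone", "biome", "continent"))
  zf <- zonal_edge_fraction(edge, forest, zones) |>
    dplyr::left_join(zone_info, by = "zone") |>
    dplyr::mutate(pct_edge = 100 * .data$edge_fraction)

  strata <- zf |>
    dplyr::group_by(.data$biome, .data$continent) |>
    dplyr::summarise(
      edge_area_ha = sum(.data$n_edge) * pixel_area_ha,
      interior_area_ha = sum(.data$n_forest - .data$n_edge) * pixel_area_ha,
      .groups = "drop") |>
    dplyr::mutate(
      total_forest_ha = .data$edge_area_ha + .data$interior_area_ha,
      edge_area_mha = .data$edge_area_ha / 1e6,
      interior_area_mha = .data$interior_area_ha / 1e6,
      pct_edge = 100 * .data$edge_area_ha /
        pmax(.data$total_forest_ha, .Machine$double.eps))

  by_biome <- strata |>
    dplyr::group_by(.data$biome) |>
    dplyr::summarise(edge_area_ha = sum(.data$edge_area_ha),
                     total_forest_ha = sum(.data$total_forest_ha),
                     .groups = "drop")
  a_temp <- by_biome$edge_area_ha[by_biome$biome == "temperate"]
  a_trop <- by_biome$edge_area_ha[by_biome$biome == "tropical"]
  have_both <- length(a_temp) == 1 && length(a_trop) == 1 && a_trop > 0
  biome_stats <- tibble::tibble(
    edge_area_temperate_ha = if (length(a_temp) == 1) a_temp else NA_real_,
    edge_area_tropical_ha = if (length(a_trop) == 1) a_trop else NA_real_,
    ratio_temperate_tropical = if (have_both) a_temp / a_trop else NA_real_,
    pct_excess_temperate = if (have_both) {
      100 * (a_temp - a_trop) / a_trop
    } else NA_real_
  )

  structure(list(zones = zf, strata = strata, biome_stats = biome_stats,
                 tau = tau, pixel_area_ha = pixel_area_ha),
            class = "fragmentation_report")
}

#' Percent excess edge area between two printed biome areas
#'
#' Worked-example arithmetic for comparing published edge-forest areas:
#' `100 * (a - b) / b`.
#'
#' @param area_a,area_b Edge-forest areas (same units, e.g. Mha).
#' @return Percent excess of `area_a` over `area_b`.
#' @export
pct_excess_area <- function(area_a, area_b) 100 * (area_a - area_b) / area_b

#' @export
print.fragmentation_report <- function(x, ...) {
  cat("<fragmentation_report> tau =", x$tau, "\n")
  print(x$strata)
  print(x$biome_stats)
  invisible(x)
}

#' Agreement between two per-zone edge-percentage products
#'
#' Ordinary least-squares variance explained (R-squared of regressing `b`
#' on `a`) and root-mean-square difference between two vectors of per-zone
#' percent edge forest derived from different land-cover products.
#'
#' @param a,b Numeric vectors of per-zone percent edge (same zones, same
#'   order); missing pairs are dropped.
#' @return A one-row tibble with `r_squared`, `rmse`, `n`.
#' @export
compare_products <- function(a, b) {
  if (length(a) != length(b)) stop_ef("per-zone vectors differ in length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) stop_ef("need at least two zones to compare products")
  r2 <- if (stats::var(a) == 0 || stats::var(b) == 0) {
    if (all(b == a)) 1 else 0
  } else {
    # a perfect fit triggers a harmless precision warning in summary.lm
    suppressWarnings(summary(stats::lm(b ~ a))$r.squared)
  }
  tibble::tibble(r_squared = r2, rmse = sqrt(mean((a - b)^2)),
                 n = length(a))
}

#' Plot edge and interior forest area by biome and continent
#'
#' @param object A `fragmentation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fragmentation_report <- function(object, ...) {
  df <- object$strata |>
    tidyr::pivot_longer(c("edge_area_mha", "interior_area_mha"),
                        names_to = "component", values_to = "area_mha") |>
    dplyr::mutate(component = ifelse(.data$component == "edge_area_mha",
                                     "edge", "interior"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$continent, y = .data$area_mha,
                                   fill = .data$component)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~ .data$biome, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "forest area (Mha)", fill = NULL) +
    ggplot2::theme_minimal()
}
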