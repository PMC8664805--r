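#' Per-zone edge forest fraction
#'
#' Fraction of forest pixels flagged as edge within each zone. Zones with
#' no forest get a missing fraction (never zero).
#'
#' @param edge Logical edge mask.
#' @param forest Logical forest mask.
#' @param zones Integer zone-id matrix of the same shape.
#' @return A tibble with `zone`, `n_forest`, `n_edge`, `edge_fraction`.
#' @export
zonal_edge_fraction <- function(edge, forest, zones) {
  stopifnot(all(dim(edge) == dim(forest)), all(dim(edge) == dim(zones)))
  ids <- sort(unique(as.vector(zones)))
  purrr::map_dfr(ids, function(z) {
    in_z <- zones == z
    nf <- sum(forest & in_z)
    ne <- sum(edge & forest & in_z)
    tibble::tibble(zone = z, n_forest = nf, n_edge = ne,
                   edge_fraction = if (nf == 0) NA_real_ else ne / nf)
  })
}

#' Forest-type composition per zone
#'
#' Area of each forest type group within each zone, from pixel counts and
#' the pixel area (0.09 ha for a 30 m grid).
#'
#' @param forest_type Character matrix of forest type per pixel (`NA` off
#'   forest).
#' @param zones Integer zone-id matrix.
#' @param group_map Optional named vector mapping raw raster values to
#'   aggregated groups (identity when `NULL`).
#' @param pixel_area_ha Area of one pixel in hectares.
#' @return A tibble with `zone`, `forest_type_group`, `area_ha`.
#' @export
zone_composition <- function(forest_type, zones, group_map = NULL,
                             pixel_area_ha = 0.09) {
  stopifnot(all(dim(forest_type) == dim(zones)))
  ft <- as.vector(forest_type)
  if (!is.null(group_map)) {
    mapped <- unname(group_map[ft])
    if (any(!is.na(ft) & is.na(mapped))) {
      stop_ef("forest-type values missing from group_map: ",
              paste(utils::head(unique(ft[!is.na(ft) & is.na(mapped)]), 5),
                    collapse = ", "))
    }
    ft <- mapped
  }
  tibble::tibble(zone = as.vector(zones), forest_type_group = ft) |>
    dplyr::filter(!is.na(.data$forest_type_group)) |>
    dplyr::count(.data$zone, .data$forest_type_group) |>
    dplyr::mutate(area_ha = .data$n * pixel_area_ha) |>
    dplyr::select(-"n")
}

#' Per-zone covariate means
#'
#' @param covariates Named list of covariate matrices.
#' @param zones Integer zone-id matrix.
#' @return A tibble with `zone` and one column per covariate.
#' @export
zone_covariate_means <- function(covariates, zones) {
  ids <- sort(unique(as.vector(zones)))
  out <- tibble::tibble(zone = ids)
  for (v in names(covariates)) {
    out[[v]] <- vapply(ids, function(z)
      mean(covariates[[v]][zones == z], na.rm = TRUE), 0)
  }
  out
}

#' Scale fitted edge effects over ecoregion zones
#'
#' For each zone, predicts interior and edge BAI for every forest type
#' group present, at the zone's covariate means, from the fitted gamma GLM;
#' area-weights the predictions by the zone's type composition; and
#' combines the resulting growth difference with the zone's edge-forest
#' fraction into the percent increase in zone-total BAI attributable to
#' edges: `pct = 100 * f * (bai_edge - bai_interior) / bai_interior`, the
#' increase of realized total growth over the all-interior counterfactual.
#' The alternative accounting (difference as a share of the realized
#' total, `100 * f * delta / (f * bai_edge + (1 - f) * bai_interior)`) is
#' available via `denominator = "realized"`.
#'
#' @param fit An `edge_glm` fitted on the matched dataset.
#' @param composition Zone composition from [zone_composition()].
#' @param covariate_means Zone covariate means from
#'   [zone_covariate_means()].
#' @param edge_fractions Zone edge fractions from [zonal_edge_fraction()].
#' @param denominator `"interior"` (default) or `"realized"`.
#' @return A tibble with one row per zone: `zone`, `edge_fraction`,
#'   `bai_interior`, `bai_edge`, `delta_bai`, `pct_increase`.
#' @export
scale_zone_bai <- function(fit, composition, covariate_means,
                           edge_fractions,
                           denominator = c("interior", "realized")) {
  stopifnot(inherits(fit, "edge_glm"))
  denominator <- match.arg(denominator)
  # a fit without a forest-type term predicts identically for every type
  known_types <- fit$fit$xlevels[["forest_type_group"]] %||%
    unique(composition$forest_type_group)
  comp <- composition
  dropped <- setdiff(unique(comp$forest_type_group), known_types)
  if (length(dropped) > 0) {
    warning("forest type(s) absent from the fitted model excluded from ",
            "scaling: ", paste(dropped, collapse = ", "), call. = FALSE)
    comp <- comp |> dplyr::filter(.data$forest_type_group %in% known_types)
  }
  edge_levels <- fit$fit$xlevels[["edge"]]
  covs <- intersect(c("light_limit", "water_limit", "temp_limit", "n_dep"),
                    names(covariate_means))

  per_zone <- comp |>
    dplyr::left_join(covariate_means, by = "zone") |>
    dplyr::group_by(.data$zone) |>
    dplyr::group_modify(function(g, key) {
      w <- g$area_ha / sum(g$area_ha)
      nd <- dplyr::bind_rows(g, g)
      nd$edge <- factor(rep(edge_levels[1:2], each = nrow(g)),
                        levels = edge_levels)
      nd$forest_type_group <- factor(rep(g$forest_type_group, 2),
                                     levels = known_types)
      Terms <- stats::delete.response(stats::terms(fit$fit))
      X <- stats::model.matrix(Terms, nd, xlev = fit$fit$xlevels)
      eta <- drop(X %*% fit$coefficients)
      if (any(eta <= 0)) {
        stop_ef("fit inadmissible at zone covariate means (eta <= 0)")
      }
      mu <- 1 / eta
      n <- nrow(g)
      tibble::tibble(bai_interior = sum(w * mu[seq_len(n)]),
                     bai_edge = sum(w * mu[n + seq_len(n)]))
    }) |>
    dplyr::ungroup()

  out <- per_zone |>
    dplyr::left_join(edge_fractions |>
                       dplyr::select("zone", "edge_fraction"),
                     by = "zone") |>
    dplyr::mutate(
      delta_bai = .data$bai_edge - .data$bai_interior,
      pct_increase = dplyr::case_when(
        is.na(.data$edge_fraction) ~ NA_real_,
        denominator == "interior" ~
          100 * .data$edge_fraction * .data$delta_bai / .data$bai_interior,
        TRUE ~ 100 * .data$edge_fraction * .data$delta_bai /
          (.data$edge_fraction * .data$bai_edge +
             (1 - .data$edge_fraction) * .data$bai_interior)
      )
    )
  out
}
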