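#' Run the edge-effects pipeline end to end
#'
#' Orchestrates the full analysis on a synthetic inventory: generation,
#' edge classification, response computation, the filtering cascade, then
#' for each requested dataset (all edges pooled; anthropogenic edges only)
#' Mahalanobis matching, AIC model selection (or a fixed model), and
#' marginal effects for each requested response, plus the mortality and
#' density/diameter analyses. A run manifest records the configuration
#' hash, seeds and per-stage table digests so identical runs are verifiably
#' identical.
#'
#' @param cfg An [edge_scenario()].
#' @param responses Responses to model: subset of `c("bai", "ba")`.
#' @param datasets Edge definitions: subset of `c("all", "anthropogenic")`.
#' @param select Use AIC model selection (`TRUE`) or fit the full
#'   interaction + covariates model directly.
#' @param inventory Optionally, a pre-generated `edge_inventory` (the
#'   configuration is then only used for analysis settings).
#' @return An object of class `edge_pipeline`: list with the inventory,
#'   the filtered `data`, per-dataset results (`match`, per-response
#'   `fit`/`selection`/`effects`), `mortality`, `density_tests`, and
#'   `manifest`.
#' @export
run_edge_pipeline <- function(cfg, responses = c("bai", "ba"),
                              datasets = c("all", "anthropogenic"),
                              select = FALSE, inventory = NULL) {
  t0 <- Sys.time()
  inv <- inventory %||% generate_inventory(cfg)
  raw <- build_analysis_data(inv)
  data <- filter_dataset(raw)

  resp_col <- c(bai = "bai_m2_ha_yr", ba = "ba_m2_ha")
  treat_of <- list(all = c("edge_anthropogenic", "edge_unknown"),
                   anthropogenic = "edge_anthropogenic")

  results <- purrr::map(datasets, function(ds) {
    m <- match_subplots(data, treat_classes = treat_of[[ds]])
    md <- matched_data(m)
    fits <- purrr::map(responses, function(r) {
      if (select) {
        sel <- select_edge_model(md, response = resp_col[[r]])
        fit <- best_model(sel)
      } else {
        sel <- NULL
        fit <- fit_edge_glm(md, response = resp_col[[r]])
      }
      list(fit = fit, selection = sel, effects = marginal_effects(fit))
    })
    names(fits) <- responses
    list(match = m, fits = fits)
  })
  names(results) <- datasets

  mortality <- mortality_analysis(data, seed = cfg$seed)
  # structural contrasts are made on the matched dataset (pooled-edge match
  # when available), mirroring the quasi-experimental design
  density_data <- if ("all" %in% datasets) {
    matched_data(results[["all"]]$match)
  } else {
    data
  }
  density_tests <- density_diameter_tests(density_data)

  manifest <- tibble::tibble(
    stage = c("config", "inventory_trees", "analysis_data", "filtered_data"),
    digest = c(rlang::hash(unclass(cfg)), rlang::hash(inv$trees),
               rlang::hash(raw), rlang::hash(tibble::as_tibble(data)))
  )
  out <- list(inventory = inv, data = data, results = results,
              mortality = mortality, density_tests = density_tests,
              manifest = list(stages = manifest, seed = cfg$seed,
                              config_hash = rlang::hash(unclass(cfg)),
                              started = t0, finished = Sys.time()))
  class(out) <- "edge_pipeline"
  out
}

#' @export
print.edge_pipeline <- function(x, ...) {
  cat("<edge_pipeline>", nrow(x$data), "analysis subplots after filtering\n")
  for (ds in names(x$results)) {
    for (r in names(x$results[[ds]]$fits)) {
      ov <- overall_effect(x$results[[ds]]$fits[[r]]$effects)
      cat(sprintf("  %s / %s: %+0.1f%% (95%% CI %0.1f to %0.1f)\n",
                  ds, r, ov$pct_diff[1], ov$pct_low[1], ov$pct_high[1]))
    }
  }
  invisible(x)
}

#' Overall percent differences recovered by a pipeline run
#'
#' @param x An `edge_pipeline`.
#' @return A tibble with one row per dataset x response: the overall
#'   percent difference, its CI, and the Wald p.
#' @export
pipeline_effects <- function(x) {
  stopifnot(inherits(x, "edge_pipeline"))
  purrr::imap_dfr(x$results, function(res, ds) {
    purrr::imap_dfr(res$fits, function(f, r) {
      overall_effect(f$effects) |>
        dplyr::mutate(dataset = ds, response = r, .before = 1)
    })
  })
}

#' Write inventory tables to CSV files
#'
#' One file per entity: `plots.csv`, `subplots.csv`, `conditions.csv`,
#' `trees.csv` (plus the generator's `truth.csv`).
#'
#' @param inv An `edge_inventory`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_inventory <- function(inv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("plots", "subplots", "conditions", "trees", "truth")) {
    readr::write_csv(inv[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Read inventory tables from CSV files
#'
#' @param dir Directory holding the entity CSVs written by
#'   [write_inventory()] (or real exports with the same schema).
#' @return An `edge_inventory` (without a config).
#' @export
read_inventory <- function(dir) {
  read1 <- function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) {
      if (nm == "truth") return(NULL)
      stop_ef("missing inventory file: ", p)
    }
    readr::read_csv(p, show_col_types = FALSE)
  }
  out <- list(plots = read1("plots"), subplots = read1("subplots"),
              conditions = read1("conditions"), trees = read1("trees"),
              truth = read1("truth"), config = NULL)
  class(out) <- "edge_inventory"
  out
}

#' @export
print.edge_inventory <- function(x, ...) {
  cat("<edge_inventory>", nrow(x$plots), "plots,", nrow(x$subplots),
      "subplots,", nrow(x$trees), "trees\n")
  invisible(x)
}

#' Covariate balance plot for a matched dataset
#'
#' Standardized mean differences per covariate before and after matching,
#' with the conventional 0.1 threshold marked.
#'
#' @param object An `edge_match`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.edge_match <- function(object, ...) {
  df <- object$balance |>
    tidyr::pivot_longer(c("smd_pre", "smd_post"), names_to = "stage",
                        values_to = "smd") |>
    dplyr::mutate(stage = ifelse(.data$stage == "smd_pre",
                                 "before matching", "after matching"))
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$smd), y = .data$covariate,
                                   colour = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = 2) +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
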