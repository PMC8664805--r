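#' Fit a gamma GLM with inverse link
#'
#' Fits the growth model `y ~ Gamma(mean = 1/eta)` with `eta` the linear
#' predictor, by iteratively reweighted least squares with step-halving
#' (convergence when the relative deviance change falls below 1e-8, at most
#' 100 iterations). The dispersion is estimated by Pearson chi-square over
#' residual degrees of freedom. The null (intercept-only) model is fitted
#' alongside to supply the Nagelkerke pseudo-R-squared.
#'
#' @param data A data frame containing the response and predictors; when it
#'   carries an `edge_class` column but no `edge` factor, a two-level
#'   `edge` factor (interior vs edge) is derived.
#' @param response Name of the strictly positive response column.
#' @param rhs Right-hand-side formula of predictors, e.g.
#'   `~ edge * forest_type_group + light_limit + water_limit + temp_limit +
#'   n_dep`.
#' @return An object of class `edge_glm`: list with the underlying `glm`
#'   fit, coefficient covariance, Pearson `dispersion`, `aic`,
#'   `log_likelihood`, `deviance`, `null_deviance`, `nagelkerke_r2`, `n`,
#'   and the model frame metadata needed for marginal effects.
#' @export
fit_edge_glm <- function(data, response = "bai_m2_ha_yr",
                         rhs = ~ edge * forest_type_group + light_limit +
                           water_limit + temp_limit + n_dep) {
  data <- ensure_edge_factor(data)
  y <- data[[response]]
  if (is.null(y)) stop_ef("response column `", response, "` not found")
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop_ef("gamma response must be strictly positive and finite; ",
            sum(y <= 0), " non-positive value(s) found")
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(deparse(rhs[[2]]), collapse = " ")))
  fit <- tryCatch(
    stats::glm(fml, data = data, family = stats::Gamma(link = "inverse"),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      f <- suppressWarnings(
        stats::glm(fml, data = data, family = stats::Gamma(link = "inverse"),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
      attr(f, "fit_warning") <- conditionMessage(w)
      f
    })
  if (!fit$converged) {
    stop_ef("IRLS did not converge within 100 iterations for `",
            response, "`")
  }
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    stop_ef("rank-deficient design; aliased terms: ",
            paste(names(stats::coef(fit))[aliased], collapse = ", "))
  }
  null_fit <- suppressWarnings(
    stats::glm(stats::as.formula(paste(response, "~ 1")), data = data,
               family = stats::Gamma(link = "inverse"),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  n <- nrow(data)
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null_fit))
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  out <- list(
    fit = fit,
    formula = fml,
    response = response,
    coefficients = stats::coef(fit),
    vcov = stats::summary.glm(fit)$cov.scaled,
    dispersion = disp,
    log_likelihood = ll,
    null_log_likelihood = ll0,
    deviance = stats::deviance(fit),
    null_deviance = fit$null.deviance,
    aic = stats::AIC(fit),
    n = n,
    k = length(stats::coef(fit)) + 1,  # dispersion counted as a parameter
    nagelkerke_r2 = nagelkerke_r2(ll, ll0, n),
    data = data
  )
  class(out) <- "edge_glm"
  out
}

ensure_edge_factor <- function(data) {
  if (!"edge" %in% names(data) && "edge_class" %in% names(data)) {
    data$edge <- factor(ifelse(data$edge_class == "interior", "interior",
                               "edge"), levels = c("interior", "edge"))
  }
  data
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell `R2 = 1 - exp(2 (l0 - l1) / n)` rescaled by its maximum
#' `1 - exp(2 l0 / n)` so that a saturated fit approaches 1.
#'
#' @param ll Log-likelihood of the fitted model (or an `edge_glm`).
#' @param ll0 Log-likelihood of the null model (ignored when `ll` is an
#'   `edge_glm`).
#' @param n Sample size (ignored when `ll` is an `edge_glm`).
#' @return Scalar in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(ll, ll0 = NULL, n = NULL) {
  if (inherits(ll, "edge_glm")) {
    n <- ll$n
    ll0 <- ll$null_log_likelihood
    ll <- ll$log_likelihood
  }
  r2_cs <- 1 - exp(2 * (ll0 - ll) / n)
  denom <- 1 - exp(2 * ll0 / n)
  max(0, min(1, r2_cs / denom))
}

#' Rank candidate gamma GLMs by AIC
#'
#' Fits the nested candidate set (null; edge; edge + type; edge x type;
#' edge x type + abiotic covariates, or a user-supplied list of RHS
#' formulas) and ranks by AIC; near-ties (delta AIC < 2) are resolved in
#' favor of parsimony (fewer parameters), then lower residual deviance, so
#' an elaboration must improve AIC by a full margin to displace a simpler
#' model. Candidates that fail to fit are retained with the error message.
#'
#' @param data Matched analysis dataset.
#' @param response Response column name.
#' @param candidates Named list of RHS formulas; `NULL` for the default
#'   roster.
#' @return An object of class `edge_model_selection`: tibble with columns
#'   `model`, `k`, `aic`, `delta_aic`, `deviance`, `nagelkerke_r2`, `rank`,
#'   `error`, with the fitted `edge_glm` objects in the `"fits"` attribute.
#' @export
select_edge_model <- function(data, response = "bai_m2_ha_yr",
                              candidates = NULL) {
  if (is.null(candidates)) {
    candidates <- list(
      null = ~ 1,
      edge = ~ edge,
      edge_type = ~ edge + forest_type_group,
      edge_x_type = ~ edge * forest_type_group,
      edge_x_type_covariates = ~ edge * forest_type_group + light_limit +
        water_limit + temp_limit + n_dep
    )
  }
  fits <- purrr::map(candidates, function(rhs) {
    tryCatch(fit_edge_glm(data, response, rhs), error = function(e) e)
  })
  tab <- purrr::imap_dfr(fits, function(f, nm) {
    if (inherits(f, "error")) {
      tibble::tibble(model = nm, k = NA_real_, aic = NA_real_,
                     deviance = NA_real_, nagelkerke_r2 = NA_real_,
                     error = conditionMessage(f))
    } else {
      tibble::tibble(model = nm, k = f$k, aic = f$aic, deviance = f$deviance,
                     nagelkerke_r2 = f$nagelkerke_r2, error = NA_character_)
    }
  })
  ok <- !is.na(tab$aic)
  ranked <- tab[ok, ][order(tab$aic[ok]), ]
  # near-tie resolution (delta AIC < 2): parsimony first (fewer
  # parameters), then lower residual deviance — so a nested elaboration
  # must beat the simpler model by a full AIC margin to displace it;
  # bubble passes on the small candidate roster
  if (nrow(ranked) > 1) {
    repeat {
      swapped <- FALSE
      for (i in seq_len(nrow(ranked) - 1)) {
        j <- i + 1
        tied <- abs(ranked$aic[j] - ranked$aic[i]) < 2
        better <- tied && (ranked$k[j] < ranked$k[i] ||
          (ranked$k[j] == ranked$k[i] &&
             ranked$deviance[j] < ranked$deviance[i]))
        if (better) {
          tmp <- ranked[i, ]; ranked[i, ] <- ranked[j, ]; ranked[j, ] <- tmp
          swapped <- TRUE
        }
      }
      if (!swapped) break
    }
  }
  ranked$delta_aic <- ranked$aic - min(ranked$aic)
  ranked$rank <- seq_len(nrow(ranked))
  out <- dplyr::bind_rows(ranked, tab[!ok, ])
  attr(out, "fits") <- fits
  class(out) <- c("edge_model_selection", class(out))
  out
}

#' Best model from a selection table
#'
#' @param sel An `edge_model_selection`.
#' @return The top-ranked `edge_glm`.
#' @export
best_model <- function(sel) {
  stopifnot(inherits(sel, "edge_model_selection"))
  attr(sel, "fits")[[sel$model[1]]]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficient table of a gamma edge GLM
#'
#' @param x An `edge_glm`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @exportS3Method generics::tidy
tidy.edge_glm <- function(x, ...) {
  s <- stats::summary.glm(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' One-row model summary of a gamma edge GLM
#'
#' @param x An `edge_glm`.
#' @param ... Unused.
#' @return A tibble with fit statistics (AIC, deviance, pseudo-R-squared,
#'   dispersion, sample size).
#' @exportS3Method generics::glance
glance.edge_glm <- function(x, ...) {
  tibble::tibble(aic = x$aic, log_likelihood = x$log_likelihood,
                 deviance = x$deviance, null_deviance = x$null_deviance,
                 nagelkerke_r2 = x$nagelkerke_r2, dispersion = x$dispersion,
                 k = x$k, n = x$n)
}

#' @export
print.edge_glm <- function(x, ...) {
  cat("<edge_glm>", x$response, "~",
      paste(deparse(x$formula[[3]]), collapse = ""), "\n")
  cat("  n =", x$n, " AIC =", round(x$aic, 1),
      " Nagelkerke R2 =", round(x$nagelkerke_r2, 3),
      " dispersion =", signif(x$dispersion, 3), "\n")
  invisible(x)
}

#' Write a model summary as JSON
#'
#' @param x An `edge_glm`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(x, path) {
  jsonlite::write_json(
    list(response = x$response,
         formula = paste(deparse(x$formula), collapse = ""),
         coefficients = as.list(x$coefficients),
         std_errors = as.list(sqrt(diag(x$vcov))),
         aic = x$aic, nagelkerke_r2 = x$nagelkerke_r2,
         deviance = x$deviance, dispersion = x$dispersion, n = x$n),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
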