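#' Mahalanobis distance between covariate vectors
#'
#' `sqrt((x - y)' S^-1 (x - y))` with a Moore-Penrose pseudo-inverse when
#' the covariance matrix is singular.
#'
#' @param x,y Numeric covariate vectors of equal length.
#' @param S Covariance matrix (symmetric positive semi-definite).
#' @return Non-negative scalar distance.
#' @export
mahalanobis_dist <- function(x, y, S) {
  if (length(x) != length(y) || length(x) != nrow(S) || nrow(S) != ncol(S)) {
    stop_ef("dimension mismatch between covariate vectors and covariance")
  }
  d <- x - y
  Sinv <- tryCatch(solve(S), error = function(e) MASS::ginv(S))
  sqrt(max(drop(t(d) %*% Sinv %*% d), 0))
}

# covariance -> whitening transform W with W W' = S^-1, so Euclidean
# distance on Z = X W equals Mahalanobis distance
whitening_transform <- function(S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(R)) return(solve(R))
  # PSD fallback through the eigendecomposition of the pseudo-inverse
  e <- eigen(MASS::ginv(S), symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(e$values)) %*%
    t(e$vectors)
}

#' Match interior control subplots to edge subplots
#'
#' Greedy 1:1 nearest-neighbor matching without replacement on Mahalanobis
#' distance over the continuous covariates, exact within forest type group.
#' Treated units are processed in dataset order; among equidistant controls
#' the lowest `subplot_id` is chosen. The covariance used for the distance
#' is estimated from the pooled (treated + control) sample. Unmatched
#' controls are excluded from downstream analysis.
#'
#' @param data Filtered analysis dataset (from [filter_dataset()]).
#' @param treat_classes Edge classes forming the treated group, e.g.
#'   `c("edge_anthropogenic")` or both edge classes pooled.
#' @param covariates Names of the continuous matching covariates.
#' @param exact Categorical column matched exactly (stratification).
#' @return An object of class `edge_match`: list with `pairs` (tibble of
#'   `treated_id`, `control_id`, stratum, distance), `balance` (pre/post
#'   standardized mean differences per covariate, see [balance_table()]),
#'   `covariance`, `strata` counts, and the input `data`.
#' @export
match_subplots <- function(data,
                           treat_classes = c("edge_anthropogenic",
                                             "edge_unknown"),
                           covariates = c("light_limit", "water_limit",
                                          "temp_limit", "n_dep"),
                           exact = "forest_type_group") {
  assert_columns(data, c("subplot_id", "edge_class", exact, covariates))
  keep <- data$edge_class == "interior" | data$edge_class %in% treat_classes
  d <- data[keep, ]
  treated <- d$edge_class %in% treat_classes
  if (!any(treated)) stop_ef("no treated (edge) subplots in the dataset")
  if (!any(!treated)) stop_ef("no interior control subplots in the dataset")

  X <- as.matrix(d[, covariates])
  S <- stats::cov(X)
  W <- whitening_transform(S)
  Z <- X %*% W

  strata <- split(seq_len(nrow(d)), d[[exact]])
  counts <- lapply(strata, function(i) {
    c(treated = sum(treated[i]), control = sum(!treated[i]))
  })
  short <- names(counts)[vapply(counts, function(x)
    x["treated"] > x["control"], logical(1))]
  if (length(short) > 0) {
    stop_ef("insufficient interior controls in stratum(s): ",
            paste(short, collapse = ", "))
  }

  pairs <- purrr::map_dfr(names(strata), function(st) {
    i <- strata[[st]]
    ti <- i[treated[i]]
    ci <- i[!treated[i]]
    if (length(ti) == 0) return(NULL)
    # dataset order for treated, lowest-id tie-break for controls
    d2 <- outer(rowSums(Z[ti, , drop = FALSE]^2), numeric(length(ci)), "+") +
      rep(rowSums(Z[ci, , drop = FALSE]^2), each = length(ti)) -
      2 * Z[ti, , drop = FALSE] %*% t(Z[ci, , drop = FALSE])
    ord <- order(d$subplot_id[ci])
    avail <- rep(TRUE, length(ci))
    sel <- integer(length(ti))
    dist_sel <- numeric(length(ti))
    for (t_k in seq_along(ti)) {
      drow <- d2[t_k, ]
      drow[!avail] <- Inf
      dmin <- min(drow)
      cand <- which(drow <= dmin + 1e-12 * max(dmin, 1))
      pick <- cand[which.min(d$subplot_id[ci][cand])]
      sel[t_k] <- pick
      dist_sel[t_k] <- sqrt(max(dmin, 0))
      avail[pick] <- FALSE
    }
    tibble::tibble(treated_id = d$subplot_id[ti],
                   control_id = d$subplot_id[ci][sel],
                   stratum = st, distance = dist_sel)
  })

  m <- structure(
    list(pairs = pairs, covariance = S, covariates = covariates,
         exact = exact, treat_classes = treat_classes,
         strata = tibble::tibble(
           stratum = names(counts),
           n_treated = vapply(counts, `[[`, 0, "treated"),
           n_control = vapply(counts, `[[`, 0, "control")),
         data = d),
    class = "edge_match")
  m$balance <- balance_table(m)
  m
}

#' Matched analysis dataset
#'
#' Stacks the treated subplots and their matched controls, dropping
#' unmatched interior subplots, and adds a pooled `edge` factor
#' (interior/edge) used by the regression stage.
#'
#' @param m An `edge_match`.
#' @return A tibble of matched records.
#' @export
matched_data <- function(m) {
  stopifnot(inherits(m, "edge_match"))
  keep <- c(m$pairs$treated_id, m$pairs$control_id)
  m$data |>
    dplyr::filter(.data$subplot_id %in% keep) |>
    dplyr::mutate(edge = factor(
      ifelse(.data$edge_class == "interior", "interior", "edge"),
      levels = c("interior", "edge")))
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences, `SMD = (mean_treated - mean_control) /
#' pooled SD`, for every matching covariate, before matching (all treated
#' vs all controls) and after (treated vs matched controls). `|SMD| > 0.1`
#' is flagged. A zero pooled SD yields SMD 0 when the means agree and
#' `Inf` otherwise.
#'
#' @param m An `edge_match`.
#' @return A tibble with columns `covariate`, `smd_pre`, `smd_post`,
#'   `flag_pre`, `flag_post`.
#' @export
balance_table <- function(m) {
  stopifnot(inherits(m, "edge_match"))
  d <- m$data
  treated <- d$edge_class %in% m$treat_classes
  ctrl_matched <- d$subplot_id %in% m$pairs$control_id
  smd <- function(x_t, x_c) {
    s <- sqrt((stats::var(x_t) + stats::var(x_c)) / 2)
    dm <- mean(x_t) - mean(x_c)
    if (!is.finite(s) || s == 0) return(if (dm == 0) 0 else Inf)
    dm / s
  }
  purrr::map_dfr(m$covariates, function(v) {
    tibble::tibble(
      covariate = v,
      smd_pre = smd(d[[v]][treated], d[[v]][!treated]),
      smd_post = smd(d[[v]][treated], d[[v]][ctrl_matched])
    )
  }) |>
    dplyr::mutate(flag_pre = abs(.data$smd_pre) > 0.1,
                  flag_post = abs(.data$smd_post) > 0.1)
}

#' @export
print.edge_match <- function(x, ...) {
  cat("<edge_match>", nrow(x$pairs), "pairs across",
      nrow(x$strata), "forest-type strata\n")
  cat("  treated classes:", paste(x$treat_classes, collapse = ", "), "\n")
  worst <- max(abs(x$balance$smd_post))
  cat("  max |SMD| after matching:", signif(worst, 3), "\n")
  invisible(x)
}

#' Write matched pairs and balance to CSV, run metadata to JSON
#'
#' @param m An `edge_match`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_match <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(m$pairs, file.path(dir, "pairs.csv"))
  readr::write_csv(m$balance, file.path(dir, "balance.csv"))
  jsonlite::write_json(
    list(covariates = m$covariates, exact = m$exact,
         treat_classes = m$treat_classes, strata = m$strata),
    file.path(dir, "match_meta.json"), digits = NA)
  invisible(dir)
}
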