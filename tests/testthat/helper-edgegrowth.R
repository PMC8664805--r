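# shared fixtures: a small generated inventory reused across test files
small_scenario <- function(seed = 101, n_plots = 500, ...) {
  edge_scenario(n_plots = n_plots, seed = seed, edge_fraction = 0.3, ...)
}

local_inventory <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_inventory(small_scenario())
    cache
  }
})

local_filtered <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- filter_dataset(build_analysis_data(local_inventory()))
    }
    cache
  }
})

# brute-force queen's-rule edge detector: double loop over all pixels
brute_force_edges <- function(forest, target = NULL) {
  nr <- nrow(forest); nc <- ncol(forest)
  if (is.null(target)) target <- !forest
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!forest[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (target[ii, jj]) out[i, j] <- TRUE
      }
    }
  }
  out
}

# sequential nearest-neighbor matching oracle using stats::mahalanobis
# directly: treated in input order, lowest-id tie-break, no replacement
oracle_match <- function(X_t, X_c, ids_c, S) {
  avail <- rep(TRUE, nrow(X_c))
  out <- integer(nrow(X_t))
  for (i in seq_len(nrow(X_t))) {
    d <- rep(Inf, nrow(X_c))
    d[avail] <- stats::mahalanobis(X_c[avail, , drop = FALSE],
                                   center = as.numeric(X_t[i, ]), cov = S)
    dmin <- min(d)
    cand <- which(d <= dmin + 1e-12 * max(dmin, 1))
    out[i] <- cand[which.min(ids_c[cand])]
    avail[out[i]] <- FALSE
  }
  out
}

# direct BFGS maximizer of the gamma log-likelihood kernel under the
# inverse link (beta only; independent of the IRLS path)
oracle_gamma_fit <- function(X, y, beta0 = NULL) {
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    if (any(eta <= 0)) return(1e10)
    sum(log(1 / eta) + y * eta)   # -sum(log mu^-1... kernel up to constants
  }
  grad <- function(beta) {
    eta <- drop(X %*% beta)
    if (any(eta <= 0)) return(rep(0, length(beta)))
    drop(t(X) %*% (y - 1 / eta))
  }
  if (is.null(beta0)) {
    beta0 <- c(1 / mean(y), rep(0, ncol(X) - 1))
  }
  opt <- stats::optim(beta0, negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  opt$par
}

# gamma log-likelihood kernel (shape-free part that the MLE of beta
# maximizes): sum(log eta - y * eta)
gamma_kernel <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(log(eta) - y * eta)
}
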