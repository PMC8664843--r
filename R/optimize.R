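#' Build the filter-optimization objective
#'
#' Returns a function `f(M, N)` giving the mean k-fold CV F1-score of one
#' classifier family on features rebuilt from scratch (band-pass, artifact
#' mask with RMS window `M`, `N`-second chunks, beat detection, annotation,
#' feature extraction) from the supplied recordings. Only training
#' recordings should be passed in: the held-out test set must never reach
#' the objective. Probe points where the chain yields no usable samples or a
#' single class score 0.
#'
#' @param cohort List of training [recording()]s (or `(recording, truth)`
#'   pairs).
#' @param family Classifier family (default `"xgb"`).
#' @param level `"chunk"` or `"subject"`.
#' @param task `"binary"` or `"severity"`.
#' @param params Fixed classifier hyperparameters used at every probe
#'   (re-tuning inside the optimizer would multiply its cost).
#' @param folds CV folds (default `config$cv_folds`).
#' @param seed Integer seed for the CV fold assignment.
#' @param config A [cm_config()].
#' @return A memoizing function of `(M, N)`.
#' @export
filter_objective <- function(cohort, family = "xgb", level = "chunk",
                             task = "binary",
                             params = list(max_depth = 4, eta = 0.3,
                                           nrounds = 60,
                                           class_weight = "balanced"),
                             folds = NULL, seed = 1L, config = cm_config()) {
  config <- as_cm_config(config)
  if (is.null(folds)) folds <- config$cv_folds
  cache <- new.env(parent = emptyenv())
  function(M, N) {
    key <- sprintf("%.1f|%.2f", M, N)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch({
      fm <- extract_cohort_features(cohort, level = level, M = M, N = N,
                                    config = config)
      y <- droplevels(task_labels(fm, task))
      if (nlevels(y) < 2) 0 else {
        suppressWarnings(
          cv_f1(feature_values(fm), y, fm$sample_id, family, params, folds,
                seed)
        )
      }
    }, error = function(e) 0)
    cache[[key]] <- val
    val
  }
}

matern52_kernel <- function(X1, X2, ell) {
  D <- 0
  for (d in seq_len(ncol(X1))) {
    D <- D + (outer(X1[, d], X2[, d], "-") / ell[d])^2
  }
  r <- sqrt(5 * pmax(D, 0))
  (1 + r + r^2 / 3) * exp(-r)
}

gp_posterior <- function(X, y, Xs, ell = c(0.3, 0.3), noise = 1e-6) {
  mu0 <- mean(y)
  sf2 <- max(var(y), 1e-10)
  K <- sf2 * matern52_kernel(X, X, ell) + diag(noise + 1e-8, nrow(X))
  Ks <- sf2 * matern52_kernel(Xs, X, ell)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y - mu0))
  mu <- mu0 + Ks %*% alpha
  v <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(sf2 - colSums(v^2), 1e-12)
  list(mu = as.numeric(mu), sd = sqrt(s2))
}

expected_improvement <- function(mu, sd, best) {
  z <- (mu - best) / sd
  (mu - best) * pnorm(z) + sd * dnorm(z)
}

#' Jointly optimize the RMS window and chunk length by Bayesian optimization
#'
#' Maximizes `F1(M, N)` over the box `M` in `[100, 2000]` ms, `N` in
#' `[2, 25]` s with a Gaussian-process surrogate (Matern-5/2 kernel on the
#' unit-scaled box) and expected-improvement acquisition over a random
#' candidate pool, starting from a Latin-hypercube design. The whole run is
#' deterministic under `seed`.
#'
#' @param cohort Training recordings (never the test set) - or pass a ready
#'   `objective` directly.
#' @param family Classifier family for the objective.
#' @param budget Total objective evaluations (including the initial design;
#'   at least 10).
#' @param bounds_m,bounds_n Box constraints (defaults from `config`).
#' @param seed Integer seed.
#' @param objective Optional `f(M, N)` overriding [filter_objective()].
#' @param config A [cm_config()].
#' @param ... Passed to [filter_objective()].
#' @return A `cm_filteropt` list: `M_star` (ms), `N_star` (s), `best_f1`,
#'   `trace` (tibble `M, N, f1` in evaluation order).
#' @export
optimize_filter_params <- function(cohort = NULL, family = "xgb",
                                   budget = NULL, bounds_m = NULL,
                                   bounds_n = NULL, seed = 1L,
                                   objective = NULL, config = cm_config(),
                                   ...) {
  config <- as_cm_config(config)
  if (is.null(budget)) budget <- config$bo_budget
  stopifnot(budget >= 10)
  if (is.null(bounds_m)) bounds_m <- config$m_bounds_ms
  if (is.null(bounds_n)) bounds_n <- config$n_bounds_s
  if (is.null(objective)) {
    stopifnot(!is.null(cohort))
    objective <- filter_objective(cohort, family = family, seed = seed,
                                  config = config, ...)
  }
  set.seed(seed)
  n_init <- min(config$bo_init_points, budget - 2L)
  U <- lhs::randomLHS(n_init, 2)
  unscale <- function(u) {
    cbind(bounds_m[1] + u[, 1] * diff(bounds_m),
          bounds_n[1] + u[, 2] * diff(bounds_n))
  }
  X <- U
  P <- unscale(U)
  y <- vapply(seq_len(nrow(P)), function(i) objective(P[i, 1], P[i, 2]),
              numeric(1))
  while (length(y) < budget) {
    cand <- matrix(runif(2 * config$bo_candidate_pool), ncol = 2)
    post <- gp_posterior(X, y, cand)
    ei <- expected_improvement(post$mu, post$sd, max(y))
    # avoid re-probing: suppress candidates closer than ~1% of the box to an
    # evaluated point
    d2min <- apply(cand, 1, function(u) min(colSums((t(X) - u)^2)))
    ei[d2min < 1e-4] <- -Inf
    u <- cand[which.max(ei), , drop = FALSE]
    p <- unscale(u)
    X <- rbind(X, u)
    P <- rbind(P, p)
    y <- c(y, objective(p[1], p[2]))
  }
  best <- which.max(y)
  structure(
    list(M_star = P[best, 1], N_star = P[best, 2], best_f1 = y[best],
         trace = tibble::tibble(M = P[, 1], N = P[, 2], f1 = y)),
    class = "cm_filteropt"
  )
}

#' @export
print.cm_filteropt <- function(x, ...) {
  cat(sprintf("<cm_filteropt> M* = %.0f ms, N* = %.2f s | best F1 %.4f (%d evaluations)\n",
              x$M_star, x$N_star, x$best_f1, nrow(x$trace)))
  invisible(x)
}

#' Exhaustive sweep of the filter parameters
#'
#' Evaluates the same objective as [optimize_filter_params()] on the full
#' `M_list` x `N_list` grid, from which performance-versus-M curves at fixed
#' N (and vice versa) can be drawn.
#'
#' @param cohort Training recordings (or `objective`).
#' @param family Classifier family.
#' @param M_list,N_list Grid values within the optimization bounds.
#' @param objective Optional ready objective.
#' @param config A [cm_config()].
#' @param ... Passed to [filter_objective()].
#' @return A tibble `M, N, f1` over the grid.
#' @export
sweep_filter_params <- function(cohort = NULL, family = "xgb",
                                M_list = c(100, 500, 1000, 1500, 2000),
                                N_list = c(2, 5, 10, 15, 20),
                                objective = NULL, config = cm_config(), ...) {
  config <- as_cm_config(config)
  if (is.null(objective)) {
    stopifnot(!is.null(cohort))
    objective <- filter_objective(cohort, family = family, config = config,
                                  ...)
  }
  grid <- expand.grid(M = M_list, N = N_list)
  grid$f1 <- vapply(seq_len(nrow(grid)),
                    function(i) objective(grid$M[i], grid$N[i]), numeric(1))
  tibble::as_tibble(grid)
}
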