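#' Exact Shapley scores by full subset enumeration
#'
#' Computes, for every feature i, the Shapley value
#' `alpha_i = sum over subsets g not containing i of
#' |g|! (n - |g| - 1)! / n! * (v(g + i) - v(g))`,
#' by enumerating all `2^n` subsets with a memoized value function. The
#' efficiency identity `sum(alpha) = v(full set) - v(empty set)` holds to
#' numerical precision, as do the symmetry and dummy axioms.
#'
#' @param value_fn Function mapping a character vector of feature names (a
#'   subset, possibly empty) to a scalar value (e.g. a CV F1-score).
#' @param features Character vector of feature names (at most 15; the `2^n`
#'   enumeration is guarded).
#' @return A `cm_shapley` list: `scores` (named numeric), `mode = "exact"`,
#'   `v_full`, `v_empty`.
#' @examples
#' v <- function(s) sum(c(a = 0.2, b = 0.5)[s])
#' shapley_exact(v, c("a", "b"))$scores
#' @export
shapley_exact <- function(value_fn, features) {
  n <- length(features)
  stopifnot(n >= 1)
  if (n > 15) stop("exact enumeration guarded at 15 features; use shapley_sampled()",
                   call. = FALSE)
  nsub <- bitwShiftL(1L, n)
  v <- numeric(nsub)
  for (m in 0:(nsub - 1L)) {
    subset <- features[bitwAnd(bitwShiftR(m, seq_len(n) - 1L), 1L) == 1L]
    val <- value_fn(subset)
    if (!is.finite(val)) {
      stop("value function failed on subset {",
           paste(subset, collapse = ", "), "}", call. = FALSE)
    }
    v[m + 1L] <- val
  }
  # weight by subset size: s! (n - s - 1)! / n!
  wt <- exp(lfactorial(0:(n - 1)) + lfactorial(n - 1 - (0:(n - 1))) -
              lfactorial(n))
  sizes <- vapply(0:(nsub - 1L), function(m) sum(bitwAnd(
    bitwShiftR(m, seq_len(n) - 1L), 1L)), numeric(1))
  scores <- numeric(n)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(nsub - 1L), bit) == 0L) - 1L
    scores[i] <- sum(wt[sizes[without + 1L] + 1L] *
                       (v[without + bit + 1L] - v[without + 1L]))
  }
  structure(
    list(scores = setNames(scores, features), mode = "exact",
         v_full = v[nsub], v_empty = v[1]),
    class = "cm_shapley"
  )
}

#' Shapley scores by permutation sampling
#'
#' Monte-Carlo estimator of the exact enumeration: for each sampled
#' permutation of the features, every feature's marginal contribution on
#' joining its predecessors is recorded; the per-feature mean estimates the
#' Shapley value and the standard error of that mean is reported.
#'
#' @param value_fn As in [shapley_exact()].
#' @param features Character vector of feature names.
#' @param n_permutations Number of sampled permutations (at least 50).
#' @param seed Integer seed (estimates are deterministic under it).
#' @return A `cm_shapley` list with `scores`, `se` (per-feature Monte-Carlo
#'   standard errors), `mode = "sampled"`, `n_permutations`, `v_full`,
#'   `v_empty`.
#' @export
shapley_sampled <- function(value_fn, features, n_permutations = 200,
                            seed = 1L) {
  n <- length(features)
  stopifnot(n >= 1, n_permutations >= 50)
  set.seed(seed)
  cache <- new.env(parent = emptyenv())
  v <- function(subset) {
    key <- paste0("s:", paste(sort(subset), collapse = "|"))
    if (is.null(cache[[key]])) cache[[key]] <- value_fn(subset)
    cache[[key]]
  }
  contrib <- matrix(NA_real_, n_permutations, n,
                    dimnames = list(NULL, features))
  for (p in seq_len(n_permutations)) {
    perm <- sample(features)
    prev <- v(character())
    for (k in seq_len(n)) {
      cur <- v(perm[seq_len(k)])
      contrib[p, perm[k]] <- cur - prev
      prev <- cur
    }
  }
  structure(
    list(scores = colMeans(contrib),
         se = apply(contrib, 2, sd) / sqrt(n_permutations),
         mode = "sampled", n_permutations = n_permutations, seed = seed,
         v_full = v(features), v_empty = v(character())),
    class = "cm_shapley"
  )
}

#' @export
print.cm_shapley <- function(x, ...) {
  cat(sprintf("<cm_shapley> %s | %d features | sum(scores) = %.4f\n",
              x$mode, length(x$scores), sum(x$scores)))
  invisible(x)
}

#' Cross-validated F1 value function over feature subsets
#'
#' Returns the set function used for Shapley attribution: a subset of
#' features maps to the mean k-fold CV F1-score of the family retrained on
#' those columns of the training matrix, with the hyperparameters fixed once
#' (re-tuning inside the `2^n` subsets would be computationally
#' indefensible). The empty subset maps to 0 by convention, so efficiency
#' reads `sum(alpha) = F1(full set)`.
#'
#' @param train Training [feature_matrix()].
#' @param family Classifier family.
#' @param task `"binary"` or `"severity"`.
#' @param params Fixed hyperparameters (default: light boosted-tree
#'   settings).
#' @param folds CV folds.
#' @param seed Integer seed for fold assignment.
#' @return Function: character subset -> mean CV F1 in `[0, 1]`.
#' @export
f1_value_fn <- function(train, family = "xgb", task = "binary",
                        params = list(max_depth = 3, eta = 0.3, nrounds = 40,
                                      class_weight = "balanced"),
                        folds = 5, seed = 1L) {
  stopifnot(nrow(train) > 0)
  x <- feature_values(train)
  y <- droplevels(task_labels(train, task))
  groups <- train$sample_id
  function(subset) {
    subset <- intersect(subset, colnames(x))
    if (!length(subset)) return(0)
    suppressWarnings(
      cv_f1(x[, subset, drop = FALSE], y, groups, family, params, folds, seed)
    )
  }
}

#' Compare top-k features between two importance criteria
#'
#' Ranks features by absolute score under both criteria (e.g. Shapley values
#' versus a classifier's native gain importance) and reports the top-k lists
#' and their overlap.
#'
#' @param shap A `cm_shapley` (or named numeric vector).
#' @param importance Named numeric vector over the same feature set.
#' @param k Top-list size (clamped to the number of features).
#' @return A list: `top_shapley`, `top_importance` (character vectors),
#'   `intersection`, `overlap_fraction`, `k`.
#' @export
rank_and_compare <- function(shap, importance, k = 20) {
  s <- if (inherits(shap, "cm_shapley")) shap$scores else shap
  stopifnot(setequal(names(s), names(importance)))
  k <- min(k, length(s))
  top_s <- names(sort(abs(s), decreasing = TRUE))[seq_len(k)]
  top_i <- names(sort(abs(importance), decreasing = TRUE))[seq_len(k)]
  inter <- intersect(top_s, top_i)
  list(top_shapley = top_s, top_importance = top_i, intersection = inter,
       overlap_fraction = length(inter) / k, k = k)
}
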