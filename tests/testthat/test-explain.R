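rand_value_fn <- function(features, seed) {
  # a reproducible arbitrary set function
  force(features)
  function(subset) {
    if (!length(subset)) return(0)
    key <- sum(2^(match(sort(subset), features) - 1))
    set.seed(seed * 131071 + key)
    runif(1)
  }
}

test_that("two-feature game gives the closed-form attribution", {
  v <- function(s) {
    key <- paste(sort(s), collapse = "")
    c("0" = 0, "f1" = 0.6, "f2" = 0.2, "f1f2" = 1.0)[[if (key == "") "0" else key]]
  }
  sh <- shapley_exact(v, c("f1", "f2"))
  expect_equal(unname(sh$scores), c(0.7, 0.3), tolerance = 1e-12)
  expect_equal(sum(sh$scores), sh$v_full - sh$v_empty, tolerance = 1e-12)
})

test_that("additivity and dummy axioms hold exactly", {
  w <- c(a = 0.4, b = -0.1, c = 0.25)
  v_add <- function(s) sum(w[s])
  sh <- shapley_exact(v_add, names(w))
  expect_equal(sh$scores, w, tolerance = 1e-12)

  v_dummy <- function(s) as.numeric("a" %in% s) * 0.8
  sh2 <- shapley_exact(v_dummy, c("a", "b", "c"))
  expect_equal(unname(sh2$scores), c(0.8, 0, 0), tolerance = 1e-12)
})

test_that("efficiency and symmetry hold on random value functions", {
  for (seed in 1:3) {
    feats <- paste0("f", 1:8)
    v <- rand_value_fn(feats, seed)
    sh <- shapley_exact(v, feats)
    expect_equal(sum(sh$scores), v(feats) - v(character()), tolerance = 1e-9)
  }
  # exchangeable features receive equal scores
  v_sym <- function(s) length(intersect(s, c("x", "y")))^2 + 0.5 * ("z" %in% s)
  sh <- shapley_exact(v_sym, c("x", "y", "z"))
  expect_equal(sh$scores[["x"]], sh$scores[["y"]], tolerance = 1e-12)
})

test_that("enumeration guard and failure reporting are informative", {
  expect_error(shapley_exact(function(s) 0, paste0("f", 1:16)), "15")
  v_bad <- function(s) if (setequal(s, c("a", "b"))) NA_real_ else 0
  expect_error(shapley_exact(v_bad, c("a", "b", "c")), "a, b")
})

test_that("sampled estimator agrees with exact within 3 standard errors", {
  feats <- paste0("f", 1:8)
  v <- rand_value_fn(feats, 4)
  ex <- shapley_exact(v, feats)
  sm <- shapley_sampled(v, feats, n_permutations = 400, seed = 2)
  expect_true(all(abs(sm$scores - ex$scores) <= 3 * pmax(sm$se, 1e-12)))
  expect_equal(sum(sm$scores), sm$v_full - sm$v_empty,
               tolerance = 3 * sum(sm$se) + 1e-12)
  sm2 <- shapley_sampled(v, feats, n_permutations = 400, seed = 2)
  expect_identical(sm$scores, sm2$scores)
})

test_that("Monte-Carlo error shrinks like one over root permutations", {
  feats <- paste0("f", 1:6)
  v <- rand_value_fn(feats, 9)
  se1 <- mean(shapley_sampled(v, feats, 200, seed = 3)$se)
  se2 <- mean(shapley_sampled(v, feats, 800, seed = 3)$se)
  expect_equal(se2 / se1, 0.5, tolerance = 0.2)
})

test_that("the CV-F1 value function is anchored at zero and at full-set F1", {
  fm <- fx_separable_fm(n_per_class = 15, p = 3)
  vf <- f1_value_fn(fm, family = "dt",
                    params = list(maxdepth = 3, minbucket = 1, minsplit = 2,
                                  class_weight = "none"),
                    folds = 3, seed = 5)
  expect_equal(vf(character()), 0)
  full <- vf(c("f1", "f2", "f3"))
  expect_gt(full, 0.9) # separable cohort
  expect_equal(vf(c("f3", "f2", "f1")), full) # order-invariant
})

test_that("a duplicated informative feature shares its credit", {
  fm <- fx_separable_fm(n_per_class = 15, p = 3)
  dup <- fm
  dup$f2 <- fm$f1 # exact copy of the informative column
  vf_dup <- f1_value_fn(dup, family = "dt",
                        params = list(maxdepth = 3, minbucket = 1,
                                      minsplit = 2, class_weight = "none"),
                        folds = 3, seed = 5)
  sh_dup <- shapley_exact(vf_dup, c("f1", "f2", "f3"))
  vf_single <- f1_value_fn(fm[, c("sample_id", "label", "f1", "f3")],
                           family = "dt",
                           params = list(maxdepth = 3, minbucket = 1,
                                         minsplit = 2, class_weight = "none"),
                           folds = 3, seed = 5)
  sh_single <- shapley_exact(vf_single, c("f1", "f3"))
  expect_lt(sh_dup$scores[["f1"]], sh_single$scores[["f1"]])
  expect_lt(sh_dup$scores[["f2"]], sh_single$scores[["f1"]])
  expect_equal(sh_dup$scores[["f1"]], sh_dup$scores[["f2"]],
               tolerance = 1e-9) # symmetry of the two copies
})

test_that("top-k comparison reports overlap fractions correctly", {
  s <- c(a = 3, b = -2, c = 1, d = 0.5)
  expect_equal(rank_and_compare(s, s, k = 2)$overlap_fraction, 1)
  rev_imp <- c(a = 0.5, b = 1, c = 2, d = 3)
  expect_equal(rank_and_compare(s, rev_imp, k = 4)$overlap_fraction, 1)
  expect_equal(rank_and_compare(s, rev_imp, k = 2)$overlap_fraction, 0)
  expect_equal(rank_and_compare(s, s, k = 99)$k, 4) # clamped
})

test_that("planted informative features surface in both rankings", {
  set.seed(12)
  n <- 60
  p <- 8
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  lab <- rep(c("healthy", "severe"), each = n / 2)
  for (j in 1:3) x[, j] <- x[, j] + ifelse(lab == "severe", 2.5, 0)
  fm <- feature_matrix(tibble::as_tibble(x),
                       sample_ids = sprintf("s%02d", 1:n), labels = lab)
  params <- list(max_depth = 3, eta = 0.3, nrounds = 30,
                 class_weight = "none")
  vf <- f1_value_fn(fm, family = "xgb", params = params, folds = 3, seed = 1)
  sh <- shapley_sampled(vf, paste0("f", 1:p), n_permutations = 60, seed = 4)
  fit <- cardiomech:::cm_fit("xgb", feature_values(fm),
                             cardiomech:::binary_labels(fm$label), params)
  imp <- feature_importance(fit)
  cmp <- rank_and_compare(sh, imp, k = 5)
  for (f in c("f1", "f2", "f3")) {
    expect_true(f %in% cmp$top_shapley)
    expect_true(f %in% cmp$top_importance)
  }
})
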