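fab_fm <- function(n_subjects, chunks_per_subject = 1, p = 3, seed = 1,
                   labels = rep(c("healthy", "severe"),
                                length.out = n_subjects)) {
  set.seed(seed)
  subj <- rep(sprintf("S%02d", seq_len(n_subjects)), each = chunks_per_subject)
  n <- length(subj)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  feature_matrix(tibble::as_tibble(x),
                 sample_ids = sprintf("%s_c%d", subj,
                                      seq_len(chunks_per_subject)),
                 labels = rep(labels, each = chunks_per_subject),
                 subject_ids = subj)
}

test_that("subject-level split is stratified 80/20 and seeded", {
  fm <- fab_fm(45, labels = c(rep("healthy", 13), rep("mild", 11),
                              rep("moderate", 12), rep("severe", 9)))
  sp <- split_dataset(fm, "subject", seed = 4)
  expect_equal(length(sp$test_ids), 9)
  expect_equal(length(sp$train_ids), 36)
  expect_identical(sp, split_dataset(fm, "subject", seed = 4))
  # every class appears on both sides
  for (ids in list(sp$train_ids, sp$test_ids)) {
    labs <- fm$label[match(ids, fm$sample_id)]
    expect_setequal(unique(labs), unique(fm$label))
  }
})

test_that("chunk-level split never separates a subject's chunks", {
  fm <- fab_fm(12, chunks_per_subject = 8)
  sp <- split_dataset(fm, "chunk", seed = 2)
  subj <- attr(fm, "subject_ids")
  tr_subj <- subj[match(sp$train_ids, fm$sample_id)]
  te_subj <- subj[match(sp$test_ids, fm$sample_id)]
  expect_length(intersect(tr_subj, te_subj), 0)
  frac <- length(sp$test_ids) / nrow(fm)
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.35)
})

test_that("classification metrics match hand-counted confusion cells", {
  truth <- factor(c(rep("AS", 4), rep("healthy", 6)),
                  levels = c("healthy", "AS"))
  pred <- factor(c("AS", "AS", "AS", "healthy", # TP = 3, FN = 1
                   "AS", rep("healthy", 5)),     # FP = 1, TN = 5
                 levels = c("healthy", "AS"))
  m <- classification_metrics(truth, pred)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)

  perfect <- classification_metrics(truth, truth)
  expect_equal(unlist(perfect[c("precision", "recall", "accuracy", "f1")]),
               c(precision = 1, recall = 1, accuracy = 1, f1 = 1))

  all_one <- factor(rep("AS", 10), levels = c("healthy", "AS"))
  balanced <- factor(rep(c("healthy", "AS"), 5), levels = c("healthy", "AS"))
  m1 <- classification_metrics(balanced, all_one)
  expect_equal(m1$accuracy, 0.5)
  expect_equal(m1$recall, 1)
})

test_that("macro multi-class metrics agree with per-class brute force", {
  set.seed(6)
  lev <- c("healthy", "mild", "moderate", "severe")
  truth <- factor(sample(lev, 60, replace = TRUE), levels = lev)
  pred <- factor(sample(lev, 60, replace = TRUE), levels = lev)
  m <- classification_metrics(truth, pred)
  prs <- res <- numeric(4)
  for (i in seq_along(lev)) {
    tp <- sum(truth == lev[i] & pred == lev[i])
    prs[i] <- ifelse(sum(pred == lev[i]) > 0, tp / sum(pred == lev[i]), 0)
    res[i] <- ifelse(sum(truth == lev[i]) > 0, tp / sum(truth == lev[i]), 0)
  }
  expect_equal(m$precision, mean(prs), tolerance = 1e-12)
  expect_equal(m$recall, mean(res), tolerance = 1e-12)
  expect_equal(m$accuracy, mean(truth == pred), tolerance = 1e-12)
  expect_equal(rowSums(confusion_rates(m)), rep(1, 4), ignore_attr = TRUE)
})

test_that("every family separates an easy cohort perfectly in CV", {
  fm <- fx_separable_fm()
  grids <- list(
    dt = data.frame(maxdepth = 3, minbucket = 1, minsplit = 2,
                    criterion = "gini", class_weight = "balanced"),
    rf = data.frame(max.depth = 0, min.node.size = 1, mtry_frac = 0.8,
                    num.trees = 100, splitrule = "gini",
                    class_weight = "balanced"),
    xgb = data.frame(max_depth = 3, eta = 0.3, nrounds = 30,
                     class_weight = "balanced"),
    svm = data.frame(cost = 1, kernel = "linear", gamma_scale = 1,
                     class_weight = "balanced")
  )
  for (family in names(grids)) {
    mod <- tune_classifier(fm, family, "binary", grid = grids[[family]],
                           folds = 5, seed = 2)
    expect_equal(mod$best_cv_f1, 1.0, tolerance = 1e-9)
    expect_equal(nrow(mod$cv_results), 1) # size-1 grid returned unchanged
    expect_equal(mod$best_params$class_weight, "balanced")
  }
})

test_that("label-shuffled features score near the chance baseline", {
  fm <- fx_separable_fm(n_per_class = 60)
  set.seed(14)
  fm$label <- sample(fm$label)
  grid <- data.frame(max_depth = 2, eta = 0.3, nrounds = 20,
                     class_weight = "balanced")
  mod <- suppressWarnings(
    tune_classifier(fm, "xgb", "binary", grid = grid, folds = 5, seed = 3))
  expect_lt(abs(mod$best_cv_f1 - 0.5), 0.15)
})

test_that("held-out evaluation refuses leaked samples", {
  fm <- fab_fm(10, chunks_per_subject = 4)
  sp <- split_dataset(fm, "chunk", seed = 1)
  train <- fm[match(sp$train_ids, fm$sample_id), ]
  attr(train, "subject_ids") <- attr(fm, "subject_ids")[match(sp$train_ids,
                                                              fm$sample_id)]
  class(train) <- class(fm)
  grid <- data.frame(max_depth = 2, eta = 0.3, nrounds = 10,
                     class_weight = "none")
  mod <- suppressWarnings(
    tune_classifier(train, "xgb", grid = grid, folds = 3, seed = 1))
  expect_error(evaluate_model(mod, train[1:4, ]), "seen in training")
})

test_that("optimizer respects bounds, budget, and seeding", {
  flat <- function(M, N) 0.75
  opt <- optimize_filter_params(objective = flat, budget = 12, seed = 5)
  expect_equal(opt$best_f1, 0.75)
  expect_equal(nrow(opt$trace), 12)
  expect_true(all(opt$trace$M >= 100 & opt$trace$M <= 2000))
  expect_true(all(opt$trace$N >= 2 & opt$trace$N <= 25))
  opt2 <- optimize_filter_params(objective = flat, budget = 12, seed = 5)
  expect_identical(opt$trace, opt2$trace)
  expect_error(optimize_filter_params(objective = flat, budget = 5),
               "budget")
})

test_that("optimizer climbs a smooth objective close to its optimum", {
  peak <- function(M, N) {
    exp(-((M - 1500) / 600)^2 - ((N - 12) / 6)^2)
  }
  opt <- optimize_filter_params(objective = peak, budget = 30, seed = 2)
  expect_gt(opt$best_f1, 0.95) # true max is 1
})

test_that("sweep evaluates the same objective as the optimizer", {
  vals <- new.env(); vals$n <- 0
  obj <- function(M, N) {
    vals$n <- vals$n + 1
    M / 2000 + N / 25
  }
  tr <- sweep_filter_params(objective = obj, M_list = c(500), N_list = c(10))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$f1, obj(500, 10))
})

test_that("the 4-class severity task trains and reports macro metrics", {
  set.seed(21)
  lev <- c("healthy", "mild", "moderate", "severe")
  n_per <- 12
  lab <- rep(lev, each = n_per)
  x <- matrix(rnorm(length(lab) * 3), ncol = 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  x[, 1] <- 10 * (match(lab, lev) - 1) # graded point masses: separable
  fm <- feature_matrix(tibble::as_tibble(x),
                       sample_ids = sprintf("s%02d", seq_along(lab)),
                       labels = lab,
                       subject_ids = sprintf("subj%02d", seq_along(lab)))
  sp <- split_dataset(fm, "subject", seed = 3)
  train <- fm[match(sp$train_ids, fm$sample_id), ]
  attr(train, "subject_ids") <- attr(fm, "subject_ids")[match(sp$train_ids,
                                                              fm$sample_id)]
  class(train) <- class(fm)
  mod <- suppressWarnings(tune_classifier(
    train, "xgb", "severity",
    grid = data.frame(max_depth = 2, eta = 0.3, nrounds = 30,
                      class_weight = "balanced"),
    folds = 5, seed = 3))
  test <- fm[match(sp$test_ids, fm$sample_id), ]
  attr(test, "subject_ids") <- attr(fm, "subject_ids")[match(sp$test_ids,
                                                             fm$sample_id)]
  class(test) <- class(fm)
  m <- evaluate_model(mod, test)
  expect_equal(dim(m$confusion), c(4, 4))
  expect_equal(m$f1, 1.0) # macro F1 on a cleanly graded cohort
  expect_equal(m$accuracy, 1.0)
})
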