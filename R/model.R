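binary_labels <- function(labels) {
  factor(ifelse(labels == "healthy", "healthy", "AS"),
         levels = c("healthy", "AS"))
}

task_labels <- function(fm, task, levels = NULL) {
  if (task == "binary") return(binary_labels(fm$label))
  if (is.null(levels)) levels <- intersect(CLASS_LABELS, unique(fm$label))
  factor(fm$label, levels = levels)
}

#' Stratified train/test split with subject-level leakage guard
#'
#' Splits a feature matrix into training and held-out test sets, stratified
#' by class. At subject level the split is over subjects directly; at chunk
#' level whole subjects are assigned to one side so that no subject's chunks
#' appear on both (choosing, per class, the subject combination whose chunk
#' count lands closest to the requested test fraction).
#'
#' @param fm A [feature_matrix()].
#' @param level `"chunk"` or `"subject"`.
#' @param fraction_test Held-out fraction (default 0.2).
#' @param seed Integer seed; the split is deterministic given it.
#' @return A `cm_split` list: `train_ids`, `test_ids` (sample ids), `level`,
#'   `fraction_test`, `seed`.
#' @export
split_dataset <- function(fm, level = c("chunk", "subject"),
                          fraction_test = 0.2, seed = 1L) {
  level <- match.arg(level)
  subjects <- attr(fm, "subject_ids")
  info <- tibble::tibble(sample_id = fm$sample_id, label = fm$label,
                         subject = subjects)
  set.seed(seed)
  test_ids <- character()
  by_class <- split(info, info$label)
  for (cls in names(by_class)) {
    g <- by_class[[cls]]
    subj <- unique(g$subject)
    if (length(subj) < 2) {
      stop("class ", cls, " needs at least 2 subjects to stratify",
           call. = FALSE)
    }
    if (level == "subject") {
      n_test <- max(1L, round(fraction_test * length(subj)))
      pick <- sample(subj, n_test)
    } else {
      # greedy: shuffled subjects accumulated until the chunk count reaches
      # the target
      target <- fraction_test * nrow(g)
      order <- sample(subj)
      counts <- vapply(order, function(s) sum(g$subject == s), numeric(1))
      cum <- cumsum(counts)
      k <- which.min(abs(cum - target))
      if (cum[k] == nrow(g)) k <- k - 1L # never absorb a whole class
      k <- max(1L, k)
      pick <- order[seq_len(k)]
    }
    test_ids <- c(test_ids, g$sample_id[g$subject %in% pick])
  }
  structure(
    list(train_ids = setdiff(info$sample_id, test_ids), test_ids = test_ids,
         level = level, fraction_test = fraction_test, seed = seed),
    class = "cm_split"
  )
}

#' @export
print.cm_split <- function(x, ...) {
  cat(sprintf("<cm_split> %s-level | %d train / %d test (%.0f%% held out)\n",
              x$level, length(x$train_ids), length(x$test_ids),
              100 * length(x$test_ids) /
                (length(x$train_ids) + length(x$test_ids))))
  invisible(x)
}

take_samples <- function(fm, ids) {
  idx <- match(ids, fm$sample_id)
  out <- fm[idx, ]
  attr(out, "subject_ids") <- attr(fm, "subject_ids")[idx]
  class(out) <- class(fm)
  out
}

# ---- uniform classifier interface -----------------------------------------

default_grid <- function(family) {
  # hyperparameter dimensions per family: tree depth/leaf/split/feature
  # fraction and criterion for the tree ensembles, learning rate for the
  # boosted trees, cost/kernel/coefficient for the SVM; class weights
  # ("balanced" = inverse class frequency) everywhere
  switch(family,
    dt = expand.grid(maxdepth = c(3, 6, 12), minbucket = c(1, 5),
                     minsplit = c(2, 10), criterion = c("gini", "information"),
                     class_weight = c("balanced", "none"),
                     stringsAsFactors = FALSE),
    rf = expand.grid(max.depth = c(0, 8), min.node.size = c(1, 5),
                     mtry_frac = c(0.33, 0.8), num.trees = c(200),
                     splitrule = "gini", class_weight = c("balanced", "none"),
                     stringsAsFactors = FALSE),
    xgb = expand.grid(max_depth = c(2, 4, 6), min_child_weight = c(1, 3),
                      colsample_bytree = c(0.5, 1), eta = c(0.1, 0.3),
                      nrounds = c(100), class_weight = c("balanced"),
                      stringsAsFactors = FALSE),
    svm = expand.grid(cost = c(0.1, 1, 10), kernel = c("radial", "linear"),
                      gamma_scale = c(0.5, 1, 2),
                      class_weight = c("balanced", "none"),
                      stringsAsFactors = FALSE),
    stop("unknown family: ", family, call. = FALSE)
  )
}

class_weight_vector <- function(y, mode) {
  lev <- levels(y)
  if (identical(mode, "balanced")) {
    tab <- table(y)
    w <- length(y) / (length(lev) * as.numeric(tab[lev]))
    setNames(w, lev)
  } else {
    setNames(rep(1, length(lev)), lev)
  }
}

cm_fit <- function(family, x, y, params, seed = 1L) {
  cw <- class_weight_vector(y, params$class_weight %||% "none")
  case_w <- as.numeric(cw[as.character(y)])
  fit <- switch(family,
    dt = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, weights = case_w, method = "class",
                   parms = list(split = params$criterion %||% "gini"),
                   control = rpart::rpart.control(
                     maxdepth = params$maxdepth %||% 30,
                     minbucket = params$minbucket %||% 7,
                     minsplit = params$minsplit %||% 20, cp = 0, xval = 0))
    },
    rf = ranger::ranger(
      x = x, y = y,
      num.trees = params$num.trees %||% 200,
      mtry = max(1L, floor((params$mtry_frac %||% 0.33) * ncol(x))),
      min.node.size = params$min.node.size %||% 1,
      max.depth = params$max.depth %||% 0,
      splitrule = params$splitrule %||% "gini",
      class.weights = as.numeric(cw[levels(y)]),
      seed = seed, num.threads = 1, importance = "impurity"),
    xgb = {
      nc <- nlevels(y)
      obj <- if (nc == 2) "binary:logistic" else "multi:softmax"
      extra <- if (nc > 2) list(num_class = nc) else list()
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L,
                                     weight = case_w, nthread = 1)
      xgboost::xgb.train(
        params = c(list(max_depth = params$max_depth %||% 4,
                        eta = params$eta %||% 0.3,
                        min_child_weight = params$min_child_weight %||% 1,
                        colsample_bytree = params$colsample_bytree %||% 1,
                        objective = obj, nthread = 1, seed = seed), extra),
        data = dtrain, nrounds = params$nrounds %||% 100, verbose = 0)
    },
    svm = {
      gamma <- (params$gamma_scale %||% 1) / ncol(x)
      e1071::svm(x = x, y = y, cost = params$cost %||% 1,
                 kernel = params$kernel %||% "radial", gamma = gamma,
                 class.weights = cw, scale = TRUE)
    },
    stop("unknown family: ", family, call. = FALSE)
  )
  structure(list(family = family, fit = fit, levels = levels(y),
                 params = params, features = colnames(x)),
            class = "cm_fit")
}

cm_predict <- function(object, x) {
  x <- x[, object$features, drop = FALSE]
  lev <- object$levels
  pred <- switch(object$family,
    dt = {
      df <- data.frame(x, check.names = FALSE)
      as.character(predict(object$fit, df, type = "class"))
    },
    rf = as.character(predict(object$fit, data = x,
                              num.threads = 1)$predictions),
    xgb = {
      p <- predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1))
      if (length(lev) == 2) lev[(p > 0.5) + 1L] else lev[p + 1L]
    },
    svm = as.character(predict(object$fit, x))
  )
  factor(pred, levels = lev)
}

#' Native feature importance of a fitted classifier
#'
#' Split-gain importance for the boosted trees, impurity importance for the
#' random forest, and rpart's variable importance for the decision tree
#' (SVMs expose no native importance and raise).
#'
#' @param object A fitted model from [tune_classifier()] (or an internal
#'   `cm_fit`).
#' @return Named numeric vector over all features (absent features score 0).
#' @export
feature_importance <- function(object) {
  if (inherits(object, "cm_model")) object <- object$fit_obj
  stopifnot(inherits(object, "cm_fit"))
  raw <- switch(object$family,
    xgb = {
      imp <- xgboost::xgb.importance(model = object$fit)
      setNames(imp$Gain, imp$Feature)
    },
    rf = object$fit$variable.importance,
    dt = object$fit$variable.importance %||% numeric(),
    svm = stop("SVMs have no native feature importance", call. = FALSE)
  )
  out <- setNames(rep(0, length(object$features)), object$features)
  raw <- raw[names(raw) %in% names(out)]
  out[names(raw)] <- raw
  out
}

# ---- metrics ---------------------------------------------------------------

#' Classification metrics from predictions
#'
#' Binary metrics take AS as the positive class; multi-class metrics are
#' macro-averaged over classes. Accuracy is the trace of the confusion table
#' over its total.
#'
#' @param truth Factor of true labels.
#' @param pred Factor of predictions over the same levels.
#' @param positive Positive class for binary metrics (default: the second
#'   level, i.e. AS).
#' @return A `cm_metrics` list: `precision`, `recall`, `accuracy`, `f1`,
#'   `confusion` (table with truth in rows).
#' @export
classification_metrics <- function(truth, pred, positive = NULL) {
  stopifnot(length(truth) == length(pred))
  lev <- levels(truth)
  pred <- factor(pred, levels = lev)
  conf <- table(truth = truth, pred = pred)
  acc <- sum(diag(conf)) / sum(conf)
  if (length(lev) == 2) {
    if (is.null(positive)) positive <- lev[2]
    tp <- conf[positive, positive]
    fp <- sum(conf[, positive]) - tp
    fn <- sum(conf[positive, ]) - tp
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    re <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (pr + re > 0) 2 * pr * re / (pr + re) else 0
  } else {
    prs <- res <- f1s <- numeric(length(lev))
    for (i in seq_along(lev)) {
      tp <- conf[i, i]
      fp <- sum(conf[, i]) - tp
      fn <- sum(conf[i, ]) - tp
      prs[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
      res[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1s[i] <- if (prs[i] + res[i] > 0) 2 * prs[i] * res[i] / (prs[i] + res[i]) else 0
    }
    pr <- mean(prs)
    re <- mean(res)
    f1 <- mean(f1s)
  }
  structure(list(precision = pr, recall = re, accuracy = acc, f1 = f1,
                 confusion = conf),
            class = "cm_metrics")
}

#' @export
print.cm_metrics <- function(x, ...) {
  cat(sprintf("<cm_metrics> PR %.4f | RE %.4f | AC %.4f | F1 %.4f\n",
              x$precision, x$recall, x$accuracy, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Row-normalized confusion table
#' @param metrics A `cm_metrics`.
#' @return Matrix of per-true-class prediction fractions.
#' @export
confusion_rates <- function(metrics) {
  conf <- unclass(metrics$confusion)
  sweep(conf, 1, pmax(rowSums(conf), 1), "/")
}

cv_fold_assignments <- function(groups, k, seed) {
  # contiguous assignment of shuffled unique groups to k folds
  set.seed(seed)
  u <- sample(unique(groups))
  fold_of <- setNames(rep(seq_len(k), length.out = length(u)), u)
  unname(fold_of[as.character(groups)])
}

cv_f1 <- function(x, y, groups, family, params, folds, seed) {
  assign <- cv_fold_assignments(groups, folds, seed)
  scores <- c()
  for (f in sort(unique(assign))) {
    tr <- assign != f
    if (length(unique(y[tr])) < 2 || !any(!tr)) {
      warning("degenerate CV fold skipped (single class)", call. = FALSE)
      next
    }
    fit <- cm_fit(family, x[tr, , drop = FALSE], droplevels(y[tr]), params,
                  seed = seed + f)
    pred <- cm_predict(fit, x[!tr, , drop = FALSE])
    pred <- factor(as.character(pred), levels = levels(y))
    m <- classification_metrics(y[!tr], pred)
    scores <- c(scores, m$f1)
  }
  if (!length(scores)) return(0)
  mean(scores)
}

#' Tune a classifier by cross-validated grid search
#'
#' Searches the family's hyperparameter grid (tree depth, leaf/split sizes,
#' feature subsampling, split criterion, learning rate, SVM cost/kernel/
#' coefficient, and class weights) by k-fold cross-validation on the
#' training samples, selecting the configuration with the highest mean CV
#' F1-score, then refits it on the full training set. At subject level the
#' folds partition subjects; at chunk level they partition chunks.
#' Degenerate folds containing a single class are skipped with a warning.
#'
#' @param train A training [feature_matrix()].
#' @param family `"dt"`, `"rf"`, `"xgb"` or `"svm"`.
#' @param task `"binary"` (AS vs healthy) or `"severity"` (4-class).
#' @param grid Data frame of candidate configurations (default:
#'   [default_grid]).
#' @param folds Number of CV folds (default 10).
#' @param fold_by `"sample"` or `"subject"`: what the folds partition.
#' @param seed Integer seed.
#' @return A `cm_model`: `fit_obj`, `best_params`, `cv_results` (tibble of
#'   all configurations with mean CV F1), `family`, `task`, `train_ids`.
#' @export
tune_classifier <- function(train, family = c("xgb", "dt", "rf", "svm"),
                            task = c("binary", "severity"), grid = NULL,
                            folds = 10, fold_by = c("sample", "subject"),
                            seed = 1L) {
  family <- match.arg(family)
  task <- match.arg(task)
  fold_by <- match.arg(fold_by)
  if (is.null(grid)) grid <- default_grid(family)
  x <- feature_values(train)
  y <- task_labels(train, task)
  if (length(unique(y)) < 2) stop("training set has a single class", call. = FALSE)
  groups <- if (fold_by == "subject") attr(train, "subject_ids") else
    train$sample_id
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    cv_f1(x, y, groups, family, as.list(grid[i, , drop = FALSE]), folds, seed)
  }, numeric(1))
  best <- which.max(scores)
  best_params <- as.list(grid[best, , drop = FALSE])
  fit <- cm_fit(family, x, y, best_params, seed = seed)
  structure(
    list(fit_obj = fit, best_params = best_params,
         cv_results = tibble::as_tibble(cbind(grid, cv_f1 = scores)),
         best_cv_f1 = scores[best], family = family, task = task,
         train_ids = train$sample_id),
    class = "cm_model"
  )
}

#' @export
print.cm_model <- function(x, ...) {
  cat(sprintf("<cm_model> %s (%s task) | best mean CV F1 %.4f\n",
              x$family, x$task, x$best_cv_f1))
  invisible(x)
}

#' Evaluate a tuned model on held-out samples
#'
#' @param model A `cm_model` from [tune_classifier()].
#' @param test A test [feature_matrix()] (must be disjoint from the training
#'   samples; overlap raises, as a leakage guard).
#' @return A `cm_metrics`.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(model, "cm_model"), nrow(test) > 0)
  leak <- intersect(model$train_ids, test$sample_id)
  if (length(leak)) {
    stop("test samples seen in training: ", paste(head(leak, 3), collapse = ", "),
         call. = FALSE)
  }
  y <- task_labels(test, model$task, levels = model$fit_obj$levels)
  pred <- cm_predict(model$fit_obj, feature_values(test))
  pred <- factor(as.character(pred), levels = levels(y))
  classification_metrics(y, pred)
}
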