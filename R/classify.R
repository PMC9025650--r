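# Disease-status classification: logistic baselines and the balanced random
# forest (BRF) pipeline. A balanced forest trains every tree on a bootstrap
# that draws equal numbers from both classes (the majority class is randomly
# under-sampled), counteracting class imbalance without reweighting.

#' Cross-validation and classifier configuration
#'
#' @param n_splits Stratified folds per repeat (default 10).
#' @param n_repeats CV repeats (default 3).
#' @param holdout_fraction Test fraction for the single-split logistic path
#'   (default 0.30).
#' @param top_k Features kept after Gini pruning (default 13).
#' @param decision_threshold Probability threshold for
#'   sensitivity/specificity/precision (default 0.5).
#' @param num_trees Trees per forest (default 500).
#' @param mtry Features tried per split; `NULL` = ranger's default (square
#'   root of the feature count).
#' @param aggregate `"mean"` (mean of per-fold metrics, the default) or
#'   `"pooled"` (metrics recomputed on predictions pooled across folds).
#' @param seed Integer seed; fixes folds, forests and metrics.
#' @export
cv_config <- function(n_splits = 10, n_repeats = 3, holdout_fraction = 0.30,
                      top_k = 13, decision_threshold = 0.5, num_trees = 500,
                      mtry = NULL, aggregate = c("mean", "pooled"), seed = 1L) {
  aggregate <- arg_match(aggregate)
  if (n_splits < 2) config_error("n_splits must be >= 2")
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    config_error("holdout_fraction must lie in (0, 1)")
  }
  structure(list(n_splits = as.integer(n_splits),
                 n_repeats = as.integer(n_repeats),
                 holdout_fraction = holdout_fraction,
                 top_k = as.integer(top_k),
                 decision_threshold = decision_threshold,
                 num_trees = as.integer(num_trees), mtry = mtry,
                 aggregate = aggregate, seed = as.integer(seed)),
            class = "cv_config")
}

as_binary_labels <- function(labels, positive = NULL) {
  f <- as.factor(labels)
  if (nlevels(f) != 2) validation_error("labels must have exactly 2 classes")
  if (is.null(positive)) {
    positive <- if ("diabetic" %in% levels(f)) "diabetic" else levels(f)[2]
  }
  stats::relevel(f, ref = setdiff(levels(f), positive))
}

#' Threshold and ranking metrics for binary scores
#'
#' AUC by the rank (Mann-Whitney) formulation with mid-rank tie correction;
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP) at the decision threshold, with the more severe class as the
#' positive target.
#'
#' @param scores Predicted probabilities of the positive class, in `[0, 1]`.
#' @param labels Binary labels (factor/character/logical).
#' @param threshold Decision threshold (default 0.5).
#' @param positive Positive class label; defaults to `"diabetic"` when
#'   present, else the second factor level.
#' @return List with `auc`, `sensitivity`, `specificity`, `precision` and the
#'   2x2 `confusion` matrix (rows = truth, columns = prediction).
#' @examples
#' compute_metrics(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5, positive = NULL) {
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    validation_error("scores must lie in [0, 1]")
  }
  y <- as_binary_labels(labels, positive)
  pos <- levels(y)[2]
  is_pos <- y == pos
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) validation_error("labels contain a single class")
  r <- rank(scores)
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred_pos <- scores >= threshold
  tp <- sum(is_pos & pred_pos)
  fn <- sum(is_pos & !pred_pos)
  tn <- sum(!is_pos & !pred_pos)
  fp <- sum(!is_pos & pred_pos)
  confusion <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                      dimnames = list(truth = levels(y), pred = levels(y)))
  list(auc = auc,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       confusion = confusion)
}

#' Stratified fold assignment for repeated cross-validation
#'
#' Deterministic round-robin dealing within each class, so every fold's class
#' ratio is within one subject of the global ratio.
#'
#' @param labels Binary label vector.
#' @param n_splits,n_repeats Folds per repeat and number of repeats.
#' @param seed Seed for the within-class shuffles.
#' @return List of integer test-index vectors, named `"rep<R>_fold<K>"`.
#' @export
make_stratified_folds <- function(labels, n_splits, n_repeats = 1, seed = 1L) {
  y <- as.factor(labels)
  if (min(table(y)) < n_splits) {
    validation_error(sprintf(
      "smallest class (%d) is below n_splits (%d); use fewer splits",
      min(table(y)), n_splits))
  }
  set.seed(derive_seed(seed, 11))
  folds <- list()
  for (r in seq_len(n_repeats)) {
    assign <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(n_splits), length(idx))
    }
    for (k in seq_len(n_splits)) {
      folds[[sprintf("rep%d_fold%d", r, k)]] <- which(assign == k)
    }
  }
  folds
}

new_classifier_report <- function(model_tag, folds, metrics, confusion,
                                  predictions, positive, features,
                                  importance = NULL) {
  structure(list(model_tag = model_tag, folds = folds, metrics = metrics,
                 confusion = confusion, predictions = predictions,
                 positive = positive, features = features,
                 importance = importance),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report:%s> AUC %.3f | sens %.2f | spec %.2f | prec %.2f (positive = %s)\n",
    x$model_tag, x$metrics$auc, x$metrics$sensitivity, x$metrics$specificity,
    x$metrics$precision, x$positive))
  invisible(x)
}

#' Logistic classifier on a stratified train/test split
#'
#' Splits subjects into training (1 - `holdout_fraction`) and testing
#' (`holdout_fraction`) sets, stratified so each split reflects the original
#' class ratio, fits a logistic regression on the training set and evaluates
#' AUC/sensitivity/specificity/precision on the held-out set.
#'
#' @param features Data frame of numeric predictors.
#' @param labels Binary labels (positive = more severe dysglycemic class).
#' @param config A [cv_config()].
#' @param positive Optional positive-class label.
#' @return A `classifier_report`.
#' @export
logistic_classify <- function(features, labels, config = cv_config(),
                              positive = NULL) {
  features <- as_tibble(features)
  y <- as_binary_labels(labels, positive)
  set.seed(derive_seed(config$seed, 21))
  test_idx <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_test <- round(length(idx) * config$holdout_fraction)
    n_test <- max(1, min(n_test, length(idx) - 1))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  train_idx <- setdiff(seq_along(y), test_idx)
  if (length(unique(y[train_idx])) < 2) {
    validation_error("training split contains a single class")
  }
  d <- features
  d$.y <- as.integer(y == levels(y)[2])
  fit <- glm(.y ~ ., data = d[train_idx, ], family = binomial())
  scores <- predict(fit, newdata = d[test_idx, ], type = "response")
  m <- compute_metrics(scores, y[test_idx], config$decision_threshold,
                       positive = levels(y)[2])
  preds <- tibble(row = test_idx, truth = y[test_idx], score = unname(scores))
  folds <- tibble(fold = "holdout", n_test = length(test_idx),
                  auc = m$auc, sensitivity = m$sensitivity,
                  specificity = m$specificity, precision = m$precision)
  new_classifier_report("logistic", folds,
                        m[c("auc", "sensitivity", "specificity", "precision")],
                        m$confusion, preds, levels(y)[2], names(features))
}

brf_fit <- function(x, y, config, seed, importance = "none",
                    keep_inbag = FALSE) {
  frac <- min(table(y)) / length(y)
  ranger::ranger(
    x = as.data.frame(x), y = y, probability = TRUE,
    num.trees = config$num_trees, mtry = config$mtry,
    sample.fraction = rep(frac, 2), replace = TRUE,
    importance = importance, keep.inbag = keep_inbag,
    seed = seed, num.threads = 1
  )
}

#' Per-tree in-bag class counts of a balanced forest
#'
#' Instrumentation hook for the under-sampling contract: fits one balanced
#' forest with in-bag bookkeeping and tallies, per tree, how many training
#' draws came from each class. In a balanced forest the two columns are
#' equal for every tree.
#'
#' @inheritParams balanced_rf_cv
#' @return Integer matrix, trees x classes.
#' @export
brf_inbag_class_counts <- function(features, labels, config = cv_config(),
                                   positive = NULL) {
  y <- as_binary_labels(labels, positive)
  fit <- brf_fit(as_tibble(features), y, config,
                 seed = derive_seed(config$seed, 31), keep_inbag = TRUE)
  inbag <- do.call(cbind, fit$inbag.counts)  # obs x trees
  vapply(levels(y), function(cl) colSums(inbag[y == cl, , drop = FALSE]),
         numeric(fit$num.trees))  # trees x classes
}

#' Balanced random forest with repeated stratified cross-validation
#'
#' For each of `n_splits x n_repeats` stratified folds, trains a balanced
#' random forest (each tree's bootstrap draws equal numbers from both
#' classes, the majority class randomly under-sampled) on the training folds
#' and scores the held-out fold. Aggregate metrics are the mean of per-fold
#' AUC/sensitivity/specificity/precision (or recomputed on pooled
#' predictions when `config$aggregate = "pooled"`); the confusion matrix is
#' always pooled across folds.
#'
#' @param features Data frame of numeric predictors.
#' @param labels Binary labels; every class must have at least `n_splits`
#'   subjects.
#' @param config A [cv_config()].
#' @param positive Optional positive-class label.
#' @param model_tag Tag recorded in the report.
#' @return A `classifier_report` with per-fold metrics, aggregate metrics,
#'   pooled confusion matrix and out-of-fold predictions.
#' @export
balanced_rf_cv <- function(features, labels, config = cv_config(),
                           positive = NULL, model_tag = "brf") {
  features <- as_tibble(features)
  y <- as_binary_labels(labels, positive)
  folds <- make_stratified_folds(y, config$n_splits, config$n_repeats,
                                 seed = config$seed)
  fold_rows <- list()
  preds <- list()
  confusion <- NULL
  for (i in seq_along(folds)) {
    test <- folds[[i]]
    train <- setdiff(seq_along(y), test)
    fit <- brf_fit(features[train, , drop = FALSE], y[train], config,
                   seed = derive_seed(config$seed, 1000 + i))
    pr <- predict(fit, data = as.data.frame(features[test, , drop = FALSE]),
                  num.threads = 1)$predictions
    scores <- pr[, levels(y)[2]]
    m <- compute_metrics(scores, y[test], config$decision_threshold,
                         positive = levels(y)[2])
    fold_rows[[i]] <- tibble(fold = names(folds)[i], n_test = length(test),
                             auc = m$auc, sensitivity = m$sensitivity,
                             specificity = m$specificity,
                             precision = m$precision)
    preds[[i]] <- tibble(fold = names(folds)[i], row = test,
                         truth = y[test], score = scores)
    confusion <- if (is.null(confusion)) m$confusion else confusion + m$confusion
  }
  fold_tbl <- bind_rows(fold_rows)
  pred_tbl <- bind_rows(preds)
  metrics <- if (config$aggregate == "mean") {
    list(auc = mean(fold_tbl$auc), sensitivity = mean(fold_tbl$sensitivity),
         specificity = mean(fold_tbl$specificity),
         precision = mean(fold_tbl$precision, na.rm = TRUE))
  } else {
    m <- compute_metrics(pred_tbl$score, pred_tbl$truth,
                         config$decision_threshold, positive = levels(y)[2])
    m[c("auc", "sensitivity", "specificity", "precision")]
  }
  new_classifier_report(model_tag, fold_tbl, metrics, confusion, pred_tbl,
                        levels(y)[2], names(features))
}

#' Implicit feature selection with a balanced forest
#'
#' Fits one balanced forest on all data with mean-decrease-in-impurity (Gini)
#' importance and selects the features whose importance exceeds the mean
#' importance across features (the conventional select-from-model
#' threshold). Designated always-keep columns (covariates, the target CpG)
#' are retained regardless.
#'
#' @inheritParams balanced_rf_cv
#' @param always_keep Character vector of column names always retained.
#' @return Character vector of selected feature names, in the original
#'   column order.
#' @export
implicit_feature_select <- function(features, labels, config = cv_config(),
                                    always_keep = character(0),
                                    positive = NULL) {
  features <- as_tibble(features)
  y <- as_binary_labels(labels, positive)
  fit <- brf_fit(features, y, config, seed = derive_seed(config$seed, 41),
                 importance = "impurity")
  imp <- fit$variable.importance
  sel <- names(imp)[imp > mean(imp)]
  intersect(names(features), union(sel, always_keep))
}

#' Gini-importance ranking and pruning
#'
#' Ranks the selected features by Gini importance averaged over
#' `config$n_repeats` balanced forests (ties broken lexicographically by
#' feature name for determinism), keeps the top `config$top_k`, and refits
#' the cross-validated balanced forest on the retained set.
#'
#' @inheritParams balanced_rf_cv
#' @return List with `ranking` (tibble: feature, importance, rank),
#'   `selected` (retained feature names) and `report` (the final
#'   `classifier_report`).
#' @export
gini_prune <- function(features, labels, config = cv_config(),
                       positive = NULL) {
  features <- as_tibble(features)
  y <- as_binary_labels(labels, positive)
  imp <- rep(0, ncol(features))
  names(imp) <- names(features)
  for (r in seq_len(config$n_repeats)) {
    fit <- brf_fit(features, y, config,
                   seed = derive_seed(config$seed, 50 + r),
                   importance = "impurity")
    imp <- imp + fit$variable.importance[names(imp)]
  }
  imp <- imp / config$n_repeats
  ord <- order(-imp, names(imp))
  ranking <- tibble(feature = names(imp)[ord], importance = unname(imp[ord]),
                    rank = seq_along(imp))
  k <- config$top_k
  if (k > ncol(features)) {
    warn(sprintf("top_k (%d) exceeds available features (%d); keeping all",
                 k, ncol(features)))
    k <- ncol(features)
  }
  selected <- ranking$feature[seq_len(k)]
  report <- balanced_rf_cv(features[, selected, drop = FALSE], y, config,
                           positive = levels(y)[2], model_tag = "brf_pruned")
  list(ranking = ranking, selected = selected, report = report)
}
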