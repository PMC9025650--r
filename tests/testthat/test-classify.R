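test_that("metrics match hand-enumerated values and handle ties", {
  m <- compute_metrics(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$precision, 1)
  expect_equal(unname(as.vector(m$confusion)), c(2, 0, 0, 2))

  # perfect labels-as-scores
  p <- compute_metrics(c(1, 1, 0, 0, 0), c("b", "b", "a", "a", "a"),
                       positive = "b")
  expect_equal(p$auc, 1)
  # constant scores: tie-corrected AUC is exactly 0.5
  expect_equal(compute_metrics(rep(0.7, 20), rep(0:1, 10))$auc, 0.5)
  # hand-enumerated with one discordant pair: 5 concordant of 6
  m2 <- compute_metrics(c(0.9, 0.2, 0.6, 0.4), c(1, 1, 0, 0))
  expect_equal(m2$auc, 0.5)  # pairs: (.9>.6),(.9>.4),(.2<.6),(.2<.4) -> 2/4
  expect_error(compute_metrics(c(0.2, 0.3), c(1, 1)),
               class = "epigx_validation_error")
  expect_error(compute_metrics(c(1.2, 0.3), c(1, 0)),
               class = "epigx_validation_error")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- runif(150)
  labels <- rbinom(150, 1, plogis(3 * (scores - 0.5)))
  mine <- compute_metrics(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("stratified folds preserve the class ratio to within one subject", {
  labels <- factor(rep(c("control", "diabetic"), c(137, 90)))
  folds <- make_stratified_folds(labels, 10, 3, seed = 2)
  expect_identical(length(folds), 30L)
  global_ratio <- 90 / 227
  for (f in folds) {
    n_pos <- sum(labels[f] == "diabetic")
    expect_lte(abs(n_pos - global_ratio * length(f)), 1)
  }
  # each repeat partitions all subjects exactly once
  rep1 <- unlist(folds[1:10])
  expect_setequal(rep1, seq_along(labels))
  expect_error(make_stratified_folds(factor(rep(c("a", "b"), c(5, 100))), 10),
               class = "epigx_validation_error")
})

test_that("logistic path separates separable data and stratifies its split", {
  set.seed(8)
  n <- 200
  labels <- factor(rep(c("control", "diabetic"), each = n / 2))
  x <- tibble::tibble(f = ifelse(labels == "diabetic", 1, 0) + rnorm(n, 0, 0.01))
  rep <- suppressWarnings(logistic_classify(x, labels, cv_config(seed = 3)))
  expect_equal(rep$metrics$auc, 1)
  expect_equal(rep$metrics$sensitivity, 1)
  # test-set class ratio within one subject of global
  n_test_pos <- sum(rep$predictions$truth == "diabetic")
  expect_lte(abs(n_test_pos - 0.5 * nrow(rep$predictions)), 1)
  expect_identical(glance(rep)$model_tag, "logistic")
})

test_that("label permutation drives every classifier path to chance AUC", {
  set.seed(21)
  n <- 160
  x <- tibble::tibble(f1 = rnorm(n), f2 = rnorm(n))
  labels <- factor(rep(c("control", "diabetic"), each = n / 2))
  auc_lr <- vapply(1:40, function(i) {
    suppressWarnings(
      logistic_classify(x, sample(labels), cv_config(seed = i))$metrics$auc)
  }, numeric(1))
  expect_gt(mean(auc_lr), 0.4)
  expect_lt(mean(auc_lr), 0.6)
  auc_rf <- vapply(1:10, function(i) {
    balanced_rf_cv(x, sample(labels),
                   cv_config(n_splits = 4, n_repeats = 1, num_trees = 100,
                             seed = i))$metrics$auc
  }, numeric(1))
  expect_gt(mean(auc_rf), 0.4)
  expect_lt(mean(auc_rf), 0.6)
})

test_that("balanced forest draws equal class counts per tree", {
  set.seed(4)
  labels <- factor(rep(c("control", "diabetic"), c(140, 60)))
  x <- tibble::tibble(f1 = rnorm(200), f2 = rnorm(200))
  counts <- brf_inbag_class_counts(x, labels,
                                   cv_config(num_trees = 50, seed = 5))
  expect_identical(dim(counts), c(50L, 2L))
  expect_true(all(counts[, 1] == counts[, 2]))
  expect_true(all(counts[, "diabetic"] == 60))
})

test_that("cross-validated BRF is reproducible and beats chance on signal", {
  set.seed(10)
  n <- 220
  labels <- factor(rep(c("control", "diabetic"), c(150, 70)))
  x <- tibble::tibble(f1 = rnorm(n) + 1.5 * (labels == "diabetic"),
                      f2 = rnorm(n))
  cfg <- cv_config(n_splits = 5, n_repeats = 2, num_trees = 150, seed = 77)
  r1 <- balanced_rf_cv(x, labels, cfg)
  r2 <- balanced_rf_cv(x, labels, cfg)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$metrics, r2$metrics)
  expect_gt(r1$metrics$auc, 0.7)
  # confusion matrix pools every evaluated prediction across folds
  expect_equal(sum(r1$confusion), n * cfg$n_repeats)
  # per-fold tibble surfaces through tidy()
  expect_identical(nrow(tidy(r1)), 10L)
  # pooled aggregation is available and close to the fold mean
  rp <- balanced_rf_cv(x, labels, cv_config(n_splits = 5, n_repeats = 2,
                                            num_trees = 150, seed = 77,
                                            aggregate = "pooled"))
  expect_lt(abs(rp$metrics$auc - r1$metrics$auc), 0.1)
  expect_error(balanced_rf_cv(x, factor(rep(c("a", "b"), c(217, 3))),
                              cfg), class = "epigx_validation_error")
})

test_that("implicit selection recovers planted features and keeps anchors", {
  set.seed(14)
  n <- 200
  labels <- factor(rep(c("control", "diabetic"), each = 100))
  x <- tibble::tibble(.rows = n)
  for (j in 1:5) x[[paste0("planted", j)]] <-
    rnorm(n) + 0.9 * (labels == "diabetic")
  for (j in 1:95) x[[paste0("noise", j)]] <- rnorm(n)
  x$age <- rnorm(n, 45)
  cfg <- cv_config(num_trees = 300, seed = 6)
  sel <- implicit_feature_select(x, labels, cfg, always_keep = "age")
  expect_gte(sum(paste0("planted", 1:5) %in% sel), 4)
  expect_true("age" %in% sel)
  # all-noise input still runs and always-keep columns persist
  noise <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  sel0 <- implicit_feature_select(noise, labels, cfg, always_keep = "b")
  expect_true("b" %in% sel0)
})

test_that("Gini pruning ranks planted features first and is deterministic", {
  set.seed(15)
  n <- 200
  labels <- factor(rep(c("control", "diabetic"), each = 100))
  x <- tibble::tibble(p1 = rnorm(n) + 1.2 * (labels == "diabetic"),
                      p2 = rnorm(n) + 1.0 * (labels == "diabetic"))
  for (j in 1:10) x[[paste0("noise", j)]] <- rnorm(n)
  cfg <- cv_config(n_splits = 5, n_repeats = 2, num_trees = 200, top_k = 2,
                   seed = 16)
  pr <- gini_prune(x, labels, cfg)
  expect_setequal(pr$selected, c("p1", "p2"))
  pr2 <- gini_prune(x, labels, cfg)
  expect_identical(pr$ranking, pr2$ranking)
  # top_k = everything reproduces the unpruned model under the same seed
  cfg_all <- cv_config(n_splits = 5, n_repeats = 2, num_trees = 200,
                       top_k = ncol(x), seed = 16)
  pr_all <- gini_prune(x, labels, cfg_all)
  full <- balanced_rf_cv(x[, pr_all$ranking$feature, drop = FALSE], labels,
                         cfg_all)
  expect_equal(pr_all$report$metrics$auc, full$metrics$auc)
  expect_warning(gini_prune(x[, 1:3], labels,
                            cv_config(n_splits = 5, n_repeats = 1,
                                      num_trees = 50, top_k = 10, seed = 1)),
                 "top_k")
})
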