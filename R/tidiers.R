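# broom-style tidiers for fitted objects.

#' Tidy a step-wise model fit
#'
#' One row per model term with estimate, standard error, t statistic,
#' p-value and the conventional significance code (`***` < 0.001,
#' `**` < 0.01, `*` < 0.05).
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `signif`.
#' @export
tidy.stepwise_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
         statistic = sm[, 3], p_value = sm[, 4],
         signif = dplyr::case_when(sm[, 4] < 0.001 ~ "***",
                                   sm[, 4] < 0.01 ~ "**",
                                   sm[, 4] < 0.05 ~ "*",
                                   TRUE ~ ""))
}

#' Glance at a step-wise model fit
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return One-row tibble: `adj_r2`, overall F-test `p_value`, `n_used`,
#'   `n_terms`.
#' @export
glance.stepwise_fit <- function(x, ...) {
  sm <- summary(x$fit)
  p_overall <- if (is.null(sm$fstatistic)) NA_real_ else {
    unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE))
  }
  tibble(adj_r2 = x$adj_r2, p_value = p_overall, n_used = x$n_used,
         n_terms = length(x$terms))
}

#' Tidy a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return The per-fold metric tibble.
#' @export
tidy.classifier_report <- function(x, ...) x$folds

#' Glance at a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return One-row tibble of aggregate AUC, sensitivity, specificity and
#'   precision.
#' @export
glance.classifier_report <- function(x, ...) {
  tibble(model_tag = x$model_tag, auc = x$metrics$auc,
         sensitivity = x$metrics$sensitivity,
         specificity = x$metrics$specificity,
         precision = x$metrics$precision)
}
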