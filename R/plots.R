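# ggplot2 visualisations for scan and classifier results.

#' Manhattan-style plot of a scan
#'
#' Plots -log10 of the focal p-value by genomic position, faceting by
#' chromosome order, with an optional genome-wide significance line.
#'
#' @param scan A `scan_result` tibble with `chrom` and `pos` columns.
#' @param alpha Nominal significance level for the reference line; it is
#'   drawn at `alpha / n_features` (Bonferroni) when `bonferroni = TRUE`,
#'   else at `alpha`.
#' @param bonferroni Draw the Bonferroni-corrected line (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, alpha = 0.05, bonferroni = TRUE) {
  stopifnot(inherits(scan, "scan_result"))
  d <- as_tibble(scan)
  d$chrom_n <- suppressWarnings(as.integer(d$chrom))
  d <- arrange(d, .data$chrom_n, .data$pos)
  offsets <- d |>
    group_by(.data$chrom_n) |>
    summarise(span = max(as.numeric(.data$pos)), .groups = "drop") |>
    mutate(offset = cumsum(dplyr::lag(.data$span, default = 0)))
  d <- left_join(d, offsets, by = "chrom_n") |>
    mutate(x = .data$pos + .data$offset,
           neglog_p = -log10(pmax(.data$focal_p, 1e-300)))
  line_at <- if (bonferroni) alpha / nrow(d) else alpha
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$neglog_p,
                                  colour = factor(.data$chrom_n %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(line_at), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("grey40", "steelblue")) +
    ggplot2::labs(x = "genomic position (chromosomes concatenated)",
                  y = expression(-log[10](p)),
                  title = paste("scan:", unique(d$model_tag))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_manhattan
#' @param object,... Passed through to [plot_manhattan()].
#' @export
autoplot.scan_result <- function(object, ...) plot_manhattan(object, ...)

#' ROC curve of a classifier report
#'
#' Empirical ROC over the pooled out-of-fold (or held-out) predictions.
#'
#' @param report A `classifier_report`.
#' @return A ggplot object.
#' @export
plot_roc <- function(report) {
  stopifnot(inherits(report, "classifier_report"))
  p <- report$predictions
  pos <- report$positive
  thr <- sort(unique(c(-Inf, p$score, Inf)), decreasing = TRUE)
  is_pos <- p$truth == pos
  roc <- tibble(
    tpr = vapply(thr, function(t) mean(p$score[is_pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(p$score[!is_pos] >= t), numeric(1))
  )
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s (AUC = %.2f)", report$model_tag,
                                  report$metrics$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @param object,... Passed through to [plot_roc()].
#' @export
autoplot.classifier_report <- function(object, ...) plot_roc(object)

#' Confusion-matrix tile plot
#'
#' @param report A `classifier_report`.
#' @return A ggplot object.
#' @export
plot_confusion <- function(report) {
  stopifnot(inherits(report, "classifier_report"))
  cm <- as.data.frame(as.table(report$confusion))
  names(cm) <- c("truth", "prediction", "n")
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey60", high = "steelblue4") +
    ggplot2::labs(title = paste("confusion matrix:", report$model_tag)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
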