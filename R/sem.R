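# Stochastic epimutation (SEM) detection and summaries.
#
# A SEM is a methylation value beyond Tukey-style fences widened to three
# interquartile ranges: values above Q3 + 3*IQR are high methylation outliers
# (HMO), values below Q1 - 3*IQR are low methylation outliers (LMO).
# Quartiles use linear interpolation between order statistics (type 7, the
# stats::quantile default); fences are computed from all values of the probe
# including candidate outliers, and the fence comparison is strict, so values
# exactly on a fence are not called.

#' Detect stochastic epimutations per probe
#'
#' @param meth A [methylation_matrix()].
#' @param multiplier IQR multiplier for the fences (default 3).
#' @param min_n Minimum non-missing values per probe; probes below this are
#'   skipped with a warning (default 8).
#' @return A tibble of SEM calls with class `sem_calls`: `probe_id`,
#'   `sample_id`, `class` (`HMO`/`LMO`), `value`, `lower_fence`,
#'   `upper_fence`.
#' @examples
#' m <- methylation_matrix(
#'   matrix(c(rep(0.1, 9), 0.9), 10, 1, dimnames = list(NULL, "p1")),
#'   data.frame(probe_id = "p1", chrom = "1", pos = 100)
#' )
#' detect_sems(m)
#' @export
detect_sems <- function(meth, multiplier = 3, min_n = 8) {
  stopifnot(inherits(meth, "methylation_matrix"))
  if (!is.numeric(multiplier) || multiplier <= 0) {
    config_error("multiplier must be > 0")
  }
  betas <- meth$betas
  ids <- rownames(betas)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(betas)))
  calls <- vector("list", ncol(betas))
  skipped <- character(0)
  for (j in seq_len(ncol(betas))) {
    v <- betas[, j]
    nm <- !is.na(v)
    if (sum(nm) < min_n) {
      skipped <- c(skipped, colnames(betas)[j])
      next
    }
    q <- quantile(v[nm], c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    lo <- q[1] - multiplier * iqr
    hi <- q[2] + multiplier * iqr
    out_hi <- which(nm & v > hi)
    out_lo <- which(nm & v < lo)
    if (length(out_hi) + length(out_lo) == 0) next
    calls[[j]] <- tibble(
      probe_id = colnames(betas)[j],
      sample_id = ids[c(out_hi, out_lo)],
      class = rep(c("HMO", "LMO"), c(length(out_hi), length(out_lo))),
      value = v[c(out_hi, out_lo)],
      lower_fence = lo, upper_fence = hi
    )
  }
  if (length(skipped)) {
    warn(sprintf("%d probe(s) skipped (< %d non-missing values)",
                 length(skipped), min_n))
  }
  out <- bind_rows(calls)
  if (nrow(out) == 0) {
    out <- tibble(probe_id = character(0), sample_id = character(0),
                  class = character(0), value = numeric(0),
                  lower_fence = numeric(0), upper_fence = numeric(0))
  }
  class(out) <- c("sem_calls", class(out))
  out
}

#' Summarise SEM burden by probe, subject and class
#'
#' @param calls A `sem_calls` tibble from [detect_sems()].
#' @return Named list of tibbles: `by_probe` (probe, HMO/LMO/total counts),
#'   `by_subject` (subject totals), and `summary` (call totals, subjects with
#'   at least one call, median and spread of per-subject counts).
#' @export
sem_burden <- function(calls) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    return(list(
      by_probe = tibble(probe_id = character(0), n_hmo = integer(0),
                        n_lmo = integer(0), n_total = integer(0)),
      by_subject = tibble(sample_id = character(0), n_hmo = integer(0),
                          n_lmo = integer(0), n_total = integer(0)),
      summary = tibble(n_calls = 0L, n_hmo = 0L, n_lmo = 0L,
                       n_probes = 0L, n_subjects = 0L,
                       median_per_subject = 0, sd_per_subject = 0)
    ))
  }
  by_probe <- calls |>
    group_by(.data$probe_id) |>
    summarise(n_hmo = sum(.data$class == "HMO"),
              n_lmo = sum(.data$class == "LMO"),
              n_total = n(), .groups = "drop")
  by_subject <- calls |>
    group_by(.data$sample_id) |>
    summarise(n_hmo = sum(.data$class == "HMO"),
              n_lmo = sum(.data$class == "LMO"),
              n_total = n(), .groups = "drop")
  list(
    by_probe = by_probe,
    by_subject = by_subject,
    summary = tibble(
      n_calls = nrow(calls),
      n_hmo = sum(calls$class == "HMO"),
      n_lmo = sum(calls$class == "LMO"),
      n_probes = nrow(by_probe),
      n_subjects = nrow(by_subject),
      median_per_subject = median(by_subject$n_total),
      sd_per_subject = if (nrow(by_subject) > 1) sd(by_subject$n_total) else 0
    )
  )
}

#' Case-control enrichment of SEM carriers
#'
#' Two-by-two table of subjects carrying at least one SEM versus none,
#' split into diabetic versus non-diabetic subjects, tested with the
#' two-tailed Fisher exact test (hypergeometric). The odds ratio is the exact
#' conditional maximum-likelihood estimate with its exact 95 % confidence
#' interval, consistent with the exact test. The subject (not the call) is
#' the independent unit.
#'
#' The table orientation is fixed as rows = (diabetic, non-diabetic), columns
#' = (has SEM, no SEM), so OR > 1 means carriers are over-represented among
#' diabetic subjects.
#'
#' @param calls A `sem_calls` tibble.
#' @param samples Sample tibble with `sample_id` and `glycemic_class`.
#' @return One-row tibble: counts, `odds_ratio`, `conf_low`, `conf_high`,
#'   `p_value`. A degenerate table (zero margin) reports `NA` for the OR.
#' @export
sem_enrichment <- function(calls, samples) {
  calls <- as_tibble(calls)
  samples <- as_tibble(samples)
  diabetic <- as.character(samples$glycemic_class) == "diabetic"
  if (!any(diabetic) || all(diabetic)) {
    validation_error("both diabetic and non-diabetic groups must be non-empty")
  }
  has_sem <- samples$sample_id %in% calls$sample_id
  tab <- matrix(c(sum(diabetic & has_sem), sum(diabetic & !has_sem),
                  sum(!diabetic & has_sem), sum(!diabetic & !has_sem)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("diabetic", "non_diabetic"),
                                c("sem", "no_sem")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  tibble(
    diabetic_sem = tab[1, 1], diabetic_no_sem = tab[1, 2],
    nondiabetic_sem = tab[2, 1], nondiabetic_no_sem = tab[2, 2],
    odds_ratio = if (degenerate) NA_real_ else unname(ft$estimate),
    conf_low = if (degenerate) NA_real_ else ft$conf.int[1],
    conf_high = if (degenerate) NA_real_ else ft$conf.int[2],
    p_value = ft$p.value
  )
}

#' Drop SEM-carrying probes from the methylation matrix
#'
#' Removes the probes listed in `calls` (or an explicit `probe_set`), mirroring
#' the rule that loci containing stochastic epimutations are excluded from the
#' downstream scans. The designated target probe is never dropped unless it
#' itself carries a call.
#'
#' @param meth A [methylation_matrix()].
#' @param calls A `sem_calls` tibble (used when `probe_set` is `NULL`).
#' @param probe_set Optional explicit character vector of probes to drop.
#' @param target_probe Probe id protected from dropping when it has no calls.
#' @return A filtered [methylation_matrix()].
#' @export
filter_sem_probes <- function(meth, calls = NULL, probe_set = NULL,
                              target_probe = NULL) {
  stopifnot(inherits(meth, "methylation_matrix"))
  drop <- if (is.null(probe_set)) unique(as_tibble(calls)$probe_id) else probe_set
  if (!is.null(target_probe)) {
    target_called <- !is.null(calls) &&
      target_probe %in% as_tibble(calls)$probe_id
    if (!target_called) drop <- setdiff(drop, target_probe)
  }
  keep <- !(meth$manifest$probe_id %in% drop)
  if (!any(keep)) {
    warn("all probes dropped by SEM filter; returning empty matrix")
  }
  methylation_matrix(meth$betas[, keep, drop = FALSE],
                     meth$manifest[keep, , drop = FALSE])
}
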