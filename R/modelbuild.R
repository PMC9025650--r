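# Step-wise construction of integrated variance models, nested-model F-tests
# and genotype-stratified methylation comparisons.

#' Step-wise selection configuration
#'
#' @param entry_adj_r2 Minimum univariate adjusted R-squared for a candidate
#'   to enter the pool (the screens used in practice are 0.03 for meQTL
#'   candidates and 0.1550 for interaction candidates).
#' @param retention_alpha Coefficient p-value a term must keep in the joint
#'   fit to be retained (default 0.05).
#' @param comparison_alpha Nested-model F-test alpha for accepting an
#'   addition (default 0.05).
#' @param max_kappa Condition-number threshold above which a candidate is
#'   skipped as collinear.
#' @export
stepwise_config <- function(entry_adj_r2 = 0, retention_alpha = 0.05,
                            comparison_alpha = 0.05, max_kappa = 1e8) {
  if (retention_alpha <= 0 || retention_alpha >= 1 ||
      comparison_alpha <= 0 || comparison_alpha >= 1) {
    config_error("alphas must lie in (0, 1)")
  }
  structure(list(entry_adj_r2 = entry_adj_r2,
                 retention_alpha = retention_alpha,
                 comparison_alpha = comparison_alpha,
                 max_kappa = max_kappa),
            class = "stepwise_config")
}

term_parents <- function(term) {
  if (grepl(":", term, fixed = TRUE)) strsplit(term, ":", fixed = TRUE)[[1]]
  else character(0)
}

fit_terms <- function(data, response, terms) {
  f <- if (length(terms)) reformulate(terms, response) else
    as.formula(paste(response, "~ 1"))
  lm(f, data = data)
}

adj_r2_of <- function(fit) summary(fit)$adj.r.squared

# coefficient p-value for a model term (interaction order-insensitive)
term_p <- function(fit, term) {
  sm <- summary(fit)$coefficients
  rn <- rownames(sm)
  norm <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                             function(p) paste(sort(p), collapse = ":"), "")
  hit <- which(norm(rn) == norm(term))
  if (!length(hit)) return(NA_real_)
  sm[hit[1], 4]
}

#' Additive step-wise model construction
#'
#' Starting from a base model, candidates (ranked by their univariate
#' adjusted R-squared, descending) are offered one at a time. A candidate is
#' retained iff (a) its coefficient stays significant in the joint fit at
#' `retention_alpha` and (b) the nested-model F-test against the model
#' without it is significant at `comparison_alpha`. After each accepted
#' addition, previously retained candidates that have lost significance are
#' dropped (a single sweep). Interaction candidates written `"a:b"` bring
#' both parents into the model (model hierarchy), and parents of a retained
#' interaction are never swept out. Candidates that are collinear with the
#' current model (condition number above `max_kappa`, or aliased) are skipped
#' with a log entry.
#'
#' @param data Data frame holding the response and all candidate columns.
#' @param response Name of the response column.
#' @param candidates Character vector of candidate terms (column names or
#'   `"a:b"` interactions). Screened and ranked internally unless
#'   `rank_candidates = FALSE`.
#' @param base_terms Character vector of always-kept base terms (may be
#'   empty).
#' @param config A [stepwise_config()].
#' @param rank_candidates Rank candidates by univariate adjusted R-squared
#'   (response ~ term + parents) before stepping; also applies the
#'   `entry_adj_r2` screen. Default `TRUE`.
#' @return An object of class `stepwise_fit`: the final [stats::lm()] fit,
#'   the retained term list, a step-by-step history tibble, adjusted
#'   R-squared and sample size.
#' @export
stepwise_build <- function(data, response, candidates,
                           base_terms = character(0),
                           config = stepwise_config(),
                           rank_candidates = TRUE) {
  stopifnot(inherits(config, "stepwise_config"))
  data <- as_tibble(data)
  history <- list()
  log_step <- function(term, action, p = NA_real_, f_p = NA_real_,
                       adj_r2 = NA_real_) {
    history[[length(history) + 1]] <<- tibble(
      step = length(history) + 1L, term = term, action = action,
      p_value = p, f_p = f_p, adj_r2 = adj_r2)
  }

  if (rank_candidates && length(candidates)) {
    uni <- vapply(candidates, function(tm) {
      fit <- tryCatch(fit_terms(data, response, unique(c(term_parents(tm), tm))),
                      error = function(e) NULL)
      if (is.null(fit)) return(-Inf)
      adj_r2_of(fit)
    }, numeric(1))
    keep <- uni >= config$entry_adj_r2
    for (tm in candidates[!keep]) log_step(tm, "screened_out")
    candidates <- candidates[keep][order(uni[keep], decreasing = TRUE)]
  }

  retained <- character(0)
  current <- fit_terms(data, response, base_terms)
  for (cand in candidates) {
    parents <- setdiff(term_parents(cand), c(base_terms, retained))
    proposal <- unique(c(retained, parents, cand))
    trial <- fit_terms(data, response, c(base_terms, proposal))
    if (anyNA(coef(trial))) {
      log_step(cand, "skipped_aliased")
      next
    }
    kap <- kappa(model.matrix(trial), exact = FALSE)
    if (is.finite(kap) && kap > config$max_kappa) {
      log_step(cand, "skipped_collinear")
      next
    }
    p_cand <- term_p(trial, cand)
    f_p <- nested_f_p(current, trial)
    if (!is.na(p_cand) && p_cand < config$retention_alpha &&
        !is.na(f_p) && f_p < config$comparison_alpha) {
      retained <- proposal
      current <- trial
      log_step(cand, "added", p_cand, f_p, adj_r2_of(current))
      # single sweep: drop retained terms that lost significance (never base
      # terms, never parents of a retained interaction)
      protected <- unique(c(base_terms,
                            unlist(lapply(retained[grepl(":", retained)],
                                          term_parents))))
      droppable <- setdiff(retained, protected)
      lost <- droppable[vapply(droppable, function(tm) {
        p <- term_p(current, tm)
        is.na(p) || p >= config$retention_alpha
      }, logical(1))]
      if (length(lost)) {
        retained <- setdiff(retained, lost)
        current <- fit_terms(data, response, c(base_terms, retained))
        for (tm in lost) log_step(tm, "dropped_nonsignificant",
                                  adj_r2 = adj_r2_of(current))
      }
    } else {
      log_step(cand, "rejected", p_cand, f_p)
    }
  }
  structure(list(
    fit = current, response = response, base_terms = base_terms,
    terms = c(base_terms, retained), retained = retained,
    history = if (length(history)) bind_rows(history) else
      tibble(step = integer(0), term = character(0), action = character(0),
             p_value = numeric(0), f_p = numeric(0), adj_r2 = numeric(0)),
    adj_r2 = adj_r2_of(current),
    n_used = stats::nobs(current)
  ), class = "stepwise_fit")
}

nested_f_p <- function(small, large) {
  rss_s <- sum(stats::residuals(small)^2)
  rss_l <- sum(stats::residuals(large)^2)
  df_s <- stats::df.residual(small)
  df_l <- stats::df.residual(large)
  ddf <- df_s - df_l
  if (ddf <= 0) return(1)
  f <- max(0, ((rss_s - rss_l) / ddf) / (rss_l / df_l))
  pf(f, ddf, df_l, lower.tail = FALSE)
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> %s ~ %s\n  adj R^2 = %.4f, n = %d\n",
              x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$adj_r2, x$n_used))
  invisible(x)
}

#' Nested-model comparison by extra-sum-of-squares F-test
#'
#' Classical ANOVA comparison of two nested least-squares fits on the same
#' samples. Identical models return `F = 0, p = 1`.
#'
#' @param fit_small,fit_large `lm` or `stepwise_fit` objects; the smaller
#'   model's terms must be a subset of the larger's.
#' @return One-row tibble with `statistic`, `df1`, `df2`, `p_value`.
#' @export
compare_nested <- function(fit_small, fit_large) {
  small <- if (inherits(fit_small, "stepwise_fit")) fit_small$fit else fit_small
  large <- if (inherits(fit_large, "stepwise_fit")) fit_large$fit else fit_large
  if (!inherits(small, "lm") || !inherits(large, "lm")) {
    validation_error("compare_nested expects lm or stepwise_fit objects")
  }
  if (stats::nobs(small) != stats::nobs(large)) {
    validation_error("models were fit on different sample sizes")
  }
  t_s <- attr(stats::terms(small), "term.labels")
  t_l <- attr(stats::terms(large), "term.labels")
  norm <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                             function(p) paste(sort(p), collapse = ":"), "")
  if (!all(norm(t_s) %in% norm(t_l))) {
    validation_error("fit_small is not nested in fit_large")
  }
  rss_s <- sum(stats::residuals(small)^2)
  rss_l <- sum(stats::residuals(large)^2)
  df_s <- stats::df.residual(small)
  df_l <- stats::df.residual(large)
  ddf <- df_s - df_l
  if (ddf == 0) {
    return(tibble(statistic = 0, df1 = 0L, df2 = df_l, p_value = 1))
  }
  f <- max(0, ((rss_s - rss_l) / ddf) / (rss_l / df_l))
  tibble(statistic = f, df1 = as.integer(ddf), df2 = as.integer(df_l),
         p_value = pf(f, ddf, df_l, lower.tail = FALSE))
}

#' Two-SNP additive genetic + environment fit
#'
#' Fits `beta ~ snp_i + snp_j + hba1c + age` for one pair of distinct SNPs
#' and reports the coefficient table plus a nominal retention flag at
#' alpha = 0.05 for each SNP term.
#'
#' @param target_beta Numeric vector of target-probe betas.
#' @param snp_i,snp_j Dosage vectors (must not be identical columns).
#' @param samples Sample tibble with `hba1c` and `age`.
#' @param alpha Retention alpha (default 0.05).
#' @return List with the `lm` fit, a tidy coefficient tibble (with
#'   `retained` flags for the SNP terms), `adj_r2` and `n_used`.
#' @export
fit_ge_pair <- function(target_beta, snp_i, snp_j, samples, alpha = 0.05) {
  if (identical(as.numeric(snp_i), as.numeric(snp_j))) {
    validation_error("snp_i and snp_j are identical")
  }
  samples <- as_tibble(samples)
  d <- tibble(beta = as.numeric(target_beta), snp_i = as.numeric(snp_i),
              snp_j = as.numeric(snp_j), hba1c = as.numeric(samples$hba1c),
              age = as.numeric(samples$age))
  d <- d[complete.cases(d), ]
  fit <- lm(beta ~ snp_i + snp_j + hba1c + age, data = d)
  sm <- summary(fit)$coefficients
  coefs <- tibble(term = rownames(sm), estimate = sm[, 1],
                  std_error = sm[, 2], statistic = sm[, 3], p_value = sm[, 4])
  coefs$retained <- coefs$term %in% c("snp_i", "snp_j") & coefs$p_value < alpha
  list(fit = fit, coefficients = coefs,
       adj_r2 = summary(fit)$adj.r.squared, n_used = nrow(d))
}

#' Genotype-stratified methylation comparisons
#'
#' For the whole cohort and within each glycemic stratum, compares
#' target-probe methylation between genotype groups (dosage 0/1/2) pairwise
#' with Welch's t-test, Holm-adjusts p-values over the pairwise family within
#' each stratum, and reports the difference in mean beta in percentage points
#' together with a standardized mean difference (pooled-SD) and its bootstrap
#' percentile 95 % confidence interval.
#'
#' @param target_beta Numeric beta vector.
#' @param snp Additive dosage vector.
#' @param samples Sample tibble with `glycemic_class`.
#' @param min_group Minimum subjects per genotype group for a pair to be
#'   tested (default 3; smaller groups are reported untested).
#' @param boot Bootstrap resamples for the effect-size CI (default 2000).
#' @param seed Seed for the bootstrap.
#' @return Tibble with one row per stratum and genotype pair: group sizes,
#'   `delta_beta_pct`, `statistic`, `p_value`, `p_holm`, `smd`, `smd_low`,
#'   `smd_high`, `tested`.
#' @export
stratified_genotype_comparison <- function(target_beta, snp, samples,
                                           min_group = 3, boot = 2000,
                                           seed = 1L) {
  samples <- as_tibble(samples)
  beta <- as.numeric(target_beta)
  dose <- as.numeric(snp)
  strata <- list(cohort = rep(TRUE, nrow(samples)))
  for (g in c("control", "prediabetic", "diabetic")) {
    strata[[g]] <- as.character(samples$glycemic_class) == g
  }
  set.seed(derive_seed(seed, 97))
  rows <- list()
  for (sname in names(strata)) {
    in_s <- strata[[sname]] & !is.na(beta) & !is.na(dose)
    groups <- sort(unique(dose[in_s]))
    if (length(groups) < 2) {
      warn(sprintf("stratum '%s': fewer than 2 genotype groups", sname))
      next
    }
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    stratum_rows <- list()
    for (pr in pairs) {
      x <- beta[in_s & dose == pr[1]]
      y <- beta[in_s & dose == pr[2]]
      tested <- length(x) >= min_group && length(y) >= min_group
      if (tested) {
        tt <- stats::t.test(x, y)
        sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                     (length(x) + length(y) - 2))
        smd <- if (sp > 0) abs(mean(x) - mean(y)) / sp else 0
        bs <- vapply(seq_len(boot), function(b) {
          xb <- sample(x, replace = TRUE)
          yb <- sample(y, replace = TRUE)
          spb <- sqrt(((length(xb) - 1) * var(xb) + (length(yb) - 1) * var(yb)) /
                        (length(xb) + length(yb) - 2))
          if (is.na(spb) || spb == 0) return(0)
          abs(mean(xb) - mean(yb)) / spb
        }, numeric(1))
        ci <- quantile(bs, c(0.025, 0.975), names = FALSE)
        stratum_rows[[length(stratum_rows) + 1]] <- tibble(
          stratum = sname, group1 = pr[1], group2 = pr[2],
          n1 = length(x), n2 = length(y),
          delta_beta_pct = 100 * (mean(x) - mean(y)),
          statistic = unname(tt$statistic), p_value = tt$p.value,
          smd = smd, smd_low = ci[1], smd_high = ci[2], tested = TRUE)
      } else {
        stratum_rows[[length(stratum_rows) + 1]] <- tibble(
          stratum = sname, group1 = pr[1], group2 = pr[2],
          n1 = length(x), n2 = length(y),
          delta_beta_pct = 100 * (mean(x) - mean(y)),
          statistic = NA_real_, p_value = NA_real_,
          smd = NA_real_, smd_low = NA_real_, smd_high = NA_real_,
          tested = FALSE)
      }
    }
    st <- bind_rows(stratum_rows)
    st$p_holm <- NA_real_
    tested_idx <- which(st$tested)
    if (length(tested_idx)) {
      st$p_holm[tested_idx] <- adjust_pvalues(st$p_value[tested_idx], "holm")
    }
    rows[[length(rows) + 1]] <- st
  }
  if (!length(rows)) {
    return(tibble(stratum = character(0), group1 = numeric(0),
                  group2 = numeric(0), n1 = integer(0), n2 = integer(0),
                  delta_beta_pct = numeric(0), statistic = numeric(0),
                  p_value = numeric(0), smd = numeric(0), smd_low = numeric(0),
                  smd_high = numeric(0), tested = logical(0),
                  p_holm = numeric(0)))
  }
  bind_rows(rows)
}
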