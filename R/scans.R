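# Genome-wide least-squares scans around the focal CpG.

#' Adjust p-values for multiple testing
#'
#' Thin validating wrapper around [stats::p.adjust()] exposing the three
#' corrections used across the scan families: Benjamini-Hochberg step-up FDR,
#' single-step Bonferroni, and step-down Holm. All methods are monotone and
#' clipped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method One of `"bh"`, `"bonferroni"`, `"holm"`.
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values, same length as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03), "bh")
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni", "holm"),
                           m = length(p)) {
  method <- arg_match(method)
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    validation_error("p-values must be numeric in [0, 1]")
  }
  p.adjust(p, method = c(bh = "BH", bonferroni = "bonferroni",
                         holm = "holm")[[method]], n = m)
}

#' Proximity rule anchored at the target CpG
#'
#' Defines the cis window around the focal probe: SNPs on the same chromosome
#' within `cis_window` base pairs (inclusive) are `cis`; same chromosome
#' beyond the window is `long_cis`; different chromosome is `trans`.
#'
#' @param chrom Target chromosome.
#' @param pos Target position (1-based).
#' @param cis_window Window in bp, default 1 Mb.
#' @export
proximity_rule <- function(chrom, pos, cis_window = 1e6) {
  if (cis_window <= 0) config_error("cis_window must be > 0")
  structure(list(chrom = chrom, pos = pos, cis_window = cis_window),
            class = "proximity_rule")
}

#' Classify SNPs as cis / long-range cis / trans
#'
#' @param rule A [proximity_rule()].
#' @param chrom,pos Vectors of SNP coordinates.
#' @return Factor with levels `cis`, `long_cis`, `trans`.
#' @export
classify_proximity <- function(rule, chrom, pos) {
  stopifnot(inherits(rule, "proximity_rule"))
  same <- as.character(chrom) == as.character(rule$chrom)
  dist <- abs(pos - rule$pos)
  out <- ifelse(!same, "trans", ifelse(dist <= rule$cis_window, "cis", "long_cis"))
  factor(out, levels = c("cis", "long_cis", "trans"))
}

# numeric design columns from a sample table; factors/characters/logicals are
# coded 0/1/2... by level order (sex: female = 0, male = 1 under default
# alphabetic levels is avoided by coding explicitly below)
sample_covariate <- function(samples, var) {
  v <- samples[[var]]
  if (is.null(v)) validation_error(sprintf("samples is missing column '%s'", var))
  if (var == "sex" && (is.character(v) || is.factor(v))) {
    return(as.numeric(as.character(v) == "male"))  # female = 0, male = 1
  }
  if (is.logical(v)) return(as.numeric(v))
  if (is.factor(v)) return(as.numeric(v) - 1)
  as.numeric(v)
}

new_scan_result <- function(rows, model_tag) {
  out <- arrange(rows, .data$focal_p, .data$feature_id)
  out$model_tag <- rep(model_tag, length.out = nrow(out))
  class(out) <- c("scan_result", class(tibble()))
  out
}

# shared per-feature OLS loop; build_design maps (feature, response,
# covariates) to the fitted design, focal_term names the ranked coefficient.
scan_core <- function(feature_mat, y, covar_mat, build_design, focal_term,
                      extra_fun = NULL) {
  ids <- colnames(feature_mat)
  n_feat <- length(ids)
  n_used <- integer(n_feat)
  estimate <- std_error <- statistic <- focal_p <- adj_r2 <-
    rep(NA_real_, n_feat)
  focal_p[] <- 1
  note <- character(n_feat)
  coefs <- p_terms <- vector("list", n_feat)
  extra <- if (is.null(extra_fun)) NULL else rep(NA_real_, n_feat)
  extra_name <- NULL
  base_ok <- !is.na(y) & complete.cases(covar_mat)
  for (j in seq_len(n_feat)) {
    x <- feature_mat[, j]
    ok <- base_ok & !is.na(x)
    xs <- x[ok]
    n_used[j] <- sum(ok)
    if (n_used[j] < 4 || length(unique(xs)) < 2) {
      note[j] <- "degenerate_feature"
      next
    }
    X <- build_design(xs, y[ok], covar_mat[ok, , drop = FALSE])
    fit <- fast_ols(X$design, X$response)
    fp <- fit$p[[focal_term]]
    if (is.na(fp)) {
      note[j] <- "aliased_focal_term"
      fp <- 1
    } else {
      estimate[j] <- fit$coef[[focal_term]]
      std_error[j] <- fit$se[[focal_term]]
      statistic[j] <- fit$t[[focal_term]]
    }
    focal_p[j] <- fp
    adj_r2[j] <- fit$adj_r2
    coefs[[j]] <- fit$coef
    p_terms[[j]] <- fit$p
    if (!is.null(extra_fun)) {
      ex <- extra_fun(fit)
      extra_name <- names(ex)[1]
      extra[j] <- ex[[1]]
    }
  }
  out <- tibble(feature_id = ids, n_used = n_used, estimate = estimate,
                std_error = std_error, statistic = statistic,
                focal_p = focal_p, adj_r2 = adj_r2,
                coefs = coefs, p_terms = p_terms, note = note)
  if (!is.null(extra_fun) && !is.null(extra_name)) out[[extra_name]] <- extra
  out
}

#' Epigenome-wide association scan of the exposure on methylation
#'
#' For each probe, fits `hba1c ~ beta + age + sex + bmi` by ordinary least
#' squares (complete cases per probe). The focal p-value is the
#' methylation-term p; Benjamini-Hochberg q-values are computed across all
#' scanned probes. Constant probes are flagged with `focal_p = 1` rather than
#' raising an error.
#'
#' @param meth A [methylation_matrix()].
#' @param samples Sample tibble with `hba1c`, `age`, `sex`, `bmi` (rows aligned
#'   with the methylation matrix).
#' @return A `scan_result` tibble ordered by focal p (ties by probe id), with
#'   probe coordinates, per-term coefficients/p-values (list columns), adjusted
#'   R-squared and `q_value`.
#' @export
ewas_scan <- function(meth, samples) {
  stopifnot(inherits(meth, "methylation_matrix"))
  samples <- as_tibble(samples)
  check_alignment(rownames(meth$betas), samples$sample_id, "methylation")
  y <- as.numeric(samples$hba1c)
  covar <- cbind(age = sample_covariate(samples, "age"),
                 sex = sample_covariate(samples, "sex"),
                 bmi = sample_covariate(samples, "bmi"))
  build <- function(x, yy, cv) {
    list(design = cbind(`(Intercept)` = 1, beta = x, cv), response = yy)
  }
  rows <- scan_core(meth$betas, y, covar, build, "beta")
  rows <- left_join(rows,
                    select(meth$manifest, feature_id = "probe_id",
                           "chrom", "pos"),
                    by = "feature_id")
  rows$proximity <- factor(NA, levels = c("cis", "long_cis", "trans"))
  rows$q_value <- adjust_pvalues(rows$focal_p, "bh")
  new_scan_result(rows, "ewas")
}

#' Scan of polymorphic-target probes against the exposure
#'
#' Identical model to [ewas_scan()] but restricted to probes flagged as
#' having a SNP at the target site (`polymorphic` column of the probe
#' manifest), with Benjamini-Hochberg correction applied within this family
#' only.
#'
#' @inheritParams ewas_scan
#' @return A `scan_result` tibble (empty, with a warning, if no probe is
#'   flagged).
#' @export
polymorphic_scan <- function(meth, samples) {
  stopifnot(inherits(meth, "methylation_matrix"))
  if (!"polymorphic" %in% names(meth$manifest)) {
    validation_error("probe manifest has no 'polymorphic' column")
  }
  keep <- which(isTRUE_vec(meth$manifest$polymorphic))
  if (length(keep) == 0) {
    warn("no polymorphic-flagged probes; returning empty scan")
    return(new_scan_result(ewas_scan_empty(), "polymorphic"))
  }
  sub <- methylation_matrix(meth$betas[, keep, drop = FALSE],
                            meth$manifest[keep, , drop = FALSE])
  res <- ewas_scan(sub, samples)
  res$model_tag <- "polymorphic"
  res$q_value <- adjust_pvalues(res$focal_p, "bh")
  new_scan_result(res, "polymorphic")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

ewas_scan_empty <- function() {
  tibble(feature_id = character(0), n_used = integer(0),
         estimate = numeric(0), std_error = numeric(0),
         statistic = numeric(0), focal_p = numeric(0), adj_r2 = numeric(0),
         coefs = list(), p_terms = list(), note = character(0),
         chrom = character(0), pos = numeric(0),
         proximity = factor(character(0), levels = c("cis", "long_cis", "trans")),
         q_value = numeric(0))
}

check_alignment <- function(row_ids, sample_ids, what) {
  if (!is.null(row_ids) && !is.null(sample_ids) &&
      !identical(as.character(row_ids), as.character(sample_ids))) {
    validation_error(sprintf("%s rows are not aligned with the sample table", what))
  }
}

#' Genome-wide meQTL scan for the target CpG
#'
#' For each SNP, fits `beta ~ dosage + age` by ordinary least squares and
#' partitions SNPs by proximity to the target probe (cis within the 1 Mb
#' window, long-range cis beyond it on the same chromosome, trans elsewhere).
#' Monomorphic SNPs (after complete-case deletion) are flagged with
#' `focal_p = 1`.
#'
#' @param target_beta Numeric vector of target-probe beta values, aligned with
#'   `samples` and the genotype rows.
#' @param geno A [genotype_matrix()].
#' @param samples Sample tibble with `age`.
#' @param rule A [proximity_rule()] giving the target probe's coordinates.
#' @return A `scan_result` tibble with `proximity`, `adj_r2` and a nominal
#'   `retained` flag (`focal_p < 0.05`).
#' @export
meqtl_scan <- function(target_beta, geno, samples, rule) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(rule, "proximity_rule"))
  samples <- as_tibble(samples)
  check_alignment(rownames(geno$dosages), samples$sample_id, "genotype")
  covar <- cbind(age = sample_covariate(samples, "age"))
  build <- function(x, yy, cv) {
    list(design = cbind(`(Intercept)` = 1, dosage = x, cv), response = yy)
  }
  rows <- scan_core(geno$dosages, as.numeric(target_beta), covar, build, "dosage")
  rows <- left_join(rows,
                    select(geno$manifest, feature_id = "snp_id", "chrom", "pos"),
                    by = "feature_id")
  rows$proximity <- classify_proximity(rule, rows$chrom, rows$pos)
  rows$retained <- rows$focal_p < 0.05 & rows$note == ""
  new_scan_result(rows, "meqtl")
}

#' Genome-wide SNP-by-exposure (GxE) interaction scan
#'
#' For each SNP, fits `beta ~ dosage * hba1c + age` (interaction plus both
#' main effects); the interaction-term p-value is used for selection and
#' ranking, and the adjusted R-squared of the full model is reported.
#'
#' @inheritParams meqtl_scan
#' @return A `scan_result` tibble; `estimate`/`focal_p` refer to the
#'   `dosage:hba1c` interaction term.
#' @export
gxe_scan <- function(target_beta, geno, samples, rule = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  samples <- as_tibble(samples)
  check_alignment(rownames(geno$dosages), samples$sample_id, "genotype")
  covar <- cbind(age = sample_covariate(samples, "age"),
                 hba1c = as.numeric(samples$hba1c))
  build <- function(x, yy, cv) {
    list(design = cbind(`(Intercept)` = 1, dosage = x,
                        hba1c = cv[, "hba1c"], age = cv[, "age"],
                        `dosage:hba1c` = x * cv[, "hba1c"]),
         response = yy)
  }
  rows <- scan_core(geno$dosages, as.numeric(target_beta), covar, build,
                    "dosage:hba1c")
  rows <- left_join(rows,
                    select(geno$manifest, feature_id = "snp_id", "chrom", "pos"),
                    by = "feature_id")
  rows$proximity <- if (is.null(rule)) {
    factor(NA, levels = c("cis", "long_cis", "trans"))
  } else {
    classify_proximity(rule, rows$chrom, rows$pos)
  }
  rows$retained <- rows$focal_p < 0.05 & rows$note == ""
  new_scan_result(rows, "gxe")
}

#' Genome-wide CpG-by-SNP (GxMeth) interaction scan for the exposure
#'
#' For each SNP, fits `hba1c ~ beta * dosage + age + sex + bmi`. The focal
#' p-value is the interaction-term p, Bonferroni-corrected at family size
#' equal to the number of SNPs tested; the SNP additive (main-effect) p-value
#' is also reported, since both interactive and additive discoveries are of
#' interest.
#'
#' @inheritParams meqtl_scan
#' @param rule Optional [proximity_rule()] for the proximity column.
#' @return A `scan_result` tibble with `bonferroni_p`, `additive_p` and
#'   `significant` (Bonferroni at 0.05).
#' @export
gxmeth_scan <- function(target_beta, geno, samples, rule = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  samples <- as_tibble(samples)
  check_alignment(rownames(geno$dosages), samples$sample_id, "genotype")
  tb <- as.numeric(target_beta)
  covar <- cbind(age = sample_covariate(samples, "age"),
                 sex = sample_covariate(samples, "sex"),
                 bmi = sample_covariate(samples, "bmi"),
                 beta = tb)
  y <- as.numeric(samples$hba1c)
  build <- function(x, yy, cv) {
    list(design = cbind(`(Intercept)` = 1, dosage = x, beta = cv[, "beta"],
                        age = cv[, "age"], sex = cv[, "sex"], bmi = cv[, "bmi"],
                        `beta:dosage` = cv[, "beta"] * x),
         response = yy)
  }
  extra <- function(fit) list(additive_p = unname(fit$p[["dosage"]]))
  rows <- scan_core(geno$dosages, y, covar, build, "beta:dosage", extra)
  rows <- left_join(rows,
                    select(geno$manifest, feature_id = "snp_id", "chrom", "pos"),
                    by = "feature_id")
  rows$proximity <- if (is.null(rule)) {
    factor(NA, levels = c("cis", "long_cis", "trans"))
  } else {
    classify_proximity(rule, rows$chrom, rows$pos)
  }
  rows$bonferroni_p <- adjust_pvalues(rows$focal_p, "bonferroni")
  rows$significant <- rows$bonferroni_p < 0.05
  new_scan_result(rows, "gxmeth")
}

#' @export
print.scan_result <- function(x, ...) {
  tag <- unique(x$model_tag)
  cat(sprintf("<scan_result:%s> %d features\n",
              paste(tag, collapse = ","), nrow(x)))
  NextMethod()
}
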