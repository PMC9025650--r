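# End-to-end orchestration: simulate -> QC/binning -> SEM -> scans ->
# step-wise models -> classifiers, with a fixed artifact layout and a log.

#' Default pipeline configuration
#'
#' Every tunable constant of the analysis is a named key with its
#' conventional default: glycemic bins 5.7/6.5, MAF threshold 0.05, LD
#' pruning 50/5/0.5, SEM multiplier 3, FDR and Bonferroni alpha 0.05,
#' step-wise entry screens (adjusted R-squared 0.03 for meQTL candidates,
#' 0.1550 for interaction candidates), 10x3 repeated stratified CV, 70/30
#' logistic split and top-13 Gini pruning. Override any subset via `...` or
#' load from YAML with [read_pipeline_config()].
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    sim = list(n_subjects = 300, n_probes = 500, n_snps = 2000,
               planted_meqtl = list(list(snp_id = "snp_00042", fraction = 0.04)),
               planted_gxe = list(list(snp_id = "snp_00123", fraction = 0.05)),
               planted_gxmeth = list(list(snp_id = "snp_00777", effect = 8)),
               planted_sem = list(list(probe_id = "cg_00007", n = 3,
                                       direction = "high"))),
    input = list(genotypes = NULL, genotype_manifest = NULL,
                 methylation = NULL, probe_manifest = NULL,
                 phenotypes = NULL),
    stages = list(qc = TRUE, sem = TRUE, scans = TRUE, models = TRUE,
                  classify = TRUE),
    bin_lower = 5.7, bin_upper = 6.5,
    maf_threshold = 0.05,
    ld_window = 50, ld_shift = 5, ld_r2 = 0.5,
    sem_multiplier = 3,
    fdr_alpha = 0.05, bonferroni_alpha = 0.05,
    cis_window = 1e6,
    meqtl_entry_adj_r2 = 0.03, gxe_entry_adj_r2 = 0.1550,
    retention_alpha = 0.05, comparison_alpha = 0.05,
    cv_splits = 10, cv_repeats = 3, holdout_fraction = 0.30,
    top_k = 13, num_trees = 500, decision_threshold = 0.5
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    config_error(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  for (nm in names(overrides)) {
    # sub-configs merge key-by-key, each provided key replacing the default
    # wholesale (planted-effect lists are unnamed and must never deep-merge)
    if (nm %in% c("sim", "input", "stages") && is.list(overrides[[nm]])) {
      sub <- cfg[[nm]]
      sub[names(overrides[[nm]])] <- overrides[[nm]]
      cfg[[nm]] <- sub
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    parse_error(sprintf("cannot parse config %s: %s", path, conditionMessage(e)))
  })
  if (!is.list(raw)) parse_error(sprintf("config %s is not a YAML mapping", path))
  do.call(pipeline_config, raw)
}

pipeline_log <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", "epigx", sprintf(fmt, ...))
  writeLines(msg, con)
  inform(msg)
}

#' Run the integrated genetic-epigenetic pipeline
#'
#' Executes the stages end to end — simulation (or file input), genotype QC
#' and phenotype binning/exclusion, stochastic-epimutation detection and
#' filtering, the EWAS/polymorphic/meQTL/GxE/GxMeth scans, step-wise
#' integrated modeling, and classification — writing each stage's TSV/JSON
#' artifacts plus a parameter-echo log into `out_dir`. Re-running with the
#' same config is reproducible.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("epigx_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  pipeline_log(con, "seed = %d; R %s; epigx %s", config$seed,
               getRversion(),
               as.character(utils::packageVersion("epigx")))
  pipeline_log(con, "config: %s", jsonlite::toJSON(unclass(
    config[setdiff(names(config), c("sim", "input"))]), auto_unbox = TRUE))

  results <- list(config = config)

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$input$genotypes)) {
    geno <- read_genotypes(config$input$genotypes, config$input$genotype_manifest)
    meth <- read_methylation(config$input$methylation, config$input$probe_manifest)
    samples <- read_samples(config$input$phenotypes)
    truth <- NULL
    target_probe <- meth$manifest$probe_id[1]
    pipeline_log(con, "loaded cohort from files: %d samples", nrow(samples))
  } else {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    sc <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(sc)
    geno <- cohort$geno
    meth <- cohort$meth
    samples <- cohort$samples
    truth <- cohort$truth
    target_probe <- sc$target_probe_id
    write_genotypes(geno, file.path(out_dir, "genotypes.tsv"),
                    file.path(out_dir, "snp_manifest.tsv"))
    write_methylation(meth, file.path(out_dir, "methylation.tsv"),
                      file.path(out_dir, "probe_manifest.tsv"))
    readr::write_tsv(truth$effects, file.path(out_dir, "ground_truth_effects.tsv"))
    readr::write_tsv(truth$sem, file.path(out_dir, "ground_truth_sem.tsv"))
    pipeline_log(con, "simulated cohort: %d subjects, %d probes, %d SNPs",
                 nrow(samples), ncol(meth$betas), ncol(geno$dosages))
  }
  results$truth <- truth

  # ---- QC / binning -------------------------------------------------------
  if (isTRUE(config$stages$qc)) {
    samples$glycemic_class <- bin_glycemic_class(samples$hba1c,
                                                 config$bin_lower,
                                                 config$bin_upper)
    samples <- apply_exclusions(samples)
    n_excl <- sum(samples$excluded)
    keep <- !samples$excluded
    samples <- samples[keep, , drop = FALSE]
    geno <- genotype_matrix(geno$dosages[keep, , drop = FALSE], geno$manifest)
    meth <- methylation_matrix(meth$betas[keep, , drop = FALSE], meth$manifest)
    geno <- filter_maf(geno, config$maf_threshold)
    geno <- ld_prune(geno, config$ld_window, config$ld_shift, config$ld_r2)
    pipeline_log(con, "QC: excluded %d subjects; %d SNPs after MAF+LD",
                 n_excl, ncol(geno$dosages))
  }
  write_samples(samples, file.path(out_dir, "samples.tsv"))
  results$samples <- samples

  # ---- SEM ----------------------------------------------------------------
  if (isTRUE(config$stages$sem)) {
    calls <- detect_sems(meth, config$sem_multiplier)
    burden <- sem_burden(calls)
    readr::write_tsv(as_tibble(calls), file.path(out_dir, "sem_calls.tsv"))
    enrich <- tryCatch(sem_enrichment(calls, samples), error = function(e) NULL)
    jsonlite::write_json(
      list(summary = burden$summary,
           enrichment = if (is.null(enrich)) "not_estimable" else enrich),
      file.path(out_dir, "sem_summary.json"), auto_unbox = TRUE, digits = NA)
    # the focal probe is the anchor of every downstream scan and is kept even
    # if it carries calls: fence-exceeding values at the target reflect the
    # planted dose response in the exposure tail, not stochastic epimutation
    drop_set <- setdiff(unique(as_tibble(calls)$probe_id), target_probe)
    if (target_probe %in% as_tibble(calls)$probe_id) {
      pipeline_log(con, "SEM: target probe had calls; retained as scan anchor")
    }
    meth <- filter_sem_probes(meth, calls, probe_set = drop_set)
    pipeline_log(con, "SEM: %d calls across %d probes; %d probes retained",
                 burden$summary$n_calls, burden$summary$n_probes,
                 ncol(meth$betas))
    results$sem <- list(calls = calls, burden = burden, enrichment = enrich)
  }

  target_idx <- match(target_probe, meth$manifest$probe_id)
  if (is.na(target_idx)) {
    abort("target probe was removed upstream; cannot continue scans",
          class = "epigx_pipeline_error")
  }
  target_beta <- meth$betas[, target_idx]
  rule <- proximity_rule(meth$manifest$chrom[target_idx],
                         meth$manifest$pos[target_idx], config$cis_window)

  # ---- scans --------------------------------------------------------------
  if (isTRUE(config$stages$scans)) {
    scans <- list(
      ewas = ewas_scan(meth, samples),
      polymorphic = suppressWarnings(polymorphic_scan(meth, samples)),
      meqtl = meqtl_scan(target_beta, geno, samples, rule),
      gxe = gxe_scan(target_beta, geno, samples, rule),
      gxmeth = gxmeth_scan(target_beta, geno, samples, rule)
    )
    for (nm in names(scans)) {
      readr::write_tsv(select(as_tibble(scans[[nm]]), -"coefs", -"p_terms"),
                       file.path(out_dir, sprintf("scan_%s.tsv", nm)))
    }
    pipeline_log(con, "scans: ewas %d probes; meqtl/gxe/gxmeth %d SNPs",
                 nrow(scans$ewas), nrow(scans$meqtl))
    results$scans <- scans
  }

  # ---- step-wise models ---------------------------------------------------
  if (isTRUE(config$stages$models) && isTRUE(config$stages$scans)) {
    d <- as_tibble(as.data.frame(geno$dosages))
    d$beta <- target_beta
    d$hba1c <- samples$hba1c
    d$age <- samples$age
    meqtl_cand <- results$scans$meqtl |>
      filter(.data$retained, .data$adj_r2 >= config$meqtl_entry_adj_r2) |>
      pull("feature_id")
    gxe_cand <- results$scans$gxe |>
      filter(.data$retained, .data$adj_r2 >= config$gxe_entry_adj_r2) |>
      pull("feature_id")
    swc <- stepwise_config(retention_alpha = config$retention_alpha,
                           comparison_alpha = config$comparison_alpha)
    m_genetic <- stepwise_build(d, "beta", meqtl_cand, base_terms = "age",
                                config = swc)
    # G+E = the final genetic model with the exposure added, so the two fits
    # are nested and comparable by the extra-sum-of-squares F-test
    m_ge <- stepwise_build(d, "beta", character(0),
                           base_terms = c("age", "hba1c", m_genetic$retained),
                           config = swc)
    m_integrated <- stepwise_build(
      d, "beta", c(meqtl_cand, paste0(gxe_cand, ":hba1c")),
      base_terms = c("age", "hba1c"), config = swc)
    for (pair in list(c("genetic", "m_genetic"), c("ge", "m_ge"),
                      c("integrated", "m_integrated"))) {
      fit <- get(pair[2])
      readr::write_tsv(tidy(fit),
                       file.path(out_dir, sprintf("model_%s.tsv", pair[1])))
      jsonlite::write_json(glance(fit),
                           file.path(out_dir, sprintf("model_%s.json", pair[1])),
                           auto_unbox = TRUE, digits = NA)
    }
    cmp <- compare_nested(m_genetic, m_ge)
    pipeline_log(con,
                 "models: genetic adjR2=%.4f, G+E adjR2=%.4f (F p=%.3g), integrated adjR2=%.4f",
                 m_genetic$adj_r2, m_ge$adj_r2, cmp$p_value,
                 m_integrated$adj_r2)
    results$models <- list(genetic = m_genetic, ge = m_ge,
                           integrated = m_integrated, comparison = cmp)
  }

  # ---- classification -----------------------------------------------------
  if (isTRUE(config$stages$classify)) {
    sub <- samples$glycemic_class %in% c("control", "diabetic")
    labels <- droplevels(samples$glycemic_class[sub])
    covars <- tibble(age = samples$age[sub],
                     sex = as.numeric(samples$sex[sub] == "male"),
                     bmi = samples$bmi[sub])
    cvc <- cv_config(n_splits = config$cv_splits, n_repeats = config$cv_repeats,
                     holdout_fraction = config$holdout_fraction,
                     top_k = config$top_k, num_trees = config$num_trees,
                     decision_threshold = config$decision_threshold,
                     seed = config$seed)
    base_rep <- balanced_rf_cv(covars, labels, cvc, model_tag = "covariates")
    feat <- covars
    feat$cg_target <- target_beta[sub]
    cpg_rep <- balanced_rf_cv(feat, labels, cvc, model_tag = "covariates_cpg")
    gxmeth_snps <- results$scans$gxmeth |>
      filter(.data$significant) |> pull("feature_id")
    full <- feat
    for (s in gxmeth_snps) full[[s]] <- geno$dosages[sub, s]
    sel <- implicit_feature_select(full, labels, cvc,
                                   always_keep = names(feat))
    pruned <- gini_prune(full[, sel, drop = FALSE], labels, cvc)
    reports <- list(covariates = base_rep, covariates_cpg = cpg_rep,
                    pruned = pruned$report)
    jsonlite::write_json(lapply(reports, glance),
                         file.path(out_dir, "classifier_report.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_tsv(pruned$ranking, file.path(out_dir, "gini_ranking.tsv"))
    pipeline_log(con,
                 "classify: covariate AUC=%.3f, +CpG AUC=%.3f, pruned AUC=%.3f",
                 base_rep$metrics$auc, cpg_rep$metrics$auc,
                 pruned$report$metrics$auc)
    results$classify <- list(reports = reports, selected = sel,
                             ranking = pruned$ranking)
  }

  pipeline_log(con, "pipeline complete; artifacts in %s", out_dir)
  invisible(results)
}
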