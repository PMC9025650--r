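# Synthetic cohort generator with planted effects and known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: Hardy-Weinberg genotypes over a MAF spectrum, a right-skewed
# glycemic exposure built from three clinical strata, beta-distributed
# (logit-normal) methylation with a dose-dependent exposure effect at one
# target probe, planted cis/trans meQTL and SNP-by-exposure interaction
# effects of stated latent variance fractions, planted fence-exceeding
# stochastic epimutations, and an imbalanced three-class glycemic status
# derived from HbA1c. One seed in the config determines every draw.

#' Reference cohort summary statistics
#'
#' Group-level summary statistics (group sizes, age, HbA1c, BMI, sex and
#' self-report flag rates) transcribed from a published African American
#' cohort study of HbA1c and cg19693031 methylation. Used as the simulator's
#' default stratum parameters and for cohort bookkeeping checks.
#'
#' @return A tibble with one row per glycemic group.
#' @export
cohort_reference <- function() {
  path <- system.file("extdata", "cohort_reference.tsv", package = "epigx")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator. Planted effects are
#' named lists: `planted_meqtl` and `planted_gxe` entries are
#' `list(snp_id =, fraction =)` with `fraction` the latent-scale variance
#' fraction of the target-probe methylation explained by the term;
#' `planted_gxmeth` entries are `list(snp_id =, effect =)` with `effect` on
#' the exposure (HbA1c %) scale per unit of centred dosage-times-centred-beta;
#' `planted_sem` entries are `list(probe_id =, n =, direction =)` with
#' `direction` in `{"high", "low"}`.
#'
#' @param n_subjects Cohort size (>= 30). Default 506.
#' @param n_probes,n_snps Array sizes.
#' @param n_chromosomes Chromosomes over which features are scattered.
#' @param target_probe_id,target_chrom,target_pos Focal probe identity and
#'   coordinates (defaults anchor it on chromosome 1).
#' @param maf_range Pair of minor-allele frequencies in (0, 0.5].
#' @param missing_rate Per-entry genotype missingness rate (planted SNPs are
#'   always complete).
#' @param class_proportions Named triple (control, prediabetic, diabetic)
#'   summing to 1; defaults to the reference cohort's 142/274/90 split.
#' @param exposure_variance_fraction,age_variance_fraction Latent variance
#'   fractions of target-probe methylation explained by HbA1c and age.
#' @param latent_scale Logistic link scale mapping the unit-variance latent
#'   score to the logit-beta scale; the default 0.4 keeps betas in the
#'   near-linear band around `target_mean_beta` so latent fractions
#'   approximate observed R-squared.
#' @param target_mean_beta Anchor methylation level of the focal probe.
#' @param polymorphic_fraction Fraction of background probes flagged as
#'   having a SNP at the target site.
#' @param planted_meqtl,planted_gxe,planted_gxmeth,planted_sem Planted
#'   effects; see Details.
#' @param seed Integer seed; fully determines the output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 506, n_probes = 500, n_snps = 2000,
                       n_chromosomes = 22,
                       target_probe_id = "cg19693031",
                       target_chrom = "1", target_pos = 145441552,
                       maf_range = c(0.05, 0.5), missing_rate = 0,
                       class_proportions = c(control = 142, prediabetic = 274,
                                             diabetic = 90) / 506,
                       exposure_variance_fraction = 0.15,
                       age_variance_fraction = 0.02,
                       latent_scale = 0.4, target_mean_beta = 0.66,
                       polymorphic_fraction = 0.05,
                       planted_meqtl = list(), planted_gxe = list(),
                       planted_gxmeth = list(), planted_sem = list(),
                       seed = 1L) {
  if (!is.numeric(maf_range) || length(maf_range) != 2 ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    config_error("maf_range must be an increasing pair in (0, 0.5]")
  }
  if (n_subjects < 30) config_error("n_subjects must be >= 30")
  if (abs(sum(class_proportions) - 1) > 1e-8 || length(class_proportions) != 3) {
    config_error("class_proportions must be a triple summing to 1")
  }
  fracs <- c(exposure_variance_fraction, age_variance_fraction,
             vapply(planted_meqtl, function(e) e$fraction, numeric(1)),
             vapply(planted_gxe, function(e) e$fraction, numeric(1)))
  if (any(fracs < 0 | fracs >= 1) || sum(fracs) >= 1) {
    config_error("variance fractions must lie in [0, 1) and sum to < 1")
  }
  for (s in planted_sem) {
    if (!s$direction %in% c("high", "low")) {
      config_error("planted_sem direction must be 'high' or 'low'")
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_probes = as.integer(n_probes),
    n_snps = as.integer(n_snps), n_chromosomes = as.integer(n_chromosomes),
    target_probe_id = target_probe_id, target_chrom = as.character(target_chrom),
    target_pos = target_pos, maf_range = maf_range,
    missing_rate = missing_rate, class_proportions = class_proportions,
    exposure_variance_fraction = exposure_variance_fraction,
    age_variance_fraction = age_variance_fraction,
    latent_scale = latent_scale, target_mean_beta = target_mean_beta,
    polymorphic_fraction = polymorphic_fraction,
    planted_meqtl = planted_meqtl, planted_gxe = planted_gxe,
    planted_gxmeth = planted_gxmeth, planted_sem = planted_sem,
    seed = as.integer(seed)
  ), class = "sim_config")
}

snp_ids <- function(n) sprintf("snp_%05d", seq_len(n))
probe_ids_for <- function(config) {
  ids <- sprintf("cg_%05d", seq_len(config$n_probes - 1L))
  c(config$target_probe_id, ids)
}
sample_ids_for <- function(n) sprintf("S%04d", seq_len(n))

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each SNP's minor-allele frequency is drawn uniformly from
#' `config$maf_range` and dosages are binomial(2, MAF) per subject
#' (Hardy-Weinberg proportions). The manifest scatters SNPs uniformly over
#' `n_chromosomes` chromosomes; columns are ordered by chromosome and
#' position. SNPs named in any planted-effect list never receive missing
#' entries.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1))
  n <- config$n_subjects
  m <- config$n_snps
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  dos <- matrix(rbinom(n * m, 2, rep(maf, each = n)), nrow = n, ncol = m)
  chrom <- as.character(sample.int(config$n_chromosomes, m, replace = TRUE))
  pos <- sample.int(2.4e8, m, replace = TRUE)
  ord <- order(as.integer(chrom), pos)
  dos <- dos[, ord, drop = FALSE]
  man <- tibble(snp_id = snp_ids(m), chrom = chrom[ord], pos = pos[ord],
                a1 = "A", a2 = "B", maf = maf[ord])
  colnames(dos) <- man$snp_id
  rownames(dos) <- sample_ids_for(n)
  if (config$missing_rate > 0) {
    protected <- unlist(lapply(c(config$planted_meqtl, config$planted_gxe,
                                 config$planted_gxmeth),
                               function(e) e$snp_id))
    miss <- matrix(runif(n * m) < config$missing_rate, n, m)
    miss[, man$snp_id %in% protected] <- FALSE
    dos[miss] <- NA
  }
  genotype_matrix(dos, man)
}

planted_design_column <- function(type, snp, hba1c) {
  x <- switch(type,
              meqtl = snp,
              gxe = (snp - mean(snp)) * (hba1c - mean(hba1c)))
  x - mean(x)
}

#' Simulate phenotypes, methylation and ground truth
#'
#' Draws the glycemic class from `class_proportions`, HbA1c from a truncated
#' normal within each class's clinical bin (component means and spreads from
#' [cohort_reference()]), age/sex/BMI from the per-class reference marginals,
#' and self-report flags at the reference rates. The target-probe beta is a
#' logistic-bounded linear combination of centred exposure, age, planted SNP
#' main effects and SNP-by-exposure interactions plus Gaussian noise on the
#' logit (latent) scale, with each planted term scaled to explain its
#' configured variance fraction of the unit-variance latent score.
#' Planted CpG-by-SNP (GxMeth) terms then perturb HbA1c on the exposure
#' scale, and the glycemic class is re-binned from the final HbA1c.
#' Background probes are null logit-normal noise; probes named in
#' `planted_sem` carry the requested number of outliers placed strictly
#' outside the 3xIQR fences of the probe's remaining values.
#'
#' @param config A [sim_config()].
#' @param geno A [genotype_matrix()] produced by [simulate_genotypes()] from
#'   the same config.
#' @return List with `samples` (tibble), `meth` ([methylation_matrix()]) and
#'   `truth` (list of `effects` and `sem` tibbles).
#' @export
simulate_phenotypes_and_methylation <- function(config, geno) {
  stopifnot(inherits(config, "sim_config"), inherits(geno, "genotype_matrix"))
  planted_snps <- unlist(lapply(c(config$planted_meqtl, config$planted_gxe,
                                  config$planted_gxmeth),
                                function(e) e$snp_id))
  missing_planted <- setdiff(planted_snps, geno$manifest$snp_id)
  if (length(missing_planted)) {
    config_error(paste("planted SNP id(s) not in manifest:",
                       paste(missing_planted, collapse = ", ")))
  }
  probe_ids <- probe_ids_for(config)
  missing_probes <- setdiff(
    vapply(config$planted_sem, function(e) e$probe_id, character(1)),
    setdiff(probe_ids, config$target_probe_id)
  )
  if (length(missing_probes)) {
    config_error(paste("planted SEM probe id(s) not in manifest:",
                       paste(missing_probes, collapse = ", ")))
  }

  set.seed(derive_seed(config$seed, 2))
  n <- config$n_subjects
  ref <- cohort_reference()
  cls_levels <- c("control", "prediabetic", "diabetic")
  cls <- sample(cls_levels, n, replace = TRUE, prob = config$class_proportions)
  ref_row <- match(cls, ref$group)

  bin_bounds <- list(control = c(3.8, 5.7), prediabetic = c(5.7 + 1e-6, 6.5 - 1e-6),
                     diabetic = c(6.5, 14))
  hba1c <- numeric(n)
  for (g in cls_levels) {
    idx <- which(cls == g)
    if (!length(idx)) next
    r <- ref[ref$group == g, ]
    b <- bin_bounds[[g]]
    hba1c[idx] <- rtrunc_norm(length(idx), r$hba1c_mean, r$hba1c_sd, b[1], b[2])
  }
  age <- rtrunc_norm(n, ref$age_mean[ref_row], ref$age_sd[ref_row], 21, 90)
  bmi_m <- ref$bmi_mean[ref_row]
  bmi_s <- ref$bmi_sd[ref_row]
  bmi <- exp(rnorm(n, log(bmi_m^2 / sqrt(bmi_m^2 + bmi_s^2)),
                   sqrt(log(1 + bmi_s^2 / bmi_m^2))))
  sex <- ifelse(runif(n) < ref$pct_female[ref_row] / 100, "female", "male")
  dx <- runif(n) < (ref$selfreport_dx_diabetes / ref$n)[ref_row]
  rx <- runif(n) < (ref$selfreport_rx_diabetes / ref$n)[ref_row]

  # target-probe latent score: unit variance, planted fractions exact in
  # expectation
  terms <- list(list(type = "exposure", x = hba1c,
                     fraction = config$exposure_variance_fraction, sign = -1),
                list(type = "age", x = age,
                     fraction = config$age_variance_fraction, sign = -1))
  for (e in config$planted_meqtl) {
    terms <- c(terms, list(list(
      type = "meqtl", id = e$snp_id,
      x = geno$dosages[, e$snp_id], fraction = e$fraction, sign = 1)))
  }
  for (e in config$planted_gxe) {
    terms <- c(terms, list(list(
      type = "gxe", id = e$snp_id,
      x = planted_design_column("gxe", geno$dosages[, e$snp_id], hba1c),
      fraction = e$fraction, sign = 1)))
  }
  # exact in-sample scaling: every planted column is centred and standardised
  # against its sample spread, and the Gaussian noise is residualised against
  # the planted design so each term's realised latent variance fraction equals
  # its configured value rather than merely matching it in expectation
  noise_sd <- sqrt(1 - sum(vapply(terms, function(t) t$fraction, numeric(1))))
  active <- Filter(function(t) t$fraction > 0, terms)
  noise <- rnorm(n)
  if (length(active)) {
    Xp <- do.call(cbind, lapply(active, function(t) t$x - mean(t$x)))
    noise <- qr.resid(qr(cbind(1, Xp)), noise)
  }
  latent <- noise / sd(noise) * noise_sd
  effects <- list()
  for (t in terms) {
    xc <- t$x - mean(t$x)
    sdx <- sd(xc)
    b <- if (sdx > 0) t$sign * sqrt(t$fraction) / sdx else 0
    latent <- latent + b * xc
    effects[[length(effects) + 1]] <- tibble(
      type = t$type, feature_id = t$id %||% t$type, value = t$fraction,
      coefficient = b * config$latent_scale)
  }
  target_beta <- plogis(qlogis(config$target_mean_beta) +
                        config$latent_scale * latent)

  # GxMeth perturbation of the exposure, then re-bin
  for (e in config$planted_gxmeth) {
    snp <- geno$dosages[, e$snp_id]
    prod <- (snp - mean(snp)) * (target_beta - mean(target_beta))
    hba1c <- hba1c + e$effect * prod
    effects[[length(effects) + 1]] <- tibble(
      type = "gxmeth", feature_id = e$snp_id, value = e$effect,
      coefficient = e$effect)
  }
  hba1c <- pmax(hba1c, 3.5)
  glycemic_class <- bin_glycemic_class(hba1c)

  samples <- tibble(
    sample_id = sample_ids_for(n), age = age, sex = sex, bmi = bmi,
    hba1c = hba1c, self_report_dx_diabetes = dx, self_report_rx_diabetes = rx,
    glycemic_class = glycemic_class, excluded = FALSE, exclusion_reason = ""
  )

  # background probes: null logit-normal noise; SEM probes carry planted
  # fence-exceeding outliers
  betas <- matrix(NA_real_, n, config$n_probes,
                  dimnames = list(samples$sample_id, probe_ids))
  betas[, 1] <- target_beta
  sem_map <- setNames(config$planted_sem,
                      vapply(config$planted_sem, function(e) e$probe_id,
                             character(1)))
  sem_truth <- list()
  for (j in seq_len(config$n_probes)[-1]) {
    pid <- probe_ids[j]
    sem <- sem_map[[pid]]
    if (is.null(sem)) {
      mu <- runif(1, 0.15, 0.85)
      sd_logit <- runif(1, 0.2, 0.3)
      betas[, j] <- plogis(rnorm(n, qlogis(mu), sd_logit))
    } else {
      mu <- if (sem$direction == "high") runif(1, 0.35, 0.55) else runif(1, 0.45, 0.65)
      v <- plogis(rnorm(n, qlogis(mu), 0.15))
      out_idx <- sample.int(n, sem$n)
      rest <- v[-out_idx]
      q <- quantile(rest, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      if (sem$direction == "high") {
        v[out_idx] <- pmin(q[2] + 3 * iqr + runif(sem$n, 0.02, 0.08), 0.995)
      } else {
        v[out_idx] <- pmax(q[1] - 3 * iqr - runif(sem$n, 0.02, 0.08), 0.005)
      }
      betas[, j] <- v
      sem_truth[[length(sem_truth) + 1]] <- tibble(
        probe_id = pid, sample_id = samples$sample_id[out_idx],
        direction = sem$direction)
    }
  }

  probe_chrom <- as.character(sample.int(config$n_chromosomes,
                                         config$n_probes, replace = TRUE))
  probe_pos <- sample.int(2.4e8, config$n_probes, replace = TRUE)
  probe_chrom[1] <- config$target_chrom
  probe_pos[1] <- config$target_pos
  island_levels <- c("Island", "N Shore", "S Shore", "N Shelf", "S Shelf",
                     "Open Sea")
  island <- sample(island_levels, config$n_probes, replace = TRUE,
                   prob = c(0.3, 0.1, 0.1, 0.05, 0.05, 0.4))
  island[1] <- "Open Sea"
  poly <- runif(config$n_probes) < config$polymorphic_fraction
  poly[1] <- FALSE
  manifest <- tibble(probe_id = probe_ids, chrom = probe_chrom,
                     pos = probe_pos, island_status = island,
                     gene = c("TXNIP", rep("", config$n_probes - 1L)),
                     polymorphic = poly)

  truth <- list(
    effects = bind_rows(effects),
    sem = if (length(sem_truth)) bind_rows(sem_truth) else
      tibble(probe_id = character(0), sample_id = character(0),
             direction = character(0))
  )
  list(samples = samples,
       meth = methylation_matrix(betas, manifest),
       truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [simulate_genotypes()] and
#' [simulate_phenotypes_and_methylation()] from one config.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `samples`, `geno`, `meth`, `truth`.
#' @export
simulate_cohort <- function(config) {
  geno <- simulate_genotypes(config)
  rest <- simulate_phenotypes_and_methylation(config, geno)
  c(list(config = config, geno = geno), rest)
}
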