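test_that("nested comparison matches closed-form RSS arithmetic and anova", {
  # 3-point dataset with hand-computable residual sums of squares
  d <- tibble::tibble(y = c(1, 2, 4), x = c(0, 1, 2))
  small <- lm(y ~ 1, data = d)        # RSS = 14/3
  large <- lm(y ~ x, data = d)        # slope 1.5, RSS = 1/6
  res <- compare_nested(small, large)
  rss_s <- 14 / 3; rss_l <- 1 / 6
  f_expected <- ((rss_s - rss_l) / 1) / (rss_l / 1)
  expect_equal(res$statistic, f_expected, tolerance = 1e-10)
  ref <- anova(small, large)
  expect_equal(res$statistic, ref$F[2], tolerance = 1e-10)
  expect_equal(res$p_value, ref$`Pr(>F)`[2], tolerance = 1e-10)

  # identical fits -> F = 0, p = 1
  same <- compare_nested(large, large)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # non-nested fits are rejected
  d$z <- c(1, 0, 1)
  expect_error(compare_nested(lm(y ~ z, d), lm(y ~ x, d)),
               class = "epigx_validation_error")
})

test_that("adding pure noise gives uniform nested-model p-values", {
  set.seed(99)
  p <- vapply(1:300, function(i) {
    y <- rnorm(100)
    x <- rnorm(100)
    compare_nested(lm(y ~ 1), lm(y ~ x))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("stepwise recovers a planted feature among nulls", {
  found_true <- n_null <- numeric(25)
  for (i in 1:25) {
    set.seed(500 + i)
    n <- 500
    d <- tibble::tibble(.rows = n)
    for (j in 1:20) d[[paste0("null", j)]] <- rnorm(n)
    d$signal <- rnorm(n)
    d$y <- sqrt(0.1) * d$signal + sqrt(0.9) * rnorm(n)
    fit <- stepwise_build(d, "y", c(paste0("null", 1:20), "signal"))
    found_true[i] <- "signal" %in% fit$retained
    n_null[i] <- length(setdiff(fit$retained, "signal"))
  }
  expect_gte(mean(found_true), 0.95)
  # expected false-inclusion count is ~alpha x pool size ~ 1; allow MC error
  expect_lte(mean(n_null), 1 + 2 * stats::sd(n_null) / sqrt(length(n_null)))
})

test_that("stepwise honours its contracts on degenerate inputs", {
  set.seed(3)
  d <- tibble::tibble(y = rnorm(100), x = rnorm(100), age = rnorm(100, 45))
  d$y <- d$y + 0.5 * d$x
  # zero candidates -> base model
  fit0 <- stepwise_build(d, "y", character(0), base_terms = "age")
  expect_identical(fit0$terms, "age")
  # duplicate candidate columns: the second adds no variance and is rejected
  d$x_dup <- d$x
  fit <- stepwise_build(d, "y", c("x", "x_dup"), base_terms = "age",
                        rank_candidates = FALSE)
  expect_identical(fit$retained, "x")
  expect_true(any(fit$history$action %in%
                    c("rejected", "skipped_collinear", "skipped_aliased")))
  # monotone fit: final adj R^2 >= base-model adj R^2
  base_fit <- summary(lm(y ~ age, data = d))$adj.r.squared
  expect_gte(fit$adj_r2, base_fit)
  # determinism
  fit2 <- stepwise_build(d, "y", c("x", "x_dup"), base_terms = "age",
                         rank_candidates = FALSE)
  expect_identical(fit$terms, fit2$terms)
})

test_that("interaction candidates always bring both parents (hierarchy)", {
  set.seed(11)
  n <- 400
  d <- tibble::tibble(snp = rbinom(n, 2, 0.3), hba1c = rnorm(n, 6, 1),
                      age = rnorm(n, 45, 8))
  d$y <- 0.05 * d$snp * d$hba1c + rnorm(n, 0, 0.3)
  fit <- stepwise_build(d, "y", "snp:hba1c", base_terms = "age")
  expect_true("snp:hba1c" %in% fit$retained)
  expect_true(all(c("snp", "hba1c") %in% fit$terms))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p_value", "signif") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$n_used, 400L)
  expect_lte(gl$adj_r2, 1)
})

test_that("two-SNP additive fit matches a reference fit and validates input", {
  co <- simulate_cohort(tiny_config(seed = 14))
  s <- co$samples
  tb <- co$meth$betas[, 1]
  g <- co$geno$dosages
  res <- fit_ge_pair(tb, g[, 1], g[, 2], s)
  ref <- summary(lm(tb ~ g[, 1] + g[, 2] + s$hba1c + s$age))
  expect_equal(res$coefficients$estimate, unname(ref$coefficients[, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$adj_r2, ref$adj.r.squared, tolerance = 1e-8)
  expect_error(fit_ge_pair(tb, g[, 1], g[, 1], s),
               class = "epigx_validation_error")
})

test_that("planted pair jointly recovers about the sum of its fractions", {
  r2 <- vapply(1:20, function(i) {
    cfg <- sim_config(n_subjects = 500, n_probes = 3, n_snps = 50,
                      seed = 700 + i,
                      planted_meqtl = list(
                        list(snp_id = "snp_00005", fraction = 0.04),
                        list(snp_id = "snp_00025", fraction = 0.05)))
    co <- simulate_cohort(cfg)
    fit <- fit_ge_pair(co$meth$betas[, "cg19693031"],
                       co$geno$dosages[, "snp_00005"],
                       co$geno$dosages[, "snp_00025"], co$samples)
    fit$adj_r2
  }, numeric(1))
  # genetic 0.09 + exposure 0.15 (+ age 0.02 via correlation) on the latent
  # scale; allow generous Monte-Carlo slack for the logistic mapping
  expect_gt(mean(r2), 0.12)
  expect_lt(mean(r2), 0.40)
})

test_that("stratified genotype comparisons localise a diabetic-only shift", {
  set.seed(42)
  n <- 600
  cls <- sample(c("control", "prediabetic", "diabetic"), n, TRUE,
                prob = c(0.3, 0.5, 0.2))
  snp <- rbinom(n, 2, 0.35)
  beta <- rnorm(n, 0.6, 0.03)
  shift <- cls == "diabetic" & snp >= 1
  beta[shift] <- beta[shift] - 0.13
  samples <- tibble::tibble(sample_id = sprintf("S%03d", 1:n),
                            glycemic_class = cls)
  res <- stratified_genotype_comparison(beta, snp, samples, seed = 7)
  d01 <- res[res$stratum == "diabetic" & res$group1 == 0 & res$group2 == 1, ]
  expect_equal(d01$delta_beta_pct, 13, tolerance = 2.5)
  expect_lt(d01$p_holm, 0.001)
  c01 <- res[res$stratum == "cohort" & res$group1 == 0 & res$group2 == 1, ]
  expect_lt(abs(c01$delta_beta_pct), abs(d01$delta_beta_pct))  # attenuated
  ctrl <- res[res$stratum == "control" & res$group1 == 0 & res$group2 == 1, ]
  expect_gt(ctrl$p_value, 0.01)
  # effect size carries a bootstrap CI bracketing the point estimate
  expect_true(d01$smd_low <= d01$smd && d01$smd <= d01$smd_high)
})

test_that("identical genotype groups give zero effect sizes", {
  set.seed(9)
  beta <- rnorm(200, 0.5, 0.05)
  snp <- rep(c(0, 1), each = 100)
  samples <- tibble::tibble(sample_id = sprintf("S%03d", 1:200),
                            glycemic_class = rep("control", 200))
  suppressWarnings(
    res <- stratified_genotype_comparison(beta, snp, samples, boot = 200)
  )
  row <- res[res$stratum == "cohort", ]
  expect_lt(abs(row$delta_beta_pct), 2)
  expect_lt(row$smd, 0.35)
  expect_gt(row$p_value, 0.05)
})
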