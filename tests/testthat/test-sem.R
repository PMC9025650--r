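# independent brute-force oracle: sort, take interpolated quartiles by direct
# order-statistic arithmetic, apply the fence rule
brute_force_sems <- function(v, multiplier = 3) {
  s <- sort(v)
  n <- length(s)
  interp_q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  q1 <- interp_q(0.25); q3 <- interp_q(0.75)
  iqr <- q3 - q1
  list(hmo = which(v > q3 + multiplier * iqr),
       lmo = which(v < q1 - multiplier * iqr),
       lower = q1 - multiplier * iqr, upper = q3 + multiplier * iqr)
}

# full hypergeometric enumeration of the two-tailed Fisher exact p
brute_force_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(r1 + r2, c1)
  }, numeric(1))
  p_obs <- probs[ks == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("hand-computable degenerate probe yields a single HMO", {
  m <- manual_meth(matrix(c(rep(0.1, 9), 0.9), 10, 1,
                          dimnames = list(sprintf("S%02d", 1:10), "p1")))
  calls <- detect_sems(m)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$class, "HMO")
  expect_identical(calls$sample_id, "S10")
  expect_equal(calls$lower_fence, 0.1)
  expect_equal(calls$upper_fence, 0.1)
  # a value exactly on the fence is not an outlier
  m2 <- manual_meth(matrix(rep(0.1, 10), 10, 1))
  expect_identical(nrow(detect_sems(m2)), 0L)
  expect_error(detect_sems(m, multiplier = 0), class = "epigx_config_error")
  expect_warning(detect_sems(manual_meth(matrix(runif(5), 5, 1))), "skipped")
})

test_that("calls agree exactly with the brute-force oracle on random probes", {
  set.seed(77)
  n_probe <- 1000
  betas <- matrix(plogis(rnorm(200 * n_probe, 0, 1.2)), 200, n_probe)
  # salt in heavy-tailed probes so outliers actually occur
  idx <- sample.int(length(betas), 2000)
  betas[idx] <- runif(2000)
  m <- manual_meth(betas)
  calls <- detect_sems(m)
  for (j in seq_len(n_probe)) {
    oracle <- brute_force_sems(betas[, j])
    mine <- calls[calls$probe_id == colnames(betas)[j], ]
    expect_equal(sort(as.integer(mine$sample_id[mine$class == "HMO"])),
                 oracle$hmo, ignore_attr = TRUE)
    expect_equal(sort(as.integer(mine$sample_id[mine$class == "LMO"])),
                 oracle$lmo, ignore_attr = TRUE)
    if (nrow(mine)) {
      expect_equal(mine$upper_fence[1], oracle$upper)
      expect_equal(mine$lower_fence[1], oracle$lower)
    }
  }
  # HMO and LMO sets are disjoint per probe by construction of the fences
  expect_identical(anyDuplicated(calls[, c("probe_id", "sample_id")]), 0L)
})

test_that("fences are affine-equivariant so calls are scale-invariant", {
  set.seed(5)
  v <- c(plogis(rnorm(100)), 0.999)  # guarantees at least one candidate
  m1 <- manual_meth(matrix(v, 101, 1))
  calls1 <- detect_sems(m1)
  a <- 0.5; b <- 0.1
  m2 <- manual_meth(matrix(a * v + b, 101, 1))
  calls2 <- detect_sems(m2)
  expect_identical(calls1$sample_id, calls2$sample_id)
  expect_identical(calls1$class, calls2$class)
  expect_equal(calls2$upper_fence, a * calls1$upper_fence + b)
  expect_equal(calls2$lower_fence, a * calls1$lower_fence + b)
})

test_that("false-call rate on tight uniform probes is below 0.1 %", {
  set.seed(12)
  n_probes <- 400
  betas <- matrix(runif(500 * n_probes, 0.4, 0.6), 500, n_probes)
  calls <- detect_sems(manual_meth(betas))
  expect_lt(nrow(calls) / n_probes, 0.001)
})

test_that("planted outliers are all recovered with the right class", {
  co <- simulate_cohort(tiny_config(
    seed = 8,
    planted_sem = list(list(probe_id = "cg_00003", n = 3, direction = "high"),
                       list(probe_id = "cg_00009", n = 4, direction = "low"))))
  calls <- detect_sems(co$meth)
  hi <- calls[calls$probe_id == "cg_00003", ]
  expect_setequal(hi$sample_id[hi$class == "HMO"],
                  co$truth$sem$sample_id[co$truth$sem$probe_id == "cg_00003"])
  lo <- calls[calls$probe_id == "cg_00009", ]
  expect_setequal(lo$sample_id[lo$class == "LMO"],
                  co$truth$sem$sample_id[co$truth$sem$probe_id == "cg_00009"])
})

test_that("burden counts conserve totals", {
  expect_identical(sem_burden(detect_sems(manual_meth(
    matrix(runif(100, 0.4, 0.6), 50, 2))))$summary$n_calls, 0L)
  calls <- tibble::tibble(
    probe_id = sample(sprintf("p%d", 1:23), 49, replace = TRUE),
    sample_id = sample(sprintf("S%d", 1:27), 49, replace = TRUE),
    class = sample(c("HMO", "LMO"), 49, replace = TRUE),
    value = runif(49), lower_fence = 0, upper_fence = 1)
  b <- sem_burden(calls)
  expect_identical(sum(b$by_subject$n_total), 49L)
  expect_identical(sum(b$by_probe$n_total), 49L)
  expect_identical(b$summary$n_hmo + b$summary$n_lmo, 49L)
  # probe with both classes tallies both
  mixed <- calls[1, ]
  mixed$class <- "LMO"; calls$class[1] <- "HMO"
  mixed$sample_id <- "S_extra"
  b2 <- sem_burden(rbind(calls, mixed))
  row <- b2$by_probe[b2$by_probe$probe_id == calls$probe_id[1], ]
  expect_gte(row$n_hmo, 1L)
  expect_gte(row$n_lmo, 1L)
})

test_that("enrichment matches the hypergeometric enumeration oracle", {
  mk_samples <- function(n_diab, n_ctrl) tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n_diab + n_ctrl)),
    glycemic_class = rep(c("diabetic", "control"), c(n_diab, n_ctrl)))
  mk_calls <- function(ids) tibble::tibble(
    probe_id = "p1", sample_id = ids, class = "HMO", value = 0.9,
    lower_fence = 0, upper_fence = 0.8)

  # balanced table [[10,10],[10,10]] -> OR 1, p 1
  s <- mk_samples(20, 20)
  res <- sem_enrichment(mk_calls(c(sprintf("S%03d", 1:10),
                                   sprintf("S%03d", 21:30))), s)
  expect_equal(res$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(res$p_value, 1)

  # table [[1,9],[11,3]] against full enumeration
  s2 <- mk_samples(10, 14)
  calls2 <- mk_calls(c("S001", sprintf("S%03d", 11:21)))
  res2 <- sem_enrichment(calls2, s2)
  tab <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  expect_equal(res2$diabetic_sem, 1)
  expect_equal(res2$p_value, brute_force_fisher_p(tab), tolerance = 1e-12)

  # one group empty -> error
  expect_error(sem_enrichment(mk_calls("S001"),
                              tibble::tibble(sample_id = "S001",
                                             glycemic_class = "diabetic")),
               class = "epigx_validation_error")
})

test_that("probe filtering drops flagged probes but protects the target", {
  co <- simulate_cohort(tiny_config(
    seed = 4,
    planted_sem = list(list(probe_id = "cg_00002", n = 3, direction = "high"))))
  calls <- detect_sems(co$meth)
  filtered <- filter_sem_probes(co$meth, calls, target_probe = "cg19693031")
  expect_false("cg_00002" %in% filtered$manifest$probe_id)
  expect_true("cg19693031" %in% filtered$manifest$probe_id ||
                "cg19693031" %in% calls$probe_id)
  # empty call set is the identity
  none <- detect_sems(manual_meth(matrix(runif(60, 0.4, 0.6), 30, 2)))
  m <- manual_meth(matrix(runif(60, 0.4, 0.6), 30, 2))
  expect_identical(filter_sem_probes(m, none)$manifest$probe_id,
                   m$manifest$probe_id)
  # all probes flagged -> empty matrix with warning
  expect_warning(out <- filter_sem_probes(m, probe_set = m$manifest$probe_id),
                 "all probes")
  expect_identical(ncol(out$betas), 0L)
})
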