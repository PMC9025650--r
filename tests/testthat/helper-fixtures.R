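# Small cohort fixtures built in code.

tiny_config <- function(seed = 1L, ...) {
  sim_config(n_subjects = 120, n_probes = 30, n_snps = 60, seed = seed, ...)
}

# standard mid-size cohort with one planted effect of each kind
planted_config <- function(seed = 1L, n_subjects = 300, ...) {
  sim_config(
    n_subjects = n_subjects, n_probes = 60, n_snps = 200, seed = seed,
    planted_meqtl = list(list(snp_id = "snp_00010", fraction = 0.05)),
    planted_gxe = list(list(snp_id = "snp_00020", fraction = 0.05)),
    planted_gxmeth = list(list(snp_id = "snp_00030", effect = 8)),
    planted_sem = list(list(probe_id = "cg_00007", n = 3, direction = "high")),
    ...
  )
}

# bare containers assembled by hand for unit tests
manual_geno <- function(dosages, chrom = NULL, pos = NULL) {
  m <- ncol(dosages)
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("snp_%05d", seq_len(m))
  }
  genotype_matrix(dosages, tibble::tibble(
    snp_id = colnames(dosages),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% seq_len(m) * 1000,
    a1 = "A", a2 = "B"
  ))
}

manual_meth <- function(betas, polymorphic = NULL) {
  m <- ncol(betas)
  if (is.null(colnames(betas))) colnames(betas) <- sprintf("cg_%05d", seq_len(m))
  methylation_matrix(betas, tibble::tibble(
    probe_id = colnames(betas), chrom = rep("1", m), pos = seq_len(m) * 1000,
    island_status = "Open Sea", gene = "",
    polymorphic = polymorphic %||% rep(FALSE, m)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
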