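#' Construct a genotype matrix container
#'
#' Couples an additive-coded dosage matrix (samples x SNPs, values 0/1/2 or
#' `NA`) with its SNP manifest. Dosages count copies of the minor allele, the
#' standard additive recoding used by PLINK `--recode A`.
#'
#' @param dosages Numeric matrix, samples in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids); entries in `{0, 1, 2, NA}`.
#' @param manifest Data frame with one row per SNP column: `snp_id`, `chrom`,
#'   `pos` (1-based), and optionally `a1`, `a2`, `maf`.
#' @return An object of class `genotype_matrix` (list with `dosages` and
#'   `manifest`).
#' @export
genotype_matrix <- function(dosages, manifest) {
  dosages <- as.matrix(dosages)
  manifest <- as_tibble(manifest)
  if (ncol(dosages) != nrow(manifest)) {
    parse_error(sprintf(
      "genotype manifest has %d rows but dosage matrix has %d columns",
      nrow(manifest), ncol(dosages)
    ))
  }
  if (!all(c("snp_id", "chrom", "pos") %in% names(manifest))) {
    parse_error("genotype manifest must have columns snp_id, chrom, pos")
  }
  if (is.null(colnames(dosages))) colnames(dosages) <- manifest$snp_id
  if (ncol(dosages) > 0 &&
      !identical(colnames(dosages), as.character(manifest$snp_id))) {
    parse_error("genotype manifest snp_id order does not match dosage columns")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    validation_error("dosages must be 0, 1, 2 or NA")
  }
  structure(list(dosages = dosages, manifest = manifest),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs (%d chromosomes)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$manifest$chrom))))
  invisible(x)
}

#' Construct a methylation matrix container
#'
#' Couples a beta-value matrix (samples x probes, values in `[0, 1]`) with its
#' probe manifest (coordinates, CpG-island status, gene annotation and the
#' polymorphic-target flag).
#'
#' @param betas Numeric matrix, samples in rows, probes in columns; values in
#'   `[0, 1]` or `NA`.
#' @param manifest Data frame with one row per probe column: `probe_id`,
#'   `chrom`, `pos` (1-based), and optionally `island_status`, `gene`,
#'   `polymorphic`.
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(betas, manifest) {
  betas <- as.matrix(betas)
  manifest <- as_tibble(manifest)
  if (ncol(betas) != nrow(manifest)) {
    parse_error(sprintf(
      "probe manifest has %d rows but beta matrix has %d columns",
      nrow(manifest), ncol(betas)
    ))
  }
  if (!all(c("probe_id", "chrom", "pos") %in% names(manifest))) {
    parse_error("probe manifest must have columns probe_id, chrom, pos")
  }
  if (is.null(colnames(betas))) colnames(betas) <- manifest$probe_id
  if (ncol(betas) > 0 &&
      !identical(colnames(betas), as.character(manifest$probe_id))) {
    parse_error("probe manifest probe_id order does not match beta columns")
  }
  vals <- betas[!is.na(betas)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1)) {
    validation_error("beta values must lie in [0, 1]")
  }
  structure(list(betas = betas, manifest = manifest),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %d samples x %d probes\n",
              nrow(x$betas), ncol(x$betas)))
  invisible(x)
}

#' Bin HbA1c into glycemic classes
#'
#' Applies the clinical diagnostic cut-points: HbA1c (%) of at most 5.7 is
#' normoglycemic (`control`), strictly between 5.7 and 6.5 is `prediabetic`,
#' and 6.5 or above is `diabetic`. The published bins overlap at their
#' endpoints ("<= 5.7" and ">= 6.5"); this implementation honours both
#' inequalities literally, so 5.7 maps to `control` and 6.5 to `diabetic`.
#'
#' @param hba1c Numeric vector of HbA1c percentages (finite, positive).
#' @param lower,upper The two cut-points (defaults 5.7 and 6.5).
#' @return Factor with levels `control`, `prediabetic`, `diabetic`.
#' @examples
#' bin_glycemic_class(c(5.34, 5.7, 5.96, 6.5, 8.02))
#' @export
bin_glycemic_class <- function(hba1c, lower = 5.7, upper = 6.5) {
  if (!is.numeric(hba1c) || any(!is.finite(hba1c)) || any(hba1c <= 0)) {
    validation_error("hba1c must be finite and > 0")
  }
  cls <- ifelse(hba1c <= lower, "control",
                ifelse(hba1c < upper, "prediabetic", "diabetic"))
  factor(cls, levels = c("control", "prediabetic", "diabetic"))
}

#' Flag subjects excluded by self-report inconsistency rules
#'
#' Mirrors the cohort-cleaning rules: (a) normoglycemic controls who
#' self-report a diabetes diagnosis are removed, and (b) any non-diabetic
#' subject self-reporting anti-diabetic pharmacotherapy is removed. Phenotype
#' values are never altered; only the `excluded` flag and `exclusion_reason`
#' are set.
#'
#' @param samples Sample tibble with columns `glycemic_class`,
#'   `self_report_dx_diabetes`, `self_report_rx_diabetes`.
#' @return The input tibble with logical `excluded` and character
#'   `exclusion_reason` columns.
#' @export
apply_exclusions <- function(samples) {
  samples <- as_tibble(samples)
  req <- c("glycemic_class", "self_report_dx_diabetes", "self_report_rx_diabetes")
  if (!all(req %in% names(samples))) {
    validation_error(paste("samples must have columns:", paste(req, collapse = ", ")))
  }
  cls <- as.character(samples$glycemic_class)
  rule_a <- cls == "control" & samples$self_report_dx_diabetes
  rule_b <- cls != "diabetic" & samples$self_report_rx_diabetes
  samples$excluded <- rule_a | rule_b
  samples$exclusion_reason <- dplyr::case_when(
    rule_a & rule_b ~ "control_selfreport_dx;nondiabetic_selfreport_rx",
    rule_a ~ "control_selfreport_dx",
    rule_b ~ "nondiabetic_selfreport_rx",
    TRUE ~ ""
  )
  samples
}

#' Empirical minor allele frequency per SNP
#'
#' Computed from non-missing additive dosages: `maf = min(p, 1 - p)` with
#' `p = mean(dosage) / 2`.
#'
#' @param geno A [genotype_matrix()].
#' @return Named numeric vector of MAFs.
#' @export
empirical_maf <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  p <- colMeans(geno$dosages, na.rm = TRUE) / 2
  setNames(pmin(p, 1 - p), colnames(geno$dosages))
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs whose empirical MAF exceeds `threshold` (the conventional
#' "MAF > 5 %" genotype QC step). MAF is computed from non-missing dosages,
#' not taken from the manifest.
#'
#' @param geno A [genotype_matrix()].
#' @param threshold MAF threshold in `(0, 0.5)`; SNPs with MAF `<= threshold`
#'   are dropped. Default 0.05.
#' @return A filtered [genotype_matrix()] with a `maf` manifest column.
#' @export
filter_maf <- function(geno, threshold = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 0.5) {
    config_error("maf threshold must lie in (0, 0.5)")
  }
  maf <- empirical_maf(geno)
  keep <- !is.na(maf) & maf > threshold
  if (!any(keep)) warn("all SNPs removed by MAF filter")
  manifest <- geno$manifest[keep, , drop = FALSE]
  manifest$maf <- unname(maf[keep])
  genotype_matrix(geno$dosages[, keep, drop = FALSE], manifest)
}

#' Windowed linkage-disequilibrium pruning
#'
#' Greedy sliding-window LD pruning over additive dosages, per chromosome in
#' position order: within each window of `window` SNPs, while any retained
#' pair has squared Pearson correlation above `r2_threshold`, the later SNP of
#' the pair (in position order) is removed; the window then advances by
#' `shift` SNPs. Removal is permanent across windows. Defaults are the common
#' 50-SNP window, 5-SNP shift and r-squared 0.5.
#'
#' @param geno A [genotype_matrix()].
#' @param window Window size in SNPs (>= shift).
#' @param shift Window shift in SNPs (>= 1).
#' @param r2_threshold Pairwise squared-correlation threshold.
#' @return A pruned [genotype_matrix()]; output columns are a subset of the
#'   input columns, and the operation is idempotent.
#' @export
ld_prune <- function(geno, window = 50, shift = 5, r2_threshold = 0.5) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (shift < 1 || window < shift) {
    config_error("require window >= shift >= 1")
  }
  dos <- geno$dosages
  man <- geno$manifest
  keep <- rep(TRUE, ncol(dos))
  names(keep) <- colnames(dos)
  for (chr in unique(man$chrom)) {
    idx <- which(man$chrom == chr)
    idx <- idx[order(man$pos[idx])]
    if (length(idx) < 2) next
    start <- 1
    repeat {
      win <- idx[start:min(start + window - 1, length(idx))]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        repeat {
          cc <- suppressWarnings(
            stats::cor(dos[, win, drop = FALSE], use = "pairwise.complete.obs")
          )
          cc[is.na(cc)] <- 0
          r2 <- cc^2
          r2[lower.tri(r2, diag = TRUE)] <- 0
          hit <- which(r2 > r2_threshold, arr.ind = TRUE)
          if (nrow(hit) == 0) break
          # first offending pair in position order; drop the later SNP
          hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
          drop_col <- win[hit[1, 2]]
          keep[drop_col] <- FALSE
          win <- win[win != drop_col]
          if (length(win) < 2) break
        }
      }
      if (start + window - 1 >= length(idx)) break
      start <- start + shift
    }
  }
  genotype_matrix(dos[, keep, drop = FALSE], man[keep, , drop = FALSE])
}

# ---- readers / writers -----------------------------------------------------

#' Read and write cohort tables
#'
#' Plain-text TSV round-trip for the three cohort containers. Genotypes use a
#' PLINK `.raw`-style additive table (first column `sample_id`, one column per
#' SNP, values 0/1/2/NA) plus a BIM-like manifest; methylation uses a beta
#' matrix plus probe manifest; phenotypes are a single TSV with named columns.
#' Missing dosages/betas are encoded as `NA` and survive the round-trip.
#'
#' @param geno,meth,samples Object to write.
#' @param values_path,manifest_path,path File paths.
#' @return Readers return the corresponding container; writers return the
#'   input invisibly.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_genotypes <- function(geno, values_path, manifest_path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  df <- as_tibble(geno$dosages)
  df <- tibble(sample_id = rownames(geno$dosages)) |> dplyr::bind_cols(df)
  readr::write_tsv(df, values_path)
  readr::write_tsv(geno$manifest, manifest_path)
  invisible(geno)
}

#' @rdname cohort_io
#' @export
read_genotypes <- function(values_path, manifest_path) {
  df <- readr::read_tsv(values_path, show_col_types = FALSE)
  if (names(df)[1] != "sample_id") {
    parse_error(sprintf("%s: first column must be sample_id", values_path))
  }
  man <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  man$chrom <- as.character(man$chrom)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$sample_id
  genotype_matrix(mat, man)
}

#' @rdname cohort_io
#' @export
write_methylation <- function(meth, values_path, manifest_path) {
  stopifnot(inherits(meth, "methylation_matrix"))
  df <- as_tibble(meth$betas)
  df <- tibble(sample_id = rownames(meth$betas)) |> dplyr::bind_cols(df)
  readr::write_tsv(df, values_path)
  readr::write_tsv(meth$manifest, manifest_path)
  invisible(meth)
}

#' @rdname cohort_io
#' @export
read_methylation <- function(values_path, manifest_path) {
  df <- readr::read_tsv(values_path, show_col_types = FALSE)
  if (names(df)[1] != "sample_id") {
    parse_error(sprintf("%s: first column must be sample_id", values_path))
  }
  man <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  man$chrom <- as.character(man$chrom)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$sample_id
  methylation_matrix(mat, man)
}

#' @rdname cohort_io
#' @export
write_samples <- function(samples, path) {
  readr::write_tsv(as_tibble(samples), path)
  invisible(samples)
}

#' @rdname cohort_io
#' @export
read_samples <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(df)) {
    parse_error(sprintf("%s: missing sample_id column", path))
  }
  if ("glycemic_class" %in% names(df)) {
    df$glycemic_class <- factor(df$glycemic_class,
                                levels = c("control", "prediabetic", "diabetic"))
  }
  df
}
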