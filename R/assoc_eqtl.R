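## Individual-level association and the eQTL stage. Case-control status
## is regressed on allele dosage by logistic regression with principal-
## component covariates to absorb population stratification; a known hit
## can be conditioned on to probe for secondary signals. Expression is
## log2-transformed, quantile-normalized across the replicates of each
## individual, collapsed to per-individual means, median-centered across
## individuals, and regressed on minor-allele dosage.

#' Logistic dosage association with covariates
#'
#' Maximum-likelihood logistic regression of a binary phenotype on the
#' focal SNP's additive dosage plus optional covariates (typically the
#' top principal components) and, for conditional analysis, the dosage of
#' a known associated SNP. Fitting is iteratively reweighted least
#' squares with convergence tolerance 1e-8 and at most 100 iterations;
#' non-convergence or a diverging coefficient (|beta| > 20, the
#' separation signature) is an error naming the SNP. Complete cases only.
#'
#' @param genotypes a `"genotype_matrix"` of dosages in \[0, 2\].
#' @param phenotype binary 0/1 vector, one entry per sample.
#' @param snp_id focal SNP.
#' @param covariates optional N x C numeric matrix (e.g. from
#'   [pc_covariates()]).
#' @param condition_snp optional SNP id whose dosage is added as a
#'   covariate (conditional analysis).
#' @return An object of class `"assoc_result"`: `snp_id`, `beta`, `se`,
#'   `z`, `p`, `or`, `n`, `covariates_used`, `conditioned_on`.
#' @export
logistic_assoc <- function(genotypes, phenotype, snp_id, covariates = NULL,
                           condition_snp = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  j <- match(snp_id, genotypes$snp_ids)
  if (is.na(j)) stop_data("SNP ", snp_id, " not in genotype matrix")
  if (length(phenotype) != length(genotypes$sample_ids))
    stop_data("phenotype length must match the sample count")
  if (!all(phenotype %in% c(0, 1)))
    stop_data("phenotype must be binary 0/1")
  dose <- genotypes$dosages[, j]
  dat <- data.frame(y = phenotype, dose = dose)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(phenotype))
      stop_data("covariate rows must match the sample count")
    cov_names <- if (!is.null(colnames(covariates))) colnames(covariates)
      else paste0("PC", seq_len(ncol(covariates)))
    colnames(covariates) <- cov_names
    dat <- cbind(dat, covariates)
  }
  if (!is.null(condition_snp)) {
    jc <- match(condition_snp, genotypes$snp_ids)
    if (is.na(jc)) stop_data("conditioning SNP ", condition_snp, " not found")
    dat$cond_dose <- genotypes$dosages[, jc]
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (var(dat$dose) == 0)
    stop_data("zero-variance dosage at ", snp_id)
  fit <- suppressWarnings(
    glm(y ~ ., data = dat, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)))
  est <- summary(fit)$coefficients
  if (!fit$converged || abs(est["dose", "Estimate"]) > 20)
    stop_data("logistic fit for ", snp_id,
              " did not converge (possible separation)")
  b <- est["dose", "Estimate"]; s <- est["dose", "Std. Error"]
  structure(list(snp_id = snp_id, beta = b, se = s, z = b / s,
                 p = 2 * pnorm(-abs(b / s)), or = exp(b), n = nrow(dat),
                 covariates_used = cov_names,
                 conditioned_on = condition_snp),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, digits = 4, ...) {
  cat(sprintf("Logistic association %s: beta = %.*f (se %.*f), OR = %.*f, p = %.3g, n = %d\n",
              x$snp_id, digits, x$beta, digits, x$se, digits, x$or, x$p, x$n))
  if (length(x$covariates_used))
    cat("  covariates:", paste(x$covariates_used, collapse = ", "), "\n")
  if (!is.null(x$conditioned_on))
    cat("  conditioned on:", x$conditioned_on, "\n")
  invisible(x)
}

#' Principal-component covariates from genotype dosages
#'
#' Top eigenvectors of the correlation matrix of centered, scaled
#' dosages; the standard stratification adjustment. Monomorphic SNPs are
#' dropped before scaling.
#'
#' @param genotypes a `"genotype_matrix"`.
#' @param k number of components (default 10).
#' @return N x k matrix of principal-component scores, columns PC1..PCk.
#' @export
pc_covariates <- function(genotypes, k = 10) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$dosages
  g <- g[, apply(g, 2, function(x) var(x, na.rm = TRUE) > 0), drop = FALSE]
  g <- scale(g)
  g[is.na(g)] <- 0
  k <- min(k, ncol(g), nrow(g) - 1)
  pcs <- stats::prcomp(g, center = FALSE, scale. = FALSE)$x[, seq_len(k),
                                                            drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(k))
  rownames(pcs) <- genotypes$sample_ids
  pcs
}

#' Quantile-normalize expression across the replicates of each individual
#'
#' Values are log2-transformed (an error if any value is nonpositive),
#' then within each individual the replicate columns are quantile
#' normalized — every replicate's sorted values are replaced by the mean
#' of sorted values across that individual's replicates — and finally the
#' replicates are collapsed to their per-probe mean, leaving one column
#' per individual. Individuals with a single replicate pass through as a
#' pure log transform.
#'
#' @param expr an `"expression_matrix"` with raw (positive) intensities.
#' @return An `"expression_matrix"` on the log2 scale, one column per
#'   individual.
#' @export
quantile_normalize_replicates <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (any(expr$values <= 0))
    stop_data("expression values must be positive before log transform")
  lv <- log2(expr$values)
  individuals <- unique(expr$sample_ids)
  out <- matrix(NA_real_, nrow = nrow(lv), ncol = length(individuals))
  for (i in seq_along(individuals)) {
    cols <- which(expr$sample_ids == individuals[i])
    block <- lv[, cols, drop = FALSE]
    if (length(cols) > 1)
      block <- limma::normalizeQuantiles(block)
    out[, i] <- rowMeans(block)
  }
  expression_matrix(out, expr$probe_info, individuals,
                    replicate_ids = rep(1L, length(individuals)))
}

#' Median-center expression across individuals
#'
#' Subtracts each individual column's median so every column median is
#' exactly zero; idempotent.
#'
#' @param expr an `"expression_matrix"` with one column per individual.
#' @return The median-centered `"expression_matrix"`.
#' @export
median_normalize_individuals <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  meds <- apply(expr$values, 2, median)
  out <- sweep(expr$values, 2, meds)
  expression_matrix(out, expr$probe_info, expr$sample_ids,
                    expr$replicate_ids)
}

#' cis-eQTL scan around a SNP
#'
#' For each probe whose gene transcription start lies within
#' `window_kb` kilobases of the SNP position, regresses normalized
#' expression on minor-allele dosage by least squares and reports the
#' slope, its t-test p-value, and the Bonferroni-corrected p-value
#' `min(1, p_nominal * n_probes_tested)` — the correction counts probes
#' tested, not genes. Window membership is measured from the SNP position
#' to the probe's annotated transcription start.
#'
#' @param expr a normalized `"expression_matrix"` (one column per
#'   individual) whose `probe_info` carries a `tss` column.
#' @param dosages a `"genotype_matrix"` with the focal SNP.
#' @param snp_id focal SNP.
#' @param snp_pos 1-based position of the SNP (same coordinate system as
#'   `tss`).
#' @param window_kb cis-window half-width in kilobases (default 300).
#' @return data.frame of class `"eqtl_result"`: one row per tested probe
#'   with probe_id, gene_id, slope, se, p_nominal, p_bonferroni, n.
#'   Empty (with a warning) when no probe falls in the window.
#' @export
eqtl_scan <- function(expr, dosages, snp_id, snp_pos, window_kb = 300) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(dosages, "genotype_matrix"))
  if (!"tss" %in% names(expr$probe_info))
    stop_data("probe_info must carry a tss column for window selection")
  j <- match(snp_id, dosages$snp_ids)
  if (is.na(j)) stop_data("SNP ", snp_id, " not in dosage matrix")
  in_win <- abs(expr$probe_info$tss - snp_pos) <= window_kb * 1000
  if (!any(in_win)) {
    warning("no probe within ", window_kb, " kb of ", snp_id)
    return(structure(data.frame(probe_id = character(0),
                                gene_id = character(0), slope = numeric(0),
                                se = numeric(0), p_nominal = numeric(0),
                                p_bonferroni = numeric(0), n = integer(0)),
                     class = c("eqtl_result", "data.frame")))
  }
  shared <- intersect(expr$sample_ids, dosages$sample_ids)
  if (length(shared) < 3) stop_data("need >= 3 shared samples for the eQTL fit")
  dose <- dosages$dosages[match(shared, dosages$sample_ids), j]
  ev <- expr$values[, match(shared, expr$sample_ids), drop = FALSE]
  probes <- which(in_win)
  n_tested <- length(probes)
  rows <- lapply(probes, function(i) {
    fit <- summary(lm(ev[i, ] ~ dose))$coefficients
    p_nom <- fit["dose", "Pr(>|t|)"]
    data.frame(probe_id = expr$probe_info$probe_id[i],
               gene_id = expr$probe_info$gene_id[i],
               slope = fit["dose", "Estimate"],
               se = fit["dose", "Std. Error"],
               p_nominal = p_nom,
               p_bonferroni = bonferroni_p(p_nom, n_tested),
               n = length(shared), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_nominal), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("eqtl_result", "data.frame"))
}

#' Bonferroni-corrected p-value
#'
#' `min(1, p * n_tests)`.
#'
#' @param p nominal p-value(s).
#' @param n_tests number of tests in the family.
#' @return Corrected p-value(s).
#' @examples
#' bonferroni_p(4.8e-3, 6)  # 0.029 at 2 significant figures
#' @export
bonferroni_p <- function(p, n_tests) {
  if (n_tests < 1) stop_data("n_tests must be >= 1")
  pmin(1, p * n_tests)
}
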