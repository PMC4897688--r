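## Fixed-effect inverse-variance meta-analysis. The pooled estimate is the
## precision-weighted mean; Cochran's Q measures residual heterogeneity.
## Random-effects pooling is deliberately absent: the scan contrasts
## fixed-effect summaries within and between ancestry groups.

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-study log-odds estimates with weights `w_i = 1 / se_i^2`:
#' `beta_pooled = sum(w * beta) / sum(w)`, `se_pooled = sum(w)^(-1/2)`.
#' Cochran's heterogeneity statistic `Q = sum(w * (beta - beta_pooled)^2)`
#' is referred to a chi-square with `k - 1` degrees of freedom, and
#' `I^2 = max(0, 100 * (Q - df) / Q)` summarizes the heterogeneous
#' fraction of total variation.
#'
#' @param beta numeric vector of per-study effects (log odds), or a
#'   two-column matrix/data.frame of (beta, se).
#' @param se numeric vector of per-study standard errors, all positive.
#' @param snp_id optional label carried into the result.
#' @return An object of class `"meta_result"`: list with `snp_id`, `k`,
#'   `beta_pooled`, `se_pooled`, `z`, `p`, `or_pooled`, `ci95`
#'   (OR scale), `Q`, `df`, `p_het`, `I2`.
#' @examples
#' meta_fixed(c(0.3507, 0), c(0.05934, 0.03305))
#' @export
meta_fixed <- function(beta, se = NULL, snp_id = NA_character_) {
  if (is.null(se)) {
    m <- as.matrix(beta)
    if (ncol(m) != 2) stop_data("meta_fixed: need (beta, se) pairs")
    beta <- m[, 1]; se <- m[, 2]
  }
  if (!length(beta)) stop_data("meta_fixed: empty effect list")
  if (length(beta) != length(se)) stop_data("meta_fixed: beta/se lengths differ")
  if (any(!is.finite(se) | se <= 0)) stop_data("meta_fixed: all se must be > 0")
  if (any(!is.finite(beta))) stop_data("meta_fixed: non-finite beta")
  w <- 1 / se^2
  sw <- sum(w)
  bp <- sum(w * beta) / sw
  sp <- 1 / sqrt(sw)
  z <- bp / sp
  k <- length(beta)
  Q <- sum(w * (beta - bp)^2)
  df <- k - 1L
  p_het <- if (df == 0L) 1 else pchisq(Q, df, lower.tail = FALSE)
  I2 <- if (Q > df) 100 * (Q - df) / Q else 0
  structure(list(snp_id = snp_id, k = k,
                 beta_pooled = bp, se_pooled = sp, z = z,
                 p = 2 * pnorm(-abs(z)),
                 or_pooled = exp(bp),
                 ci95 = exp(bp + c(-1, 1) * Z975 * sp),
                 Q = Q, df = df, p_het = p_het, I2 = I2),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, digits = 4, ...) {
  cat("Fixed-effect meta-analysis",
      if (!is.na(x$snp_id)) paste0("(", x$snp_id, ")"), "\n")
  cat(sprintf("  k = %d  beta = %.*f  se = %.*f  p = %.3g\n",
              x$k, digits, x$beta_pooled, digits, x$se_pooled, x$p))
  cat(sprintf("  OR = %.*f  95%% CI = %.*f-%.*f\n", digits, x$or_pooled,
              digits, x$ci95[1], digits, x$ci95[2]))
  cat(sprintf("  Q = %.*f (df = %d)  p_het = %.3g  I2 = %.1f%%\n",
              digits, x$Q, x$df, x$p_het, x$I2))
  invisible(x)
}

#' @export
coef.meta_result <- function(object, ...) {
  c(beta = object$beta_pooled, se = object$se_pooled)
}

#' Recover log-odds and standard error from a published OR and 95% CI
#'
#' `beta = log(or_point)`; `se = (log(ci_upper) - log(ci_lower)) /
#' (2 * 1.959964)`. Lets published odds-ratio summaries enter the
#' meta-analysis and heterogeneity machinery.
#'
#' @param or_point,ci_lower,ci_upper positive reals with
#'   `ci_lower <= or_point <= ci_upper`.
#' @return Named numeric vector `c(beta, se)`.
#' @examples
#' se_from_or_ci(1.42, 1.26, 1.59)
#' @export
se_from_or_ci <- function(or_point, ci_lower, ci_upper) {
  if (any(c(or_point, ci_lower, ci_upper) <= 0))
    stop_data("se_from_or_ci: OR and CI must be positive")
  if (ci_lower > or_point || or_point > ci_upper)
    stop_data("se_from_or_ci: need ci_lower <= or_point <= ci_upper")
  c(beta = log(or_point),
    se = (log(ci_upper) - log(ci_lower)) / (2 * Z975))
}

#' Meta-analyze one SNP within an ancestry group
#'
#' Selects the cohorts of `group` (or all cohorts for `group = "all"`)
#' that carry `snp_id` post-harmonization and applies [meta_fixed()].
#' Cohorts missing the SNP are silently excluded; `k` in the result counts
#' contributors.
#'
#' @param cohorts list of harmonized `"cohort_stats"` objects.
#' @param snp_id SNP to pool.
#' @param group ancestry label, or `"all"`.
#' @return A `"meta_result"`; attribute `"cohorts"` names the contributors.
#' @export
meta_by_group <- function(cohorts, snp_id, group = "all") {
  stopifnot(all(vapply(cohorts, inherits, TRUE, "cohort_stats")))
  sel <- if (identical(group, "all")) cohorts else
    Filter(function(co) co$ancestry == group, cohorts)
  rows <- lapply(sel, function(co) {
    r <- co$records[co$records$snp_id == snp_id, , drop = FALSE]
    if (nrow(r)) data.frame(cohort_id = co$cohort_id, beta = r$beta,
                            se = r$se, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows))
    stop_data("SNP ", snp_id, " absent from all cohorts in group '", group, "'")
  res <- meta_fixed(rows$beta, rows$se, snp_id = snp_id)
  attr(res, "cohorts") <- rows$cohort_id
  res
}

#' Serialize meta-analysis results to a tab-delimited table
#'
#' @param results list of `"meta_result"` objects.
#' @param groups optional per-result group labels.
#' @param path optional output file; when `NULL` the data.frame is
#'   returned without writing.
#' @return data.frame with columns snp, group, k, beta, se, z, p, or,
#'   ci_low, ci_high, Q, df, p_het, I2.
#' @export
write_meta_table <- function(results, groups = NULL, path = NULL) {
  if (inherits(results, "meta_result")) results <- list(results)
  if (is.null(groups)) groups <- rep(NA_character_, length(results))
  tab <- do.call(rbind, Map(function(r, g) data.frame(
    snp = r$snp_id, group = g, k = r$k, beta = r$beta_pooled,
    se = r$se_pooled, z = r$z, p = r$p, or = r$or_pooled,
    ci_low = r$ci95[1], ci_high = r$ci95[2], Q = r$Q, df = r$df,
    p_het = r$p_het, I2 = r$I2, stringsAsFactors = FALSE),
    results, groups))
  rownames(tab) <- NULL
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
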