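## Between-ancestry decomposition of Cochran's Q. With inverse-variance
## weights the total Q over all cohorts splits exactly into the sum of
## within-group Q statistics plus a between-group component; under effect
## homogeneity across G ancestry groups that component is chi-square with
## G - 1 degrees of freedom. The subtraction form is the definition used
## here; its equality with the direct weighted between-group sum of
## squares is enforced as an internal-consistency invariant.

#' Cochran's Q homogeneity statistic
#'
#' `Q = sum(w_i * (beta_i - beta_bar)^2)` with `w_i = 1 / se_i^2` and
#' `beta_bar` the inverse-variance-weighted mean; `df = k - 1`; the
#' p-value is the upper chi-square tail (1 when `k = 1`).
#'
#' @param beta,se per-study effects and positive standard errors (or
#'   `beta` a two-column (beta, se) matrix).
#' @return List with `Q`, `df`, `p`.
#' @examples
#' cochran_q(c(0, 1), c(1, 1))  # Q = 0.5, p ~ 0.48
#' @export
cochran_q <- function(beta, se = NULL) {
  m <- meta_fixed(beta, se)
  list(Q = m$Q, df = m$df, p = m$p_het)
}

#' Between-ancestry heterogeneity decomposition for one SNP
#'
#' Computes the total heterogeneity statistic `Q_all` over every
#' contributing cohort, the within-group statistics `Q_within[g]`, and the
#' between-ancestry component `Q_between = Q_all - sum(Q_within)`, clamped
#' at zero within numerical tolerance. `Q_between` is referred to a
#' chi-square with `G - 1` degrees of freedom, `G` the number of groups
#' contributing at least one cohort. A negative residual beyond `1e-6`
#' indicates an internal inconsistency and is an error, since the
#' decomposition is analytically nonnegative.
#'
#' @param effects_by_group named list, one element per ancestry group,
#'   each a two-column matrix/data.frame of per-cohort (beta, se).
#' @param snp_id optional label.
#' @return An object of class `"het_result"`: `snp_id`, `Q_all`,
#'   `Q_within` (named), `Q_between`, `df_between`, `p_between`,
#'   `group_estimates` (data.frame group/beta/se/k), `k_per_group`.
#' @examples
#' asian <- rbind(se_from_or_ci(1.42, 1.26, 1.59))
#' euro <- rbind(se_from_or_ci(1.00, 0.94, 1.07))
#' q_between_ancestry(list(Asian = asian, European = euro))
#' @export
q_between_ancestry <- function(effects_by_group, snp_id = NA_character_) {
  if (is.null(names(effects_by_group)) ||
      any(!nzchar(names(effects_by_group))))
    stop_data("effects_by_group must be a named list of ancestry groups")
  effects_by_group <- Filter(function(e) NROW(e) > 0, effects_by_group)
  G <- length(effects_by_group)
  if (G < 2)
    stop_data("between-ancestry contrast needs >= 2 non-empty groups")
  per_group <- lapply(effects_by_group, function(e) meta_fixed(as.matrix(e)))
  all_eff <- do.call(rbind, lapply(effects_by_group, as.matrix))
  m_all <- meta_fixed(all_eff)
  Q_within <- vapply(per_group, `[[`, 0, "Q")
  Q_between <- m_all$Q - sum(Q_within)
  if (Q_between < -1e-6)
    stop_internal("negative Q_between beyond tolerance (", Q_between,
                  "); inconsistent inputs")
  Q_between <- max(Q_between, 0)
  df_between <- G - 1L
  structure(list(
    snp_id = snp_id,
    Q_all = m_all$Q,
    Q_within = Q_within,
    Q_between = Q_between,
    df_between = df_between,
    p_between = pchisq(Q_between, df_between, lower.tail = FALSE),
    group_estimates = data.frame(
      group = names(per_group),
      beta = vapply(per_group, `[[`, 0, "beta_pooled"),
      se = vapply(per_group, `[[`, 0, "se_pooled"),
      k = vapply(per_group, `[[`, 0L, "k"),
      row.names = NULL, stringsAsFactors = FALSE),
    k_per_group = vapply(per_group, `[[`, 0L, "k")),
    class = "het_result")
}

#' @export
print.het_result <- function(x, digits = 4, ...) {
  cat("Between-ancestry heterogeneity",
      if (!is.na(x$snp_id)) paste0("(", x$snp_id, ")"), "\n")
  cat(sprintf("  Q_all = %.*f  Q_within = %s\n", digits, x$Q_all,
              paste(sprintf("%s %.3f", names(x$Q_within), x$Q_within),
                    collapse = ", ")))
  cat(sprintf("  Q_between = %.*f (df = %d)  p = %.3g\n", digits,
              x$Q_between, x$df_between, x$p_between))
  print(x$group_estimates, digits = digits)
  invisible(x)
}

#' Genomic inflation factor of a chi-square scan
#'
#' `lambda = median(observed statistics) / median(chi-square_df)`; for
#' `df = 1` the null median is 0.4549364. Computed over a designated
#' null-SNP set when available, so true signals do not inflate the
#' estimate; a calibrated scan has lambda near 1.
#'
#' @param stats finite nonnegative chi-square statistics.
#' @param df degrees of freedom of the null distribution (default 1).
#' @return The inflation factor (positive scalar).
#' @export
genomic_lambda <- function(stats, df = 1) {
  stats <- stats[!is.na(stats)]
  if (!length(stats)) stop_data("genomic_lambda: no statistics supplied")
  if (any(!is.finite(stats) | stats < 0))
    stop_data("genomic_lambda: statistics must be finite and nonnegative")
  median(stats) / qchisq(0.5, df)
}

#' Bonferroni family-wise significance threshold
#'
#' `alpha_family / n_independent`. With the 26,146 independent SNPs of the
#' Immunochip array this yields the chip-wide level 1.9e-6.
#'
#' @param alpha_family family-wise error rate in (0, 1).
#' @param n_independent number of independent tests (>= 1).
#' @return Per-test significance threshold.
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, n_independent) {
  if (alpha_family <= 0 || alpha_family >= 1)
    stop_data("alpha_family must be in (0, 1)")
  n_independent <- as.integer(n_independent)
  if (is.na(n_independent) || n_independent < 1)
    stop_data("n_independent must be a positive integer")
  alpha_family / n_independent
}

#' Scan all SNPs for between-ancestry association heterogeneity
#'
#' The package's core fitting function. For every SNP carried by at least
#' one cohort in at least two ancestry groups it computes the
#' [q_between_ancestry()] decomposition, estimates the genomic inflation
#' factor of `Q_between` (on a user-supplied null-SNP set when given, else
#' on all scanned SNPs), and flags SNPs whose between-ancestry p-value
#' falls below the Bonferroni threshold. Lambda is reported but not used
#' to rescale p-values unless `gc_correct = TRUE`.
#'
#' @param cohorts list of harmonized `"cohort_stats"` objects (see
#'   [harmonize_alleles()]).
#' @param grouping optional named character vector mapping cohort_id to
#'   ancestry group; defaults to each cohort's own `ancestry` field.
#' @param null_snps optional character vector of SNP ids assumed null,
#'   used for the lambda estimate.
#' @param alpha family-wise significance level (default 0.05).
#' @param n_independent number of independent SNPs for the Bonferroni
#'   correction (default 26146, the Immunochip convention).
#' @param gc_correct if `TRUE`, divide `Q_between` by lambda before
#'   computing p-values (off by default).
#' @return An object of class `"het_scan"`: list with `table` (per-SNP
#'   data.frame), `lambda_gc`, `threshold`, `hits` (rows below threshold,
#'   ascending p), `single_group_snps` (ids excluded for lacking a
#'   between-group contrast), `groups`, `settings`.
#' @seealso [summary.het_scan()], [plot.het_scan()]
#' @export
het_scan <- function(cohorts, grouping = NULL, null_snps = NULL,
                     alpha = 0.05, n_independent = 26146,
                     gc_correct = FALSE) {
  stopifnot(all(vapply(cohorts, inherits, TRUE, "cohort_stats")))
  ids <- vapply(cohorts, `[[`, "", "cohort_id")
  if (is.null(grouping))
    grouping <- setNames(vapply(cohorts, `[[`, "", "ancestry"), ids)
  unmapped <- setdiff(ids, names(grouping))
  if (length(unmapped))
    stop_config("cohorts not mapped to a group: ",
                paste(unmapped, collapse = ", "))
  groups <- unname(grouping[ids])

  ## long table of per-cohort effects
  long <- do.call(rbind, Map(function(co, g) {
    r <- co$records
    data.frame(snp_id = r$snp_id, chrom = r$chrom, pos = r$pos,
               beta = r$beta, se = r$se, group = g,
               stringsAsFactors = FALSE)
  }, cohorts, groups))
  split_snp <- split(long, long$snp_id)
  spans <- vapply(split_snp, function(d) length(unique(d$group)) >= 2, TRUE)
  if (!any(spans))
    stop_data("no SNP is carried by cohorts of >= 2 ancestry groups")
  single_group_snps <- names(split_snp)[!spans]

  group_names <- sort(unique(groups))
  rows <- lapply(split_snp[spans], function(d) {
    ebg <- lapply(split(d[c("beta", "se")], d$group), as.matrix)
    h <- q_between_ancestry(ebg, snp_id = d$snp_id[1])
    out <- data.frame(snp = d$snp_id[1], chrom = d$chrom[1], pos = d$pos[1],
                      stringsAsFactors = FALSE)
    for (g in group_names) {
      i <- match(g, h$group_estimates$group)
      out[[paste0("beta_", g)]] <- if (is.na(i)) NA_real_ else
        h$group_estimates$beta[i]
      out[[paste0("se_", g)]] <- if (is.na(i)) NA_real_ else
        h$group_estimates$se[i]
      out[[paste0("k_", g)]] <- if (is.na(i)) 0L else h$group_estimates$k[i]
      out[[paste0("Q_within_", g)]] <- if (is.na(i)) NA_real_ else
        unname(h$Q_within[g])
    }
    out$Q_all <- h$Q_all
    out$Q_between <- h$Q_between
    out$df_between <- h$df_between
    out$p_between <- h$p_between
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  lam_stats <- if (!is.null(null_snps)) {
    s <- tab$Q_between[tab$snp %in% null_snps]
    if (!length(s)) stop_data("none of the null SNPs appear in the scan")
    s
  } else tab$Q_between
  lam_df <- max(tab$df_between[1], 1)
  lambda_gc <- genomic_lambda(lam_stats, df = lam_df)

  if (gc_correct) {
    adj <- tab$Q_between / max(lambda_gc, 1)
    tab$p_between <- pchisq(adj, tab$df_between, lower.tail = FALSE)
  }
  threshold <- bonferroni_threshold(alpha, n_independent)
  hits <- tab[tab$p_between < threshold, , drop = FALSE]
  hits <- hits[order(hits$p_between), , drop = FALSE]
  rownames(hits) <- NULL

  structure(list(table = tab, lambda_gc = lambda_gc, threshold = threshold,
                 hits = hits, single_group_snps = single_group_snps,
                 groups = group_names,
                 settings = list(alpha = alpha,
                                 n_independent = n_independent,
                                 gc_correct = gc_correct,
                                 null_snps = null_snps)),
            class = "het_scan")
}

#' @export
print.het_scan <- function(x, ...) {
  cat("Between-ancestry heterogeneity scan\n")
  cat(sprintf("  %d SNPs tested across groups {%s}; %d excluded (single group)\n",
              nrow(x$table), paste(x$groups, collapse = ", "),
              length(x$single_group_snps)))
  cat(sprintf("  lambda_gc = %.3f   threshold = %.3g   hits = %d\n",
              x$lambda_gc, x$threshold, nrow(x$hits)))
  if (nrow(x$hits)) {
    cat("  Top hits:\n")
    print(head(x$hits[c("snp", "Q_between", "p_between")], 5), row.names = FALSE)
  }
  invisible(x)
}

#' Summarize a heterogeneity scan
#'
#' @param object a `"het_scan"` object.
#' @param ... unused.
#' @return A list of class `"summary.het_scan"` with the scan size,
#'   lambda, threshold, hit table and quantiles of `Q_between`.
#' @export
summary.het_scan <- function(object, ...) {
  structure(list(n_snps = nrow(object$table),
                 n_single_group = length(object$single_group_snps),
                 groups = object$groups,
                 lambda_gc = object$lambda_gc,
                 threshold = object$threshold,
                 hits = object$hits,
                 q_quantiles = quantile(object$table$Q_between,
                                        c(0.5, 0.9, 0.99, 1))),
            class = "summary.het_scan")
}

#' @export
print.summary.het_scan <- function(x, ...) {
  cat(sprintf("Heterogeneity scan: %d SNPs, groups {%s} (%d single-group excluded)\n",
              x$n_snps, paste(x$groups, collapse = ", "), x$n_single_group))
  cat(sprintf("lambda_gc = %.3f, Bonferroni threshold = %.3g\n",
              x$lambda_gc, x$threshold))
  cat("Q_between quantiles:\n"); print(round(x$q_quantiles, 3))
  cat(nrow(x$hits), "hit(s)\n")
  if (nrow(x$hits)) print(x$hits[c("snp", "Q_between", "p_between")],
                          row.names = FALSE)
  invisible(x)
}

#' Quantile-quantile plot of the between-ancestry statistics
#'
#' Observed `-log10(p_between)` against the uniform expectation; the
#' identity line marks perfect calibration.
#'
#' @param x a `"het_scan"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.het_scan <- function(x, ...) {
  p <- sort(x$table$p_between)
  n <- length(p)
  exp_q <- -log10((seq_len(n) - 0.5) / n)
  obs_q <- -log10(pmax(p, .Machine$double.xmin))
  plot(exp_q, obs_q, xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)),
       main = sprintf("Q_between calibration (lambda = %.3f)", x$lambda_gc),
       ...)
  abline(0, 1, col = "grey50")
  abline(h = -log10(x$threshold), lty = 2, col = "red3")
  invisible(x)
}

#' @export
as.data.frame.het_scan <- function(x, ...) x$table

#' Write scan outputs to disk
#'
#' Emits the per-SNP table as a tab-delimited file and a JSON run summary
#' (lambda, threshold, hit count, settings).
#'
#' @param scan a `"het_scan"` object.
#' @param table_path,summary_path output paths (`NULL` to skip either).
#' @return `scan`, invisibly.
#' @export
write_scan <- function(scan, table_path = NULL, summary_path = NULL) {
  stopifnot(inherits(scan, "het_scan"))
  if (!is.null(table_path))
    write.table(scan$table, table_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- list(lambda_gc = scan$lambda_gc, threshold = scan$threshold,
              n_snps = nrow(scan$table), n_hits = nrow(scan$hits),
              hits = scan$hits$snp,
              single_group_snps = scan$single_group_snps,
              settings = scan$settings[c("alpha", "n_independent",
                                         "gc_correct")])
    jsonlite::write_json(s, summary_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(scan)
}
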