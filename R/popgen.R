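## Population-genetic utilities on phased haplotypes: allele frequencies,
## two-locus LD by direct haplotype counting, allele co-occurrence,
## Hardy-Weinberg tests, cross-platform genotype concordance and the
## post-imputation QC filter. The minor allele is defined within each
## panel separately — the same allele may be common in one population and
## rare in another, which is exactly the situation the heterogeneity scan
## is built to expose.

hap_column <- function(haps, snp_id) {
  stopifnot(inherits(haps, "haplotype_matrix"))
  j <- match(snp_id, haps$snp_ids)
  if (is.na(j)) stop_data("SNP ", snp_id, " not in haplotype panel")
  haps$alleles[, j]
}

#' Minor allele frequency from phased haplotypes
#'
#' @param haps a `"haplotype_matrix"`.
#' @param snp_id SNP to evaluate.
#' @return Frequency in \[0, 0.5\]: `min(f, 1 - f)` with `f` the mean of
#'   the alternate-coded allele column.
#' @export
maf <- function(haps, snp_id) {
  col <- hap_column(haps, snp_id)
  if (all(is.na(col))) stop_data("all alleles missing for ", snp_id)
  f <- mean(col, na.rm = TRUE)
  min(f, 1 - f)
}

#' Two-locus linkage disequilibrium from phased haplotypes
#'
#' Direct haplotype-counting estimates: with `p_a`, `p_b` the frequencies
#' of the alternate-coded alleles and `p_ab` their joint haplotype
#' frequency, `D = p_ab - p_a * p_b`, `D'` is `D` normalized by its
#' frequency-constrained bound, and
#' `r^2 = D^2 / (p_a (1 - p_a) p_b (1 - p_b))`. A monomorphic column
#' yields `r^2 = 0` with a `monomorphic` flag rather than NaN, so scans
#' over many pairs stay robust. Missing alleles are an error: the
#' contract is phased, complete haplotypes.
#'
#' @param haps a `"haplotype_matrix"`.
#' @param snp_a,snp_b SNP ids.
#' @return An object of class `"ld_result"`: `snp_pair`, `p_a`, `p_b`,
#'   `p_ab`, `D`, `D_prime`, `r2`, `n_haplotypes`, `monomorphic`.
#' @export
ld_pair <- function(haps, snp_a, snp_b) {
  a <- hap_column(haps, snp_a)
  b <- hap_column(haps, snp_b)
  if (anyNA(a) || anyNA(b))
    stop_data("missing alleles at ", snp_a, "/", snp_b,
              "; LD requires complete phased data")
  n <- length(a)
  p_a <- mean(a); p_b <- mean(b); p_ab <- mean(a & b)
  D <- p_ab - p_a * p_b
  mono <- p_a %in% c(0, 1) || p_b %in% c(0, 1)
  if (mono) {
    D_prime <- 0; r2 <- 0
  } else {
    dmax <- if (D >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b) else
      min(p_a * p_b, (1 - p_a) * (1 - p_b))
    D_prime <- if (dmax == 0) 0 else D / dmax
    r2 <- D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  }
  structure(list(snp_pair = c(snp_a, snp_b), p_a = p_a, p_b = p_b,
                 p_ab = p_ab, D = D, D_prime = D_prime, r2 = r2,
                 n_haplotypes = n, monomorphic = mono),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, digits = 4, ...) {
  cat(sprintf("LD %s - %s: r2 = %.*f, D' = %.*f, D = %.*f (n = %d)%s\n",
              x$snp_pair[1], x$snp_pair[2], digits, x$r2, digits,
              x$D_prime, digits, x$D, x$n_haplotypes,
              if (x$monomorphic) " [monomorphic]" else ""))
  invisible(x)
}

#' Mean r-squared between an index SNP and a companion set
#'
#' Arithmetic mean of pairwise [ld_pair()] `r2` values between the index
#' SNP and each listed SNP. Used to contrast how strongly a candidate
#' causal SNP tags its companions in different populations.
#'
#' @param haps a `"haplotype_matrix"`.
#' @param index_snp id of the index SNP.
#' @param others nonempty vector of companion SNP ids.
#' @return Mean r-squared.
#' @export
mean_r2_to_index <- function(haps, index_snp, others) {
  if (!length(others)) stop_data("mean_r2_to_index: empty companion list")
  mean(vapply(others, function(s) ld_pair(haps, index_snp, s)$r2, 0))
}

#' Conditional allele co-occurrence on haplotypes
#'
#' Among haplotypes carrying `allele_a` at `snp_a`, the fraction also
#' carrying `allele_b` at `snp_b`. Alleles may be given as 0/1 codes or
#' as nucleotides when the panel carries an `allele_map`.
#'
#' @param haps a `"haplotype_matrix"`.
#' @param snp_a,snp_b SNP ids.
#' @param allele_a,allele_b allele codes (0/1) or nucleotide characters.
#' @return Fraction in \[0, 1\].
#' @export
allele_cooccurrence <- function(haps, snp_a, allele_a, snp_b, allele_b) {
  code <- function(snp, allele) {
    if (allele %in% c(0, 1, "0", "1")) return(as.integer(allele))
    am <- haps$allele_map
    if (is.null(am)) stop_data("nucleotide alleles need an allele_map")
    row <- am[am$snp_id == snp, , drop = FALSE]
    if (!nrow(row)) stop_data("no allele_map entry for ", snp)
    if (allele == row$ref) 0L else if (allele == row$alt) 1L else
      stop_data("allele ", allele, " not segregating at ", snp)
  }
  a <- hap_column(haps, snp_a) == code(snp_a, allele_a)
  b <- hap_column(haps, snp_b) == code(snp_b, allele_b)
  if (!any(a)) stop_data("no haplotype carries the focal allele at ", snp_a)
  mean(b[a])
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' `method = "chisq"`: 1-df chi-square of observed genotype counts against
#' the expected proportions `p^2, 2pq, q^2` at the sample allele
#' frequency. `method = "exact"`: the standard exact test summing, over
#' the conditional distribution of heterozygote counts given the allele
#' counts, the probabilities of all outcomes no more probable than the
#' observed one. The exact test is the default QC choice (no mid-p
#' adjustment is applied).
#'
#' @param counts integer vector `(n_AA, n_Aa, n_aa)` of genotype counts.
#' @param method `"exact"` or `"chisq"`.
#' @return An object of class `"hwe_result"`: `counts`, `chisq` (for the
#'   chi-square method), `p_hwe`, `method`.
#' @examples
#' hwe_test(c(30, 40, 30), method = "chisq")  # chisq = 4, p ~ 0.046
#' @export
hwe_test <- function(counts, method = c("exact", "chisq")) {
  method <- match.arg(method)
  counts <- as.integer(counts)
  if (length(counts) != 3 || any(counts < 0) || sum(counts) == 0)
    stop_data("counts must be 3 nonnegative integers with positive total")
  n <- sum(counts)
  n_a <- 2 * counts[1] + counts[2]  # count of allele A
  if (method == "chisq") {
    p <- n_a / (2 * n)
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(expd == 0)) {
      chisq <- 0; pval <- 1
    } else {
      chisq <- sum((counts - expd)^2 / expd)
      pval <- pchisq(chisq, df = 1, lower.tail = FALSE)
    }
    return(structure(list(counts = counts, chisq = chisq, p_hwe = pval,
                          method = "chisq"), class = "hwe_result"))
  }
  ## exact: distribution of heterozygote count given allele counts
  n_rare <- min(n_a, 2 * n - n_a)
  het_vals <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(het_vals, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) + lfactorial(n) -
      (lfactorial(h) + lfactorial(hom_r) + lfactorial(hom_c)) +
      lfactorial(n_rare) + lfactorial(2 * n - n_rare) - lfactorial(2 * n)
  }, 0)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(counts[2], het_vals)]
  pval <- min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
  structure(list(counts = counts, chisq = NA_real_, p_hwe = pval,
                 method = "exact"), class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE %s test: counts (%s), p = %.4g%s\n", x$method,
              paste(x$counts, collapse = ", "), x$p_hwe,
              if (!is.na(x$chisq)) sprintf(" (chisq = %.3f)", x$chisq) else ""))
  invisible(x)
}

#' Cross-platform genotype concordance at one SNP
#'
#' Fraction of shared samples (intersected by id) with identical
#' non-missing hard calls in two genotype matrices; the check used to
#' validate array genotype calls against an independent assay.
#'
#' @param calls_a,calls_b `"genotype_matrix"` objects with hard calls.
#' @param snp_id SNP to compare.
#' @return Concordant fraction in \[0, 1\].
#' @export
genotype_concordance <- function(calls_a, calls_b, snp_id) {
  stopifnot(inherits(calls_a, "genotype_matrix"),
            inherits(calls_b, "genotype_matrix"))
  ja <- match(snp_id, calls_a$snp_ids)
  jb <- match(snp_id, calls_b$snp_ids)
  if (is.na(ja) || is.na(jb)) stop_data("SNP ", snp_id, " absent from a matrix")
  shared <- intersect(calls_a$sample_ids, calls_b$sample_ids)
  ga <- calls_a$dosages[match(shared, calls_a$sample_ids), ja]
  gb <- calls_b$dosages[match(shared, calls_b$sample_ids), jb]
  ok <- !is.na(ga) & !is.na(gb)
  if (!any(ok)) stop_data("no shared non-missing samples at ", snp_id)
  mean(ga[ok] == gb[ok])
}

#' Post-imputation quality filter
#'
#' Keeps records with imputation `info >= info_min` and minor allele
#' frequency `min(eaf, 1 - eaf) >= maf_min`; both bounds inclusive.
#' Records lacking an `info` value are rejected with reason `"no_info"`.
#'
#' @param records data.frame of summary-statistic records carrying `info`
#'   and `eaf` columns (e.g. the `records` of a `"cohort_stats"`).
#' @param info_min minimum imputation quality (default 0.5).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @return The kept records; attribute `"rejections"` is a data.frame
#'   `snp_id`/`reason` for every dropped record.
#' @export
filter_imputed <- function(records, info_min = 0.5, maf_min = 0.01) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "eaf", "info") %in% names(records)))
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$info)] <- "no_info"
  low_info <- is.na(reason) & records$info < info_min
  reason[low_info] <- "low_info"
  snp_maf <- pmin(records$eaf, 1 - records$eaf)
  low_maf <- is.na(reason) & (is.na(snp_maf) | snp_maf < maf_min)
  reason[low_maf] <- "low_maf"
  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  attr(out, "rejections") <- data.frame(snp_id = records$snp_id[!keep],
                                        reason = reason[!keep],
                                        stringsAsFactors = FALSE)
  out
}

#' Pairwise LD report for a panel
#'
#' Convenience wrapper producing the tab-delimited LD/MAF report schema:
#' one row per SNP pair with frequencies, `D`, `D'`, `r2`, the haplotype
#' count and the panel's population label.
#'
#' @param haps a `"haplotype_matrix"`.
#' @param snp_ids SNPs to include (default all).
#' @param path optional output file.
#' @return data.frame of pairwise LD results.
#' @export
ld_report <- function(haps, snp_ids = haps$snp_ids, path = NULL) {
  pairs <- utils::combn(snp_ids, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    r <- ld_pair(haps, pairs[1, i], pairs[2, i])
    data.frame(snp_a = pairs[1, i], snp_b = pairs[2, i], p_a = r$p_a,
               p_b = r$p_b, p_ab = r$p_ab, D = r$D, D_prime = r$D_prime,
               r2 = r$r2, n_haplotypes = r$n_haplotypes,
               population = haps$population, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
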