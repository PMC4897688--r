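## Readers, writers and allele harmonization for per-cohort GWAS summary
## statistics. A cohort is a "cohort_stats" object: metadata plus a
## data.frame of per-SNP records. Positions are 1-based throughout (VCF
## convention); no coordinate conversion layer exists.

SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "p", "n_cases", "n_controls", "info")

#' Construct a cohort summary-statistics object
#'
#' Bundles a per-SNP association table with cohort metadata. Records are
#' validated: `se` must be positive, `eaf` (when present) in \[0, 1\],
#' effect and other alleles distinct, and SNP ids unique within the cohort.
#' A missing `p` is recomputed from the Wald statistic as
#' `2 * pnorm(-abs(beta / se))`.
#'
#' @param records data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, and optionally `chrom`, `pos`, `eaf`,
#'   `p`, `n_cases`, `n_controls`, `info`.
#' @param cohort_id character scalar identifying the cohort.
#' @param ancestry non-empty ancestry group label (e.g. `"Asian"`).
#' @param platform genotyping platform label (default `"immunochip"`).
#' @return An object of class `"cohort_stats"`: a list with elements
#'   `cohort_id`, `ancestry`, `platform` and `records`.
#' @examples
#' recs <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "G",
#'                    eaf = 0.1, beta = 0.3, se = 0.05)
#' cohort_stats(recs, "korea_ichip", "Asian")
#' @export
cohort_stats <- function(records, cohort_id, ancestry,
                         platform = "immunochip") {
  if (!nzchar(ancestry)) stop_data("ancestry label must be non-empty")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_data("records lack mandatory columns: ", paste(miss, collapse = ", "))
  for (col in setdiff(SUMSTAT_COLS, names(records)))
    records[[col]] <- if (col %in% c("snp_id", "chrom", "effect_allele",
                                     "other_allele")) NA_character_ else NA_real_
  records <- records[SUMSTAT_COLS]
  if (anyDuplicated(records$snp_id))
    stop_data("duplicate snp_id in cohort ", cohort_id)
  if (any(!is.finite(records$se) | records$se <= 0))
    stop_data("all se must be finite and > 0 in cohort ", cohort_id)
  bad_eaf <- !is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1)
  if (any(bad_eaf)) stop_data("eaf outside [0, 1] in cohort ", cohort_id)
  if (any(records$effect_allele == records$other_allele))
    stop_data("effect_allele equals other_allele in cohort ", cohort_id)
  fix_p <- is.na(records$p) & is.finite(records$beta)
  records$p[fix_p] <- 2 * pnorm(-abs(records$beta[fix_p] / records$se[fix_p]))
  structure(list(cohort_id = as.character(cohort_id),
                 ancestry = as.character(ancestry),
                 platform = as.character(platform),
                 records = records),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("Cohort summary statistics: ", x$cohort_id,
      " (", x$ancestry, ", ", x$platform, ")\n", sep = "")
  cat("  ", nrow(x$records), " SNP records\n", sep = "")
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej))
    cat("  ", nrow(rej), " malformed input rows rejected\n", sep = "")
  invisible(x)
}

#' Read cohort summary statistics from a tab-delimited file
#'
#' The file must be tab-delimited with a header naming at least `snp`,
#' `effect_allele`, `other_allele`, `beta`, `se`; optional columns are
#' `chrom`, `pos`, `eaf`, `p`, `n_cases`, `n_controls`, `info`. Column
#' order is irrelevant. `.` denotes a missing value. Malformed rows
#' (non-numeric or non-positive `se`, non-numeric `beta`, `eaf` outside
#' \[0, 1\], identical alleles) are dropped, counted, and reported in the
#' `"rejected"` attribute of the result.
#'
#' @param path path to the summary-statistics file.
#' @param cohort_id,ancestry,platform cohort metadata, see [cohort_stats()].
#' @return A `"cohort_stats"` object; attribute `"rejected"` holds a
#'   data.frame of dropped rows with a `reason` column.
#' @export
read_sumstats <- function(path, cohort_id, ancestry,
                          platform = "immunochip") {
  if (!file.exists(path)) stop_config("summary-statistics file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", na.strings = ".",
                    colClasses = "character", check.names = FALSE)
  names(raw)[names(raw) == "snp"] <- "snp_id"
  need <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_config(path, ": missing mandatory columns: ",
                paste(miss, collapse = ", "))
  num_cols <- c("pos", "eaf", "beta", "se", "p", "n_cases", "n_controls",
                "info")
  parsed <- raw
  for (col in intersect(num_cols, names(raw)))
    parsed[[col]] <- suppressWarnings(as.numeric(raw[[col]]))

  reason <- rep(NA_character_, nrow(parsed))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  flag(!is.na(raw$beta) & is.na(parsed$beta), "non_numeric_beta")
  flag(!is.na(raw$se) & is.na(parsed$se), "non_numeric_se")
  flag(is.na(parsed$beta), "missing_beta")
  flag(is.na(parsed$se), "missing_se")
  flag(parsed$se <= 0, "nonpositive_se")
  if ("eaf" %in% names(parsed))
    flag(parsed$eaf < 0 | parsed$eaf > 1, "eaf_out_of_range")
  flag(is.na(raw$snp_id) | !nzchar(raw$snp_id), "missing_snp_id")
  flag(toupper(raw$effect_allele) == toupper(raw$other_allele),
       "identical_alleles")

  keep <- is.na(reason)
  rejected <- cbind(raw[!keep, , drop = FALSE],
                    reason = reason[!keep])
  rownames(rejected) <- NULL
  good <- parsed[keep, , drop = FALSE]
  good$effect_allele <- toupper(good$effect_allele)
  good$other_allele <- toupper(good$other_allele)
  out <- cohort_stats(good, cohort_id, ancestry, platform)
  attr(out, "rejected") <- rejected
  if (nrow(rejected))
    message(cohort_id, ": rejected ", nrow(rejected), " malformed rows (",
            paste(unique(rejected$reason), collapse = ", "), ")")
  out
}

#' Write cohort summary statistics in canonical form
#'
#' Serializes the cohort's records to the tab-delimited interchange format
#' read by [read_sumstats()], with the canonical column order and `.` for
#' missing values, so write-then-read reproduces the object.
#'
#' @param cohort a `"cohort_stats"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_stats"))
  out <- cohort$records
  names(out)[names(out) == "snp_id"] <- "snp"
  out[] <- lapply(out, function(x) {
    ## %.17g round-trips doubles exactly through the text format
    x <- if (is.double(x)) sprintf("%.17g", x) else as.character(x)
    x[is.na(x) | x == "NA"] <- "."
    x
  })
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_strand_ambiguous <- function(a1, a2) {
  pair <- paste(pmin(a1, a2), pmax(a1, a2))
  pair %in% c("A T", "C G")
}

#' Harmonize effect alleles across cohorts
#'
#' Aligns the sign convention of per-cohort effects so that the Q
#' statistics downstream compare betas for the same allele. For each SNP
#' the reference orientation is taken from the first cohort (after sorting
#' cohort ids) that carries it, with the alphabetically-first of its two
#' alleles as the effect allele; cohorts listing the swapped orientation
#' get `beta` negated and `eaf` replaced by `1 - eaf`. Cohorts whose
#' allele pair cannot be reconciled (e.g. A/C vs A/G) have that SNP
#' dropped from the joint analysis, with the drop logged. Strand-ambiguous
#' SNPs (A/T, C/G) are retained but flagged in a logical `ambiguous`
#' column; no frequency-based strand resolution is attempted.
#'
#' The operation is idempotent: harmonized input passes through unchanged.
#'
#' @param cohorts list of `"cohort_stats"` objects.
#' @return List of harmonized `"cohort_stats"` objects (same order as the
#'   input), with attributes `"flipped"` (data.frame cohort_id/snp_id of
#'   sign flips) and `"dropped"` (irreconcilable records).
#' @export
harmonize_alleles <- function(cohorts) {
  if (!length(cohorts)) stop_data("harmonize_alleles: need at least 1 cohort")
  stopifnot(all(vapply(cohorts, inherits, TRUE, "cohort_stats")))
  ord <- order(vapply(cohorts, `[[`, "", "cohort_id"))
  ## reference orientation per SNP: first carrying cohort in id-sorted order
  ref_ea <- ref_oa <- character(0)
  for (i in ord) {
    recs <- cohorts[[i]]$records
    new <- !(recs$snp_id %in% names(ref_ea))
    if (any(new)) {
      a1 <- recs$effect_allele[new]; a2 <- recs$other_allele[new]
      ea <- pmin(a1, a2); oa <- pmax(a1, a2)
      ref_ea <- c(ref_ea, setNames(ea, recs$snp_id[new]))
      ref_oa <- c(ref_oa, setNames(oa, recs$snp_id[new]))
    }
  }
  flipped <- dropped <- list()
  out <- lapply(cohorts, function(co) {
    recs <- co$records
    tea <- unname(ref_ea[recs$snp_id]); toa <- unname(ref_oa[recs$snp_id])
    ok_as_is <- recs$effect_allele == tea & recs$other_allele == toa
    swapped <- recs$effect_allele == toa & recs$other_allele == tea
    bad <- !(ok_as_is | swapped)
    if (any(swapped)) {
      recs$beta[swapped] <- -recs$beta[swapped]
      recs$eaf[swapped] <- 1 - recs$eaf[swapped]
      recs$effect_allele[swapped] <- tea[swapped]
      recs$other_allele[swapped] <- toa[swapped]
      flipped[[co$cohort_id]] <<- data.frame(
        cohort_id = co$cohort_id, snp_id = recs$snp_id[swapped],
        stringsAsFactors = FALSE)
    }
    if (any(bad)) {
      dropped[[co$cohort_id]] <<- data.frame(
        cohort_id = co$cohort_id, snp_id = recs$snp_id[bad],
        reason = "irreconcilable_alleles", stringsAsFactors = FALSE)
      message(co$cohort_id, ": dropped ", sum(bad),
              " SNP(s) with irreconcilable alleles")
      recs <- recs[!bad, , drop = FALSE]
    }
    recs$ambiguous <- is_strand_ambiguous(recs$effect_allele,
                                          recs$other_allele)
    co$records <- recs
    co
  })
  attr(out, "flipped") <- if (length(flipped))
    do.call(rbind, unname(flipped)) else
    data.frame(cohort_id = character(0), snp_id = character(0))
  attr(out, "dropped") <- if (length(dropped))
    do.call(rbind, unname(dropped)) else
    data.frame(cohort_id = character(0), snp_id = character(0),
               reason = character(0))
  out
}

#' Per-SNP cohort availability
#'
#' Which cohorts carry each SNP; downstream analyses use contributing
#' cohorts only, so `k` varies by SNP.
#'
#' @param cohorts list of `"cohort_stats"` objects.
#' @return data.frame `snp_id`, `cohort_id`, `ancestry` (one row per
#'   SNP-cohort pair).
#' @export
snp_availability <- function(cohorts) {
  do.call(rbind, lapply(cohorts, function(co)
    data.frame(snp_id = co$records$snp_id, cohort_id = co$cohort_id,
               ancestry = co$ancestry, stringsAsFactors = FALSE)))
}
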