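## End-to-end orchestration: read cohorts per a YAML config, harmonize
## alleles, run the between-ancestry scan, and write the scan table,
## hits, and a reproducibility manifest. The follow-up stage
## characterizes hits with per-population allele frequencies, LD to
## companion SNPs, allele co-occurrence and association power.

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$cohorts) || !length(config$cohorts))
    stop_config("config must list cohorts[]")
  for (co in config$cohorts) {
    if (is.null(co$path) || is.null(co$id))
      stop_config("every cohort entry needs path and id")
    if (is.null(co$ancestry) &&
        is.null(config$grouping[[co$id]]))
      stop_config("cohort ", co$id, " has no ancestry/grouping entry")
  }
  if (is.null(config$scan)) config$scan <- list()
  if (is.null(config$scan$alpha)) config$scan$alpha <- 0.05
  if (is.null(config$scan$n_independent))
    config$scan$n_independent <- 26146
  config
}

#' Run the full heterogeneity scan from a config file
#'
#' Reads each configured cohort file, harmonizes alleles, runs
#' [het_scan()] with the configured grouping, significance level,
#' independent-SNP count and optional null-SNP list, and (when `out_dir`
#' is given) writes the per-SNP scan table, the hit list, a JSON run
#' summary and a run manifest recording input checksums, settings,
#' per-stage record counts, lambda, the threshold and the hits. Re-running
#' with identical inputs and config reproduces an identical manifest
#' apart from nothing: no timestamps are recorded.
#'
#' @param config path to a YAML config, or an equivalent list, with
#'   sections `cohorts[]` (each `id`, `path`, `ancestry`, optional
#'   `platform`), optional `grouping` (cohort id to group map, overriding
#'   per-cohort ancestry), and `scan` (`alpha`, `n_independent`,
#'   `null_snps`).
#' @param out_dir optional output directory (created if needed).
#' @return The `"het_scan"` object, with the manifest list in attribute
#'   `"manifest"`.
#' @export
run_scan <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  cohorts <- lapply(cfg$cohorts, function(co) {
    anc <- if (!is.null(cfg$grouping[[co$id]])) cfg$grouping[[co$id]] else
      co$ancestry
    read_sumstats(co$path, cohort_id = co$id, ancestry = anc,
                  platform = if (is.null(co$platform)) "unknown" else
                    co$platform)
  })
  n_in <- vapply(cohorts, function(co) nrow(co$records), 0L)
  harm <- harmonize_alleles(cohorts)
  scan <- het_scan(harm,
                   null_snps = cfg$scan$null_snps,
                   alpha = cfg$scan$alpha,
                   n_independent = cfg$scan$n_independent,
                   gc_correct = isTRUE(cfg$scan$gc_correct))
  manifest <- list(
    package_version = as.character(utils::packageVersion("hetmap")),
    inputs = data.frame(
      cohort_id = vapply(cfg$cohorts, `[[`, "", "id"),
      path = vapply(cfg$cohorts, `[[`, "", "path"),
      md5 = unname(tools::md5sum(vapply(cfg$cohorts, `[[`, "", "path"))),
      n_records = n_in, stringsAsFactors = FALSE),
    settings = cfg$scan,
    n_snps_scanned = nrow(scan$table),
    n_single_group = length(scan$single_group_snps),
    lambda_gc = scan$lambda_gc,
    threshold = scan$threshold,
    hits = scan$hits$snp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scan(scan, file.path(out_dir, "scan_table.tsv"),
               file.path(out_dir, "scan_summary.json"))
    write.table(scan$hits, file.path(out_dir, "hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  }
  attr(scan, "manifest") <- manifest
  scan
}

#' Follow-up characterization of scan hits
#'
#' For every hit SNP, and in every supplied haplotype panel: the panel
#' minor allele frequency, the mean r-squared to the other hits (when a
#' companion list of length >= 1 exists), and the power of a
#' single-population association test at the panel frequency and the
#' scan's observed per-group effect size. A hit absent from a panel is
#' reported as `"not in panel"` and the run continues.
#'
#' @param scan a `"het_scan"` object.
#' @param panels named list of `"haplotype_matrix"` panels, names matching
#'   the scan's ancestry groups where power is to use that group's
#'   observed effect.
#' @param n_total per-group total sample sizes for the power column
#'   (named vector; defaults to 10,000 per group).
#' @param case_fraction case proportion used by [power_association()].
#' @param alpha significance level for the power column (default the
#'   scan's own threshold).
#' @return data.frame of class `"followup_report"`: one row per hit x
#'   panel with maf, mean_r2, power, and a status column.
#' @export
run_followup <- function(scan, panels, n_total = NULL,
                         case_fraction = 0.25, alpha = NULL) {
  stopifnot(inherits(scan, "het_scan"))
  if (is.null(alpha)) alpha <- scan$threshold
  hits <- scan$hits$snp
  if (!length(hits)) {
    out <- data.frame(snp = character(0), panel = character(0),
                      maf = numeric(0), mean_r2 = numeric(0),
                      power = numeric(0), status = character(0))
    return(structure(out, class = c("followup_report", "data.frame")))
  }
  if (is.null(n_total))
    n_total <- setNames(rep(10000, length(panels)), names(panels))
  rows <- list()
  for (pn in names(panels)) {
    panel <- panels[[pn]]
    beta_col <- paste0("beta_", pn)
    for (h in hits) {
      if (!h %in% panel$snp_ids) {
        rows[[length(rows) + 1]] <- data.frame(
          snp = h, panel = pn, maf = NA_real_, mean_r2 = NA_real_,
          power = NA_real_, status = "not in panel",
          stringsAsFactors = FALSE)
        next
      }
      f <- maf(panel, h)
      others <- setdiff(intersect(hits, panel$snp_ids), h)
      m_r2 <- if (length(others)) mean_r2_to_index(panel, h, others) else
        NA_real_
      eff <- if (beta_col %in% names(scan$table))
        scan$table[scan$table$snp == h, beta_col] else NA_real_
      pw <- if (!is.na(eff) && f > 0)
        power_association(maf = max(min(f, 0.5), 1e-6),
                          or_alt = exp(abs(eff)),
                          n_total = unname(n_total[pn]),
                          case_fraction = case_fraction,
                          alpha = alpha) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        snp = h, panel = pn, maf = f, mean_r2 = m_r2, power = pw,
        status = "ok", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("followup_report", "data.frame"))
}
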