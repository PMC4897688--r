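## Generators for every input the pipeline consumes, with the statistical
## structure the analysis assumes: per-cohort effect estimates scattered
## around their ancestry-group truth with the inverse-variance sampling
## model, block-LD haplotypes with population-specific allele
## frequencies, logistic case-control sampling, and dosage-dependent
## expression. Two fidelities share one configuration: a fast
## summary-statistic path for calibration at many replicates, and an
## individual-level path for association and eQTL testing.

## Run code under a derived RNG substream without disturbing the caller's
## stream. Substreams are keyed per cohort and per SNP so that adding a
## cohort (or SNP) never perturbs the draws of the others.
with_substream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% 2147483647L)
  expr
}

substream_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed)
  for (i in ix) s <- (s * 7919 + i) %% 2147483647
  as.integer(s)
}

#' Simulation configuration for the synthetic study
#'
#' Describes a multi-cohort, two-ancestry case-control design: per-group
#' cohort counts and per-cohort case/control sizes, per-SNP ancestry-
#' specific allele frequencies and true log-odds effects, LD-block
#' structure for haplotype generation, disease prevalence, and the eQTL
#' expression layer. The defaults emulate an Immunochip-style design with
#' 4 Asian and 11 European collections at one tenth of their published
#' sizes (Asian discovery 223 cases / 707 controls, Asian validation
#' 60 / 120 each; European 94 cases / 323 controls each), prevalence 1%.
#'
#' @param groups data.frame with columns `name`, `n_cohorts`, `n_cases`,
#'   `n_controls` (per-cohort counts).
#' @param snp_ids character vector of SNP ids.
#' @param maf M x G matrix (SNPs x groups) of alternate-allele
#'   frequencies, columns named by group; all in (0, 1).
#' @param beta M x G matrix of true per-allele log-odds effects.
#' @param ld_blocks list of `list(snps = <ids>, r2 = <target>)` blocks;
#'   SNPs outside any block are independent.
#' @param prevalence baseline disease probability in (0, 1).
#' @param expression list configuring [gen_expression()]: `probes`
#'   (data.frame probe_id/gene_id/tss/slope), `baseline`, `noise_sd`,
#'   `n_replicates`.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(groups = NULL, snp_ids = paste0("snp", 1:100),
                       maf = NULL, beta = NULL, ld_blocks = list(),
                       prevalence = 0.01, expression = NULL) {
  if (is.null(groups))
    groups <- data.frame(
      name = c("Asian", "Asian", "Asian", "Asian",
               rep("European", 11)),
      n_cases = c(223, 60, 60, 60, rep(94, 11)),
      n_controls = c(707, 120, 120, 120, rep(323, 11)))
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "n_cases", "n_controls") %in% names(groups)))
  if (any(groups$n_cases <= 0) || any(groups$n_controls <= 0))
    stop_data("every cohort needs positive case and control counts")
  gnames <- unique(groups$name)
  m <- length(snp_ids)
  if (is.null(maf))
    maf <- matrix(0.25, m, length(gnames),
                  dimnames = list(snp_ids, gnames))
  if (is.null(beta))
    beta <- matrix(0, m, length(gnames), dimnames = list(snp_ids, gnames))
  maf <- as.matrix(maf); beta <- as.matrix(beta)
  if (any(maf <= 0 | maf >= 1)) stop_data("maf entries must be in (0, 1)")
  if (is.null(colnames(maf))) colnames(maf) <- gnames
  if (is.null(colnames(beta))) colnames(beta) <- gnames
  rownames(maf) <- rownames(beta) <- snp_ids
  for (bl in ld_blocks)
    if (!all(bl$snps %in% snp_ids))
      stop_data("ld_block references undeclared SNPs")
  if (prevalence <= 0 || prevalence >= 1)
    stop_data("prevalence must be in (0, 1)")
  structure(list(groups = groups, snp_ids = snp_ids, maf = maf,
                 beta = beta, ld_blocks = ld_blocks,
                 prevalence = prevalence, expression = expression),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", nrow(x$groups), "cohorts in",
      length(unique(x$groups$name)), "groups;", length(x$snp_ids),
      "SNPs;", length(x$ld_blocks), "LD blocks\n")
  invisible(x)
}

## Standard error of a per-allele log-odds estimate under additive coding,
## from the case/control counts and allele frequency.
wald_se <- function(n_cases, n_controls, maf) {
  n <- n_cases + n_controls
  phi <- n_cases / n
  1 / sqrt(2 * n * maf * (1 - maf) * phi * (1 - phi))
}

#' Generate per-cohort GWAS summary statistics
#'
#' The fast, summary-level fidelity: for cohort i and SNP j the standard
#' error `SE_ij` follows from the cohort's case/control counts and the
#' group allele frequency via the additive-score variance, and the
#' estimate is drawn as `beta_ij ~ Normal(beta_group(j), SE_ij^2)`. The
#' emitted effect-allele frequency carries binomial sampling noise.
#' Deterministic under `seed`, with per-cohort, per-SNP substreams.
#'
#' @param config a `"sim_config"`.
#' @param seed integer seed.
#' @return List of `"cohort_stats"`, one per configured cohort, already
#'   allele-consistent (effect allele "A", other "G" throughout).
#' @export
gen_sumstats <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  m <- length(config$snp_ids)
  lapply(seq_len(nrow(config$groups)), function(ci) {
    g <- config$groups$name[ci]
    nca <- config$groups$n_cases[ci]
    nco <- config$groups$n_controls[ci]
    mafs <- config$maf[, g]
    ses <- wald_se(nca, nco, mafs)
    betas <- numeric(m)
    eafs <- numeric(m)
    for (si in seq_len(m)) {
      sub <- substream_seed(seed, ci, si)
      draws <- with_substream(sub, {
        c(rnorm(1, config$beta[si, g], ses[si]),
          rbinom(1, 2L * (nca + nco), mafs[si]))
      })
      betas[si] <- draws[1]
      eafs[si] <- draws[2] / (2 * (nca + nco))
    }
    cohort_stats(data.frame(snp_id = config$snp_ids, chrom = "1",
                            pos = seq_len(m) * 1000,
                            effect_allele = "A", other_allele = "G",
                            eaf = eafs, beta = betas, se = ses,
                            n_cases = nca, n_controls = nco,
                            stringsAsFactors = FALSE),
                 cohort_id = sprintf("%s_%02d", tolower(g), ci),
                 ancestry = g,
                 platform = "synthetic")
  })
}

## Conditional carriage probabilities linking a SNP of frequency p to a
## latent founder allele of frequency f at correlation rho; errors when
## rho exceeds the frequency-constrained maximum.
latent_conditionals <- function(p, f, rho, snp) {
  cov <- rho * sqrt(p * (1 - p) * f * (1 - f))
  p1 <- p + cov / f          # P(X = 1 | L = 1)
  p0 <- p - cov / (1 - f)    # P(X = 1 | L = 0)
  if (p1 > 1 + 1e-12 || p0 < -1e-12) {
    rho_max <- min(sqrt((1 - p) * f / (p * (1 - f))),
                   sqrt(p * (1 - f) / ((1 - p) * f)))
    stop_data("infeasible LD target at ", snp, ": requested correlation ",
              signif(rho, 4), " exceeds the frequency-constrained maximum ",
              signif(rho_max, 4))
  }
  c(min(max(p1, 0), 1), min(max(p0, 0), 1))
}

#' Generate phased block-LD haplotypes for one ancestry group
#'
#' Within each configured LD block, haplotypes are drawn from a latent
#' two-founder mixture: a block-level founder allele with frequency equal
#' to the mean block allele frequency, to which every member SNP is tied
#' at correlation `r2_target^(1/4)`, giving all SNP pairs in the block an
#' expected pairwise r-squared equal to the target while preserving each
#' SNP's marginal frequency exactly. SNPs outside any block are drawn
#' independently. Infeasible (maf, r2) combinations — a target exceeding
#' the frequency-constrained maximum correlation — raise an error naming
#' the bound.
#'
#' @param config a `"sim_config"`.
#' @param group group name (column of `config$maf`).
#' @param n_samples number of individuals (2x haplotypes; default 200).
#' @param seed integer seed.
#' @return A `"haplotype_matrix"` with `2 * n_samples` rows.
#' @export
gen_haplotypes <- function(config, group, n_samples = 200, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!group %in% colnames(config$maf))
    stop_data("unknown group: ", group)
  n_hap <- 2L * n_samples
  m <- length(config$snp_ids)
  mafs <- config$maf[, group]
  out <- matrix(0L, n_hap, m, dimnames = list(NULL, config$snp_ids))
  in_block <- rep(FALSE, m)
  for (bi in seq_along(config$ld_blocks)) {
    bl <- config$ld_blocks[[bi]]
    idx <- match(bl$snps, config$snp_ids)
    in_block[idx] <- TRUE
    rho <- bl$r2^(1 / 4)
    f <- mean(mafs[idx])
    if (bl$r2 >= 1 - 1e-12 && any(abs(mafs[idx] - f) > 1e-12))
      stop_data("r2 = 1 block needs equal allele frequencies; ",
                "frequency-constrained maximum violated")
    conds <- lapply(seq_along(idx), function(k)
      latent_conditionals(mafs[idx[k]], f, rho, config$snp_ids[idx[k]]))
    sub <- substream_seed(seed, 100000 + bi, match(group, colnames(config$maf)))
    block_draw <- with_substream(sub, {
      L <- rbinom(n_hap, 1, f)
      vapply(seq_along(idx), function(k) {
        pr <- ifelse(L == 1, conds[[k]][1], conds[[k]][2])
        rbinom(n_hap, 1, pr)
      }, integer(n_hap))
    })
    out[, idx] <- block_draw
  }
  for (si in which(!in_block)) {
    sub <- substream_seed(seed, 200000 + si,
                          match(group, colnames(config$maf)))
    out[, si] <- with_substream(sub, rbinom(n_hap, 1, mafs[si]))
  }
  haplotype_matrix(out, sample_ids = sprintf("%s_ind%04d", group,
                                             seq_len(n_samples)),
                   snp_ids = config$snp_ids,
                   allele_map = data.frame(snp_id = config$snp_ids,
                                           ref = "G", alt = "A",
                                           stringsAsFactors = FALSE),
                   population = group)
}

#' Generate an individual-level case-control cohort
#'
#' Draws genotypes as pairs of haplotypes from [gen_haplotypes()],
#' assigns disease status from the logistic model
#' `P(case) = plogis(intercept + sum_j beta_j * dose_j)` with the
#' intercept solved numerically so the marginal case probability equals
#' the configured prevalence, and retains the first `n_cases` cases and
#' `n_controls` controls encountered. An unattainable case count (the
#' sampling pool exhausted) is an error. Optionally injects two
#' subpopulations with shifted allele frequencies to exercise principal-
#' component correction.
#'
#' @param config a `"sim_config"`.
#' @param group group name.
#' @param n_cases,n_controls target counts (defaults: the group's first
#'   configured cohort).
#' @param seed integer seed.
#' @param stratify optional `list(frac = , maf_shift = )` creating a
#'   subpopulation of the given fraction whose allele frequencies are
#'   shifted by `maf_shift` (clamped to (0.01, 0.99)).
#' @param n_pcs number of principal components to return (default 10).
#' @return List with `genotypes` (a `"genotype_matrix"`), `phenotype`
#'   (0/1 vector), `covariates` (PC score matrix), `subgroup` (factor
#'   when stratified).
#' @export
gen_case_control <- function(config, group, n_cases = NULL,
                             n_controls = NULL, seed, stratify = NULL,
                             n_pcs = 10) {
  stopifnot(inherits(config, "sim_config"))
  grows <- config$groups[config$groups$name == group, , drop = FALSE]
  if (!nrow(grows)) stop_data("no cohorts configured for group ", group)
  if (is.null(n_cases)) n_cases <- grows$n_cases[1]
  if (is.null(n_controls)) n_controls <- grows$n_controls[1]
  betas <- config$beta[, group]
  prev <- config$prevalence

  draw_pool <- function(cfg, n, seed_k) {
    haps <- gen_haplotypes(cfg, group, n_samples = n, seed = seed_k)
    haps_to_genotypes(haps)
  }
  n_target <- n_cases + n_controls
  ## expected yield: prevalence fraction becomes cases; size the pool for
  ## the scarcer class with head-room
  pool_n <- ceiling(max(n_cases / prev, n_controls / (1 - prev)) * 1.4) + 200
  if (pool_n > 5e6)
    stop_data("unattainable case count at prevalence ", prev,
              ": required sampling pool exceeds 5e6 individuals")

  cfg <- config
  sub_assign <- NULL
  gm <- draw_pool(cfg, pool_n, substream_seed(seed, 300001))
  if (!is.null(stratify)) {
    ## second stratum with shifted frequencies replaces a fraction of rows
    cfg2 <- config
    cfg2$maf[] <- pmin(pmax(config$maf + stratify$maf_shift, 0.01), 0.99)
    n2 <- round(pool_n * stratify$frac)
    gm2 <- draw_pool(cfg2, max(n2, 1), substream_seed(seed, 300002))
    dos <- rbind(gm$dosages[seq_len(pool_n - n2), , drop = FALSE],
                 gm2$dosages[seq_len(n2), , drop = FALSE])
    sub_assign <- rep(c("s1", "s2"), c(pool_n - n2, n2))
    gm <- genotype_matrix(dos, sprintf("%s_ind%05d", group,
                                       seq_len(pool_n)), config$snp_ids)
  }
  score <- as.vector(gm$dosages %*% betas)
  ## intercept matching the target prevalence on this pool
  a <- uniroot(function(a) mean(plogis(a + score)) - prev,
               lower = qlogis(prev) - abs(max(score)) - 10,
               upper = qlogis(prev) + abs(max(score)) + 10)$root
  y <- with_substream(substream_seed(seed, 300003),
                      rbinom(length(score), 1, plogis(a + score)))
  case_idx <- which(y == 1)[seq_len(min(n_cases, sum(y == 1)))]
  ctrl_idx <- which(y == 0)[seq_len(min(n_controls, sum(y == 0)))]
  if (length(case_idx) < n_cases || length(ctrl_idx) < n_controls)
    stop_data("unattainable case/control counts: pool of ", pool_n,
              " yielded ", sum(y == 1), " cases / ", sum(y == 0),
              " controls")
  sel <- c(case_idx, ctrl_idx)
  gsel <- genotype_matrix(gm$dosages[sel, , drop = FALSE],
                          gm$sample_ids[sel], config$snp_ids)
  pcs <- pc_covariates(gsel, k = n_pcs)
  list(genotypes = gsel,
       phenotype = rep(c(1L, 0L), c(length(case_idx), length(ctrl_idx))),
       covariates = pcs,
       subgroup = if (!is.null(sub_assign)) factor(sub_assign[sel]))
}

#' Generate probe-level expression tied to allele dosage
#'
#' For each configured probe, log2 expression is
#' `baseline + slope * dosage + Normal(0, noise_sd)`, drawn independently
#' per replicate, then exponentiated (base 2) so the pipeline's own log
#' step applies. Defaults emulate a small lymphoblastoid eQTL panel.
#'
#' @param config a `"sim_config"` whose `expression` element configures
#'   probes (`probe_id`, `gene_id`, `tss`, `slope`, and optionally a
#'   per-probe `baseline`), `baseline` (shared default 7), `noise_sd`
#'   (default 1) and `n_replicates` (default 2).
#' @param dosages a `"genotype_matrix"` containing `snp_id`.
#' @param snp_id the regulatory SNP whose dosage drives expression.
#' @param seed integer seed.
#' @return An `"expression_matrix"` of raw intensities with
#'   `n_replicates` columns per individual.
#' @export
gen_expression <- function(config, dosages, snp_id, seed) {
  stopifnot(inherits(config, "sim_config"),
            inherits(dosages, "genotype_matrix"))
  ex <- config$expression
  if (is.null(ex) || is.null(ex$probes))
    stop_data("config$expression$probes must be configured")
  probes <- as.data.frame(ex$probes, stringsAsFactors = FALSE)
  baseline <- if (is.null(ex$baseline)) 7 else ex$baseline
  noise_sd <- if (is.null(ex$noise_sd)) 1 else ex$noise_sd
  n_rep <- if (is.null(ex$n_replicates)) 2L else as.integer(ex$n_replicates)
  j <- match(snp_id, dosages$snp_ids)
  if (is.na(j)) stop_data("SNP ", snp_id, " not in dosage matrix")
  dose <- dosages$dosages[, j]
  n <- length(dose)
  base_p <- if ("baseline" %in% names(probes)) probes$baseline else
    rep(baseline, nrow(probes))
  vals <- matrix(NA_real_, nrow(probes), n * n_rep)
  for (pi in seq_len(nrow(probes))) {
    mu <- base_p[pi] + probes$slope[pi] * dose
    noise <- with_substream(substream_seed(seed, 400000 + pi),
                            rnorm(n * n_rep, 0, noise_sd))
    vals[pi, ] <- 2^(rep(mu, each = n_rep) + noise)
  }
  expression_matrix(vals, probes[c("probe_id", "gene_id", "tss")],
                    sample_ids = rep(dosages$sample_ids, each = n_rep),
                    replicate_ids = rep(seq_len(n_rep), n))
}
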