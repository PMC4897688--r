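make_gm <- function(dosages, ids = paste0("i", seq_len(nrow(dosages)))) {
  genotype_matrix(dosages, ids, colnames(dosages))
}

test_that("logistic association on a binary exposure reproduces the 2x2 odds ratio", {
  # cases: 300 carriers / 700 non; controls: 200 carriers / 800 non
  dose <- c(rep(1, 300), rep(0, 700), rep(1, 200), rep(0, 800))
  y <- rep(c(1, 0), c(1000, 1000))
  gm <- make_gm(matrix(dose, ncol = 1, dimnames = list(NULL, "rs1")))
  fit <- logistic_assoc(gm, y, "rs1")
  or_table <- (300 * 800) / (700 * 200)
  expect_equal(fit$or, or_table, tolerance = 1e-6)
  expect_equal(fit$beta, log(or_table), tolerance = 1e-6)
  expect_equal(fit$p, 2 * pnorm(-abs(fit$z)), tolerance = 1e-12)
})

test_that("null dosage gives calibrated z statistics", {
  set.seed(88)
  ok <- vapply(1:40, function(i) {
    dose <- rbinom(2000, 2, 0.3)
    y <- rbinom(2000, 1, 0.3)
    gm <- make_gm(matrix(dose, ncol = 1, dimnames = list(NULL, "rs1")))
    abs(logistic_assoc(gm, y, "rs1")$z) < 3
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("a planted odds ratio is recovered at realistic sample size", {
  cfg <- sim_config(groups = data.frame(name = "Asian", n_cases = 1100,
                                        n_controls = 3589),
                    snp_ids = c("rs_causal", "rs_null"),
                    maf = matrix(c(0.112, 0.3), 2, 1,
                                 dimnames = list(NULL, "Asian")),
                    beta = matrix(c(log(1.38), 0), 2, 1,
                                  dimnames = list(NULL, "Asian")),
                    prevalence = 0.05)
  cc <- gen_case_control(cfg, "Asian", seed = 97)
  fit <- logistic_assoc(cc$genotypes, cc$phenotype, "rs_causal",
                        covariates = cc$covariates)
  expect_lt(abs(fit$beta - log(1.38)), 3 * fit$se)
})

test_that("degenerate dosages and separation are named errors", {
  gm <- make_gm(matrix(1, 50, 1, dimnames = list(NULL, "rs1")))
  expect_error(logistic_assoc(gm, rbinom(50, 1, 0.5), "rs1"),
               "zero-variance", class = "hetmap_data_error")
  # perfectly separating dosage
  dose <- rep(c(2, 0), each = 30)
  y <- rep(c(1, 0), each = 30)
  gm2 <- make_gm(matrix(dose, ncol = 1, dimnames = list(NULL, "rs1")))
  expect_error(logistic_assoc(gm2, y, "rs1"), "rs1",
               class = "hetmap_data_error")
})

test_that("conditional analysis on the causal SNP absorbs a proxy signal", {
  set.seed(55)
  n <- 3000
  causal <- rbinom(n, 2, 0.3)
  # proxy correlated with the causal dosage
  proxy <- pmin(pmax(causal + rbinom(n, 1, 0.2) - rbinom(n, 1, 0.2), 0), 2)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * causal))
  gm <- make_gm(cbind(causal = causal, proxy = proxy))
  marg <- logistic_assoc(gm, y, "proxy")
  cond <- logistic_assoc(gm, y, "proxy", condition_snp = "causal")
  expect_lt(marg$p, 1e-4)
  expect_gt(cond$p, 0.001)
  expect_equal(cond$conditioned_on, "causal")
})

test_that("quantile normalization across replicates behaves at its fixed points", {
  pi <- data.frame(probe_id = paste0("p", 1:3), gene_id = "g1", tss = 1000)
  # identical replicates: pure log2 transform after collapse
  v <- matrix(2^c(1, 2, 3, 1, 2, 3), 3, 2)
  em <- expression_matrix(v, pi, sample_ids = c("a", "a"),
                          replicate_ids = c(1, 2))
  norm <- quantile_normalize_replicates(em)
  expect_equal(as.numeric(norm$values), c(1, 2, 3))
  # single-replicate individuals: pure log transform
  em1 <- expression_matrix(v, pi, sample_ids = c("a", "b"))
  norm1 <- quantile_normalize_replicates(em1)
  expect_equal(norm1$values, log2(v), ignore_attr = TRUE)
  # nonpositive values refuse the log
  bad <- v; bad[1] <- 0
  expect_error(quantile_normalize_replicates(
    expression_matrix(bad, pi, c("a", "a"), c(1, 2))),
    class = "hetmap_data_error")
})

test_that("rank-identical shifted replicates collapse to averaged quantiles", {
  pi <- data.frame(probe_id = paste0("p", 1:3), gene_id = "g1", tss = 1000)
  r1 <- c(1, 2, 3)
  r2 <- c(2, 3, 4)  # same ranks, shifted by 1 on the log scale
  em <- expression_matrix(2^cbind(r1, r2), pi, sample_ids = c("a", "a"),
                          replicate_ids = c(1, 2))
  norm <- quantile_normalize_replicates(em)
  # each rank maps to the mean of the sorted values: (1+2)/2, (2+3)/2, (3+4)/2
  expect_equal(as.numeric(norm$values), c(1.5, 2.5, 3.5))
})

test_that("quantile normalization is invariant to replicate column order", {
  set.seed(20)
  pi <- data.frame(probe_id = paste0("p", 1:5), gene_id = "g1", tss = 0)
  v <- matrix(2^rnorm(20, 7), 5, 4)
  em <- expression_matrix(v, pi, sample_ids = c("a", "a", "b", "b"),
                          replicate_ids = c(1, 2, 1, 2))
  em_swap <- expression_matrix(v[, c(2, 1, 4, 3)], pi,
                               sample_ids = c("a", "a", "b", "b"),
                               replicate_ids = c(1, 2, 1, 2))
  expect_equal(quantile_normalize_replicates(em)$values,
               quantile_normalize_replicates(em_swap)$values,
               ignore_attr = TRUE)
})

test_that("median centering zeroes every column median and is idempotent", {
  pi <- data.frame(probe_id = paste0("p", 1:5), gene_id = "g1", tss = 0)
  zero <- expression_matrix(matrix(0, 5, 3), pi, paste0("i", 1:3))
  expect_equal(median_normalize_individuals(zero)$values, zero$values,
               ignore_attr = TRUE)
  set.seed(4)
  em <- expression_matrix(matrix(rnorm(15, 5), 5, 3), pi, paste0("i", 1:3))
  cen <- median_normalize_individuals(em)
  expect_equal(unname(apply(cen$values, 2, median)), rep(0, 3))
  expect_equal(median_normalize_individuals(cen)$values, cen$values,
               ignore_attr = TRUE)
  # a column with median 5 is shifted by -5
  shift <- expression_matrix(matrix(5, 5, 1), pi, "i1")
  expect_equal(as.numeric(median_normalize_individuals(shift)$values),
               rep(0, 5))
})

test_that("eQTL scan windows probes, corrects over probes tested, and recovers slopes", {
  set.seed(85)
  n <- 85
  dose <- rbinom(n, 2, 0.3)
  gm <- make_gm(matrix(dose, ncol = 1, dimnames = list(NULL, "rs_t")),
                ids = paste0("i", 1:n))
  snp_pos <- 1e6
  probes <- data.frame(probe_id = paste0("p", 1:6),
                       gene_id = c("g1", "g1", "g2", "g3", "g3", "g4"),
                       tss = c(9e5, 9.5e5, 1.05e6, 1.2e6, 1.25e6, 2e6),
                       slope = c(0.5, 0, 0, 0, 0, 0))
  # direct log-scale expression fixture: slope on probe 1 only
  vals <- 2^t(vapply(seq_len(6), function(i)
    7 + probes$slope[i] * dose + rnorm(n, 0, 0.5), numeric(n)))
  em <- expression_matrix(vals, probes[c("probe_id", "gene_id", "tss")],
                          sample_ids = paste0("i", 1:n))
  norm <- quantile_normalize_replicates(em)
  res <- eqtl_scan(norm, gm, "rs_t", snp_pos, window_kb = 300)
  # p6 at 1 Mb away is outside the 300-kb window
  expect_equal(nrow(res), 5)
  expect_false("p6" %in% res$probe_id)
  # Bonferroni multiplies by the number of probes tested while < 1
  sub <- res[res$p_bonferroni < 1, ]
  expect_equal(sub$p_bonferroni / sub$p_nominal, rep(5, nrow(sub)))
  # the regulated probe has the smallest p and a slope within 3 SE of truth
  expect_equal(res$probe_id[1], "p1")
  i1 <- which(res$probe_id == "p1")
  expect_lt(abs(res$slope[i1] - 0.5), 3 * res$se[i1])
  # no probe in window: empty result with a warning
  far <- expression_matrix(vals, transform(probes[c("probe_id", "gene_id",
                                                    "tss")], tss = 1e8),
                           sample_ids = paste0("i", 1:n))
  expect_warning(empty <- eqtl_scan(quantile_normalize_replicates(far),
                                    gm, "rs_t", snp_pos), "no probe")
  expect_equal(nrow(empty), 0)
})

test_that("null expression yields uniform eQTL p-values over seeds", {
  set.seed(66)
  pvals <- vapply(1:60, function(i) {
    n <- 60
    dose <- rbinom(n, 2, 0.3)
    gm <- make_gm(matrix(dose, ncol = 1, dimnames = list(NULL, "rs_t")),
                  ids = paste0("i", 1:n))
    probes <- data.frame(probe_id = "p1", gene_id = "g1", tss = 1000)
    em <- expression_matrix(matrix(2^rnorm(n, 7), 1, n), probes,
                            sample_ids = paste0("i", 1:n))
    eqtl_scan(quantile_normalize_replicates(em), gm, "rs_t", 1000)$p_nominal
  }, 0)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("principal components capture injected population structure", {
  cfg <- sim_config(groups = data.frame(name = "Asian", n_cases = 150,
                                        n_controls = 300),
                    snp_ids = paste0("s", 1:80),
                    maf = matrix(runif(80, 0.1, 0.5), 80, 1,
                                 dimnames = list(NULL, "Asian")),
                    prevalence = 0.1)
  cc <- gen_case_control(cfg, "Asian", seed = 12,
                         stratify = list(frac = 0.5, maf_shift = 0.25))
  pc1_by_group <- split(cc$covariates[, 1], cc$subgroup)
  gap <- abs(mean(pc1_by_group$s1) - mean(pc1_by_group$s2))
  spread <- sd(cc$covariates[, 1])
  expect_gt(gap, spread)  # PC1 separates the two strata
})
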