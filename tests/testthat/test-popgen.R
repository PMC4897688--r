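test_that("maf counts alleles and folds to the minor side", {
  haps <- make_haps(matrix(0L, 10, 1))
  expect_equal(maf(haps, "s1"), 0)
  m <- matrix(0L, 20, 1); m[1:3] <- 1L
  expect_equal(maf(make_haps(m), "s1"), 0.15)
  m2 <- matrix(1L, 20, 1); m2[1:3] <- 0L  # folded: frequency 0.85 -> 0.15
  expect_equal(maf(make_haps(m2), "s1"), 0.15)
})

test_that("simulated panel recovers a configured frequency within binomial error", {
  cfg <- sim_config(snp_ids = "rs_target",
                    maf = matrix(c(0.112, 0.0067), 1, 2,
                                 dimnames = list(NULL, c("EAS", "EUR"))),
                    groups = data.frame(name = c("EAS", "EUR"),
                                        n_cases = 10, n_controls = 10))
  haps <- gen_haplotypes(cfg, "EAS", n_samples = 185, seed = 2)
  f <- maf(haps, "rs_target")
  expect_lt(abs(f - 0.112), 3 * sqrt(0.112 * 0.888 / 370))
  haps_eur <- gen_haplotypes(cfg, "EUR", n_samples = 2000, seed = 2)
  expect_lt(abs(maf(haps_eur, "rs_target") - 0.0067),
            3 * sqrt(0.0067 * 0.9933 / 4000))
})

test_that("ld_pair reproduces hand-computed D, D' and r2", {
  # identical columns: perfect LD
  m <- cbind(rep(c(1L, 0L), c(6, 14)), rep(c(1L, 0L), c(6, 14)))
  r <- ld_pair(make_haps(m, snp_ids = c("a", "b")), "a", "b")
  expect_equal(r$r2, 1)
  expect_equal(r$D_prime, 1)
  # the four haplotypes equally frequent: equilibrium
  r0 <- ld_pair(make_pair_panel(1, 1, 1, 1), "a", "b")
  expect_equal(r0$D, 0)
  expect_equal(r0$r2, 0)
  # constructed 100-haplotype panel: p_ab=0.5, p_a=0.6, p_b=0.7
  r1 <- ld_pair(make_pair_panel(50, 10, 20, 20), "a", "b")
  expect_equal(r1$p_a, 0.6)
  expect_equal(r1$p_b, 0.7)
  expect_equal(r1$D, 0.08, tolerance = 1e-12)
  expect_equal(r1$r2, 0.0064 / (0.24 * 0.21), tolerance = 1e-12)
})

test_that("ld_pair is symmetric and flags monomorphic columns", {
  set.seed(3)
  haps <- make_haps(matrix(rbinom(200, 1, 0.4), 100, 2),
                    snp_ids = c("a", "b"))
  r_ab <- ld_pair(haps, "a", "b")
  r_ba <- ld_pair(haps, "b", "a")
  expect_equal(r_ab$r2, r_ba$r2, tolerance = 1e-15)
  expect_equal(abs(r_ab$D_prime), abs(r_ba$D_prime), tolerance = 1e-15)

  mono <- make_haps(cbind(rep(0L, 20), rbinom(20, 1, 0.5)),
                    snp_ids = c("a", "b"))
  rm <- ld_pair(mono, "a", "b")
  expect_true(rm$monomorphic)
  expect_equal(rm$r2, 0)
})

test_that("formula r2 equals squared haplotype-table correlation on random panels", {
  set.seed(31)
  checked <- 0
  while (checked < 1000) {
    n <- 2 * sample(10:60, 1)
    m <- cbind(rbinom(n, 1, runif(1, 0.1, 0.9)),
               rbinom(n, 1, runif(1, 0.1, 0.9)))
    if (var(m[, 1]) == 0 || var(m[, 2]) == 0) next
    r <- ld_pair(make_haps(m, snp_ids = c("a", "b")), "a", "b")
    expect_equal(r$r2, cor(m[, 1], m[, 2])^2, tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("mean r2 to an index SNP averages the pairwise values", {
  set.seed(5)
  m <- matrix(rbinom(400, 1, 0.4), 100, 4)
  haps <- make_haps(m)
  expect_equal(mean_r2_to_index(haps, "s1", "s2"),
               ld_pair(haps, "s1", "s2")$r2)
  # index against copies of itself
  dup <- make_haps(m[, c(1, 1, 1)], snp_ids = c("i", "c1", "c2"))
  expect_equal(mean_r2_to_index(dup, "i", c("c1", "c2")), 1)
  # brute-force recomputation oracle
  expected <- mean(vapply(2:4, function(j) cor(m[, 1], m[, j])^2, 0))
  expect_equal(mean_r2_to_index(haps, "s1", paste0("s", 2:4)), expected,
               tolerance = 1e-12)
  expect_error(mean_r2_to_index(haps, "s1", character(0)),
               class = "hetmap_data_error")
})

test_that("allele co-occurrence recovers planted conditional carriage", {
  # perfect co-segregation and perfect anti-correlation
  seg <- make_pair_panel(10, 0, 0, 10)
  expect_equal(allele_cooccurrence(seg, "a", 1, "b", 1), 1)
  anti <- make_pair_panel(0, 10, 10, 0)
  expect_equal(allele_cooccurrence(anti, "a", 1, "b", 1), 0)
  # planted 99% / 1% conditional carriage in two panels
  pop1 <- make_pair_panel(99, 1, 30, 70)   # P(b=1 | a=1) = 0.99
  pop2 <- make_pair_panel(1, 99, 30, 70)   # P(b=1 | a=1) = 0.01
  expect_equal(allele_cooccurrence(pop1, "a", 1, "b", 1), 0.99)
  expect_equal(allele_cooccurrence(pop2, "a", 1, "b", 1), 0.01)
  # conservation identity: cooccurrence * freq(a) = joint frequency
  r <- ld_pair(pop1, "a", "b")
  expect_equal(allele_cooccurrence(pop1, "a", 1, "b", 1) * r$p_a, r$p_ab,
               tolerance = 1e-12)
  # nucleotide coding through the allele map
  expect_equal(allele_cooccurrence(pop1, "a", "A", "b", "A"), 0.99)
  expect_error(allele_cooccurrence(make_pair_panel(0, 0, 5, 5), "a", 1, "b", 1),
               class = "hetmap_data_error")
})

test_that("HWE chi-square test matches hand-expected counts", {
  perfect <- hwe_test(c(25, 50, 25), method = "chisq")
  expect_equal(perfect$chisq, 0, tolerance = 1e-12)
  expect_equal(perfect$p_hwe, 1)
  dev <- hwe_test(c(30, 40, 30), method = "chisq")
  expect_equal(dev$chisq, 4.0, tolerance = 1e-12)
  expect_equal(dev$p_hwe, 0.0455, tolerance = 1e-3)
  expect_error(hwe_test(c(0, 0, 0)), class = "hetmap_data_error")
})

test_that("exact and chi-square HWE tests agree where decisions are made", {
  # mid-range p-values legitimately differ (the exact test is discrete);
  # the two methods must agree in the decision region and in rank order
  set.seed(77)
  res <- t(vapply(1:1000, function(i) {
    repeat {
      p <- runif(1, 0.2, 0.8)
      n <- sample(50:300, 1)
      g <- table(factor(rbinom(n, 2, p), levels = 0:2))
      counts <- as.integer(g)[3:1]
      pf <- (2 * counts[1] + counts[2]) / (2 * n)
      expd <- n * c(pf^2, 2 * pf * (1 - pf), (1 - pf)^2)
      if (all(expd >= 5)) break
    }
    c(hwe_test(counts, "exact")$p_hwe, hwe_test(counts, "chisq")$p_hwe)
  }, numeric(2)))
  tail_rows <- pmin(res[, 1], res[, 2]) < 0.1
  expect_gte(mean(abs(res[tail_rows, 1] - res[tail_rows, 2]) <= 0.05), 0.95)
  expect_gte(mean((res[, 1] < 0.05) == (res[, 2] < 0.05)), 0.95)
  expect_gt(cor(res[, 1], res[, 2], method = "spearman"), 0.95)
})

test_that("exact HWE p-values are well calibrated under equilibrium", {
  set.seed(404)
  ps <- vapply(1:2000, function(i) {
    g <- table(factor(rbinom(120, 2, 0.4), levels = 0:2))
    hwe_test(as.integer(g)[3:1], "exact")$p_hwe
  }, 0)
  # discrete exact p-values are conservative; sizes must not exceed nominal
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
  expect_lte(mean(ps <= 0.01), 0.01 + 3 * sqrt(0.01 * 0.99 / 2000))
})

test_that("genotype concordance intersects samples and counts matches", {
  g1 <- genotype_matrix(matrix(c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2), 10, 1),
                        paste0("i", 1:10), "rs1")
  expect_equal(genotype_concordance(g1, g1, "rs1"), 1)
  d2 <- g1$dosages; d2[4, 1] <- 0
  g2 <- genotype_matrix(d2, paste0("i", 1:10), "rs1")
  expect_equal(genotype_concordance(g1, g2, "rs1"), 0.9)
  g3 <- genotype_matrix(matrix(1, 3, 1), paste0("x", 1:3), "rs1")
  expect_error(genotype_concordance(g1, g3, "rs1"),
               class = "hetmap_data_error")
})

test_that("post-imputation filter is boundary-inclusive with reasons", {
  recs <- data.frame(
    snp_id = paste0("s", 1:10),
    eaf = c(0.01, 0.3, 0.005, 0.995, 0.2, 0.5, 0.4, 0.02, 0.6, 0.3),
    info = c(0.5, 0.49, 0.9, 0.9, NA, 0.8, 0.51, 0.5, 1.0, 0.45))
  kept <- filter_imputed(recs)
  # boundary record (info = 0.5, eaf = 0.01) is kept
  expect_true("s1" %in% kept$snp_id)
  expect_setequal(kept$snp_id, c("s1", "s6", "s7", "s8", "s9"))
  rej <- attr(kept, "rejections")
  expect_equal(nrow(rej), 5)
  expect_equal(rej$reason[rej$snp_id == "s2"], "low_info")
  expect_equal(rej$reason[rej$snp_id == "s3"], "low_maf")
  expect_equal(rej$reason[rej$snp_id == "s4"], "low_maf")  # folded MAF 0.005
  expect_equal(rej$reason[rej$snp_id == "s5"], "no_info")
  expect_equal(rej$reason[rej$snp_id == "s10"], "low_info")
})

test_that("the LD report has the documented schema", {
  set.seed(9)
  haps <- make_haps(matrix(rbinom(300, 1, 0.3), 100, 3))
  tab <- ld_report(haps)
  expect_equal(nrow(tab), 3)
  expect_named(tab, c("snp_a", "snp_b", "p_a", "p_b", "p_ab", "D",
                      "D_prime", "r2", "n_haplotypes", "population"))
})
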