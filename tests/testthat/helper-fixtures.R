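# Shared fixture builders; everything is generated in code at test time.

# Write a summary-statistics data.frame as the tab-delimited interchange
# format, "." for missing.
write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  out <- df
  out[] <- lapply(out, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "."
    x
  })
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

basic_sumstats_df <- function() {
  data.frame(snp = c("rs1", "rs2", "rs3"),
             chrom = "1", pos = c(100, 200, 300),
             effect_allele = c("A", "C", "T"),
             other_allele = c("G", "T", "C"),
             eaf = c(0.1, 0.25, 0.4),
             beta = c(0.3, -0.1, 0.05),
             se = c(0.05, 0.04, 0.06),
             p = NA, n_cases = 1000, n_controls = 2000, info = NA,
             stringsAsFactors = FALSE)
}

# Haplotype panel from an explicit 2N x M 0/1 matrix.
make_haps <- function(mat, snp_ids = paste0("s", seq_len(ncol(mat))),
                      population = "test") {
  n <- nrow(mat) / 2
  hetmap::haplotype_matrix(mat, sample_ids = paste0("i", seq_len(n)),
                           snp_ids = snp_ids,
                           allele_map = data.frame(snp_id = snp_ids,
                                                   ref = "G", alt = "A",
                                                   stringsAsFactors = FALSE),
                           population = population)
}

# Panel with prescribed two-locus haplotype counts (n11, n10, n01, n00),
# giving exact joint frequencies for LD hand-checks.
make_pair_panel <- function(n11, n10, n01, n00) {
  mat <- cbind(rep(c(1, 1, 0, 0), c(n11, n10, n01, n00)),
               rep(c(1, 0, 1, 0), c(n11, n10, n01, n00)))
  if (nrow(mat) %% 2 == 1) stop("need an even haplotype count")
  make_haps(mat, snp_ids = c("a", "b"))
}
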