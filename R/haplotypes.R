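## Phased haplotype, genotype-dosage and expression containers plus their
## file formats. Haplotypes are a 2N x M binary matrix (two rows per
## sample, 1 = alternate-coded allele), the representation LD and allele
## co-occurrence counting operate on.

#' Construct a phased haplotype matrix
#'
#' @param alleles 2N x M matrix with entries in \{0, 1\}; two consecutive
#'   rows per sample.
#' @param sample_ids length-N character vector.
#' @param snp_ids length-M character vector.
#' @param allele_map optional data.frame `snp_id`, `ref`, `alt` mapping the
#'   0/1 codes to nucleotide alleles.
#' @param population group label for the panel (e.g. `"EAS"`).
#' @return An object of class `"haplotype_matrix"`.
#' @export
haplotype_matrix <- function(alleles, sample_ids, snp_ids,
                             allele_map = NULL, population = "unknown") {
  alleles <- as.matrix(alleles)
  if (nrow(alleles) %% 2 != 0)
    stop_data("haplotype matrix must have an even number of rows")
  if (nrow(alleles) != 2 * length(sample_ids))
    stop_data("need exactly two haplotype rows per sample")
  if (ncol(alleles) != length(snp_ids))
    stop_data("snp_ids length must match the number of columns")
  if (!all(alleles %in% c(0L, 1L)))
    stop_data("haplotype alleles must be 0/1")
  storage.mode(alleles) <- "integer"
  dimnames(alleles) <- list(rep(sample_ids, each = 2), snp_ids)
  if (!is.null(allele_map)) {
    allele_map <- as.data.frame(allele_map, stringsAsFactors = FALSE)
    stopifnot(all(c("snp_id", "ref", "alt") %in% names(allele_map)))
  }
  structure(list(alleles = alleles,
                 sample_ids = as.character(sample_ids),
                 snp_ids = as.character(snp_ids),
                 allele_map = allele_map,
                 population = population),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("Phased haplotypes:", length(x$sample_ids), "samples x",
      length(x$snp_ids), "SNPs, population", x$population, "\n")
  invisible(x)
}

#' Read phased haplotypes from a VCF file
#'
#' Loads phased GT fields ("|"-separated) into a binary haplotype matrix
#' with 0 = REF and 1 = ALT. Multi-allelic sites are dropped with a
#' warning. An unphased genotype is an error naming the sample and site:
#' LD from unphased data is outside this function's contract.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples optional character vector restricting the sample set.
#' @return A `"haplotype_matrix"` with 2 rows per selected sample and an
#'   `allele_map` giving REF/ALT per SNP.
#' @export
read_haplotypes_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop_config("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning("dropping ", sum(multi), " multi-allelic site(s): ",
            paste(fix$ID[multi], collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(fix$ID, names(gt)))
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s))
      stop_data("samples absent from VCF: ", paste(missing_s, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  snp_ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, ":", fix$POS), fix$ID)
  unphased <- which(matrix(grepl("/", gt, fixed = TRUE), nrow(gt)),
                    arr.ind = TRUE)
  if (nrow(unphased))
    stop_data("unphased genotype at site ", snp_ids[unphased[1, 1]],
              " sample ", colnames(gt)[unphased[1, 2]],
              "; phased GT (|) is required")
  n <- ncol(gt); m <- nrow(gt)
  hap <- matrix(0L, nrow = 2 * n, ncol = m)
  for (j in seq_len(m)) {
    parts <- strsplit(gt[j, ], "|", fixed = TRUE)
    a <- suppressWarnings(as.integer(unlist(parts)))
    if (length(a) != 2 * n || anyNA(a))
      stop_data("malformed or missing GT at site ", snp_ids[j])
    hap[, j] <- a
  }
  haplotype_matrix(hap, sample_ids = colnames(gt), snp_ids = snp_ids,
                   allele_map = data.frame(snp_id = snp_ids, ref = fix$REF,
                                           alt = fix$ALT,
                                           stringsAsFactors = FALSE),
                   population = "unknown")
}

#' Write a haplotype matrix as a minimal phased VCF
#'
#' Emits a VCFv4.2 file with phased GT fields that [read_haplotypes_vcf()]
#' reads back identically. Chromosome and position default to placeholder
#' values when the object carries none.
#'
#' @param haps a `"haplotype_matrix"`.
#' @param path output path.
#' @param chrom,pos optional per-SNP chromosome labels and 1-based
#'   positions (defaults: `"1"` and the column index).
#' @return `path`, invisibly.
#' @export
write_haplotypes_vcf <- function(haps, path, chrom = NULL, pos = NULL) {
  stopifnot(inherits(haps, "haplotype_matrix"))
  m <- length(haps$snp_ids)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m)
  am <- haps$allele_map
  ref <- if (!is.null(am)) am$ref[match(haps$snp_ids, am$snp_id)] else rep("A", m)
  alt <- if (!is.null(am)) am$alt[match(haps$snp_ids, am$snp_id)] else rep("G", m)
  ref[is.na(ref)] <- "A"; alt[is.na(alt)] <- "G"
  n <- length(haps$sample_ids)
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", haps$sample_ids), collapse = "\t"))
  a <- haps$alleles
  body <- vapply(seq_len(m), function(j) {
    gts <- paste(a[seq(1, 2 * n, by = 2), j], a[seq(2, 2 * n, by = 2), j],
                 sep = "|")
    paste(c(chrom[j], pos[j], haps$snp_ids[j], ref[j], alt[j], ".", "PASS",
            ".", "GT", gts), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read or write the plain-text haplotype format
#'
#' A whitespace-delimited 0/1 matrix with a two-line header: line 1 the
#' sample ids (N entries), line 2 the SNP ids (M entries), then 2N rows of
#' M alleles.
#'
#' @param path file path.
#' @param population panel label attached on read.
#' @return `read_haplotype_matrix()` a `"haplotype_matrix"`;
#'   `write_haplotype_matrix()` the path, invisibly.
#' @export
read_haplotype_matrix <- function(path, population = "unknown") {
  lines <- readLines(path)
  if (length(lines) < 3) stop_config("haplotype file too short: ", path)
  sample_ids <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  snp_ids <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  body <- lapply(lines[-(1:2)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  mat <- do.call(rbind, body)
  haplotype_matrix(mat, sample_ids, snp_ids, population = population)
}

#' @rdname read_haplotype_matrix
#' @param haps a `"haplotype_matrix"` to serialize.
#' @export
write_haplotype_matrix <- function(haps, path) {
  stopifnot(inherits(haps, "haplotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(haps$sample_ids, collapse = " "),
               paste(haps$snp_ids, collapse = " ")), con)
  write.table(haps$alleles, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a genotype-dosage matrix
#'
#' @param dosages N x M numeric matrix with values in \[0, 2\] (hard calls
#'   or imputed dosages); `NA` marks missing.
#' @param sample_ids,snp_ids row and column labels.
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(dosages, sample_ids, snp_ids) {
  dosages <- as.matrix(dosages)
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop_data("dosages must lie in [0, 2]")
  dimnames(dosages) <- list(sample_ids, snp_ids)
  structure(list(dosages = dosages,
                 sample_ids = as.character(sample_ids),
                 snp_ids = as.character(snp_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype dosages:", length(x$sample_ids), "samples x",
      length(x$snp_ids), "SNPs\n")
  invisible(x)
}

#' Collapse phased haplotypes to genotype dosages
#'
#' @param haps a `"haplotype_matrix"`.
#' @return A `"genotype_matrix"` of alternate-allele counts (0/1/2).
#' @export
haps_to_genotypes <- function(haps) {
  stopifnot(inherits(haps, "haplotype_matrix"))
  a <- haps$alleles
  n <- length(haps$sample_ids)
  g <- a[seq(1, 2 * n, by = 2), , drop = FALSE] +
    a[seq(2, 2 * n, by = 2), , drop = FALSE]
  genotype_matrix(g, haps$sample_ids, haps$snp_ids)
}

#' Construct an expression matrix with probe annotation
#'
#' @param values probe x column numeric matrix (columns are
#'   individual-replicate measurements); all values finite.
#' @param probe_info data.frame `probe_id`, `gene_id` and optionally `tss`
#'   (transcription start, 1-based) covering every row.
#' @param sample_ids per-column individual ids.
#' @param replicate_ids per-column replicate index (default all 1).
#' @return An object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, probe_info, sample_ids,
                              replicate_ids = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop_data("expression values must be finite")
  probe_info <- as.data.frame(probe_info, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_info)))
  if (nrow(probe_info) != nrow(values))
    stop_data("probe_info must annotate every probe row")
  if (length(sample_ids) != ncol(values))
    stop_data("one sample id per column required")
  if (is.null(replicate_ids)) replicate_ids <- rep(1L, ncol(values))
  dimnames(values) <- list(probe_info$probe_id,
                           paste(sample_ids, replicate_ids, sep = "."))
  structure(list(values = values, probe_info = probe_info,
                 sample_ids = as.character(sample_ids),
                 replicate_ids = as.integer(replicate_ids)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression:", nrow(x$values), "probes x", ncol(x$values),
      "columns (", length(unique(x$sample_ids)), "individuals )\n")
  invisible(x)
}
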