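#' Construct a genotype panel
#'
#' A genotype panel bundles a biallelic SNP genotype matrix (accessions in
#' rows, SNPs in columns, coded as copies of the non-reference allele: 0, 1,
#' 2, or `NA` for missing) with SNP records (identifier, chromosome, 1-based
#' position) and accession records (identifier, chilling-tolerance cluster
#' label).
#'
#' @param geno Numeric matrix, accessions x SNPs, values in \{0, 1, 2, NA\}.
#' @param snps `data.frame` with columns `snp_id`, `chrom`, `pos` (1-based),
#'   one row per column of `geno`, positions sorted within chromosome.
#' @param accessions `data.frame` with columns `accession` and `cluster`,
#'   one row per row of `geno`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, snps, accessions) {
  stopifnot(is.matrix(geno), is.data.frame(snps), is.data.frame(accessions))
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)))
  stopifnot(all(c("accession", "cluster") %in% names(accessions)))
  if (nrow(snps) != ncol(geno))
    stop("`snps` must have one row per genotype column")
  if (nrow(accessions) != nrow(geno))
    stop("`accessions` must have one row per genotype row")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("genotype coding must be 0/1/2 copies of the non-reference allele")
  if (anyDuplicated(snps$snp_id)) stop("duplicated SNP identifiers")
  if (anyDuplicated(accessions$accession)) stop("duplicated accession identifiers")
  # positions must be non-decreasing within each chromosome
  by_chr <- split(snps$pos, snps$chrom)
  if (!all(vapply(by_chr, function(p) !is.unsorted(p), logical(1))))
    stop("SNP positions must be sorted within chromosome")
  dimnames(geno) <- list(accessions$accession, snps$snp_id)
  structure(list(geno = geno, snps = snps, accessions = accessions),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cl <- table(x$accessions$cluster)
  cat(sprintf("genotype_panel: %d accessions x %d SNPs on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$snps$chrom))))
  cat("clusters:", paste(sprintf("%s=%d", names(cl), cl), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("missing genotype fraction: %.4f\n", miss))
  invisible(x)
}

#' Subset a genotype panel by SNP and/or accession index
#'
#' @param panel A [genotype_panel()].
#' @param snp_idx Integer or logical index over SNPs (columns).
#' @param acc_idx Integer or logical index over accessions (rows).
#' @return A `genotype_panel` restricted to the selected rows/columns.
#' @export
subset_panel <- function(panel, snp_idx = NULL, acc_idx = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(snp_idx)) snp_idx <- seq_len(ncol(panel$geno))
  if (is.null(acc_idx)) acc_idx <- seq_len(nrow(panel$geno))
  genotype_panel(panel$geno[acc_idx, snp_idx, drop = FALSE],
                 panel$snps[snp_idx, , drop = FALSE],
                 panel$accessions[acc_idx, , drop = FALSE])
}

#' Per-SNP allele statistics
#'
#' Minor allele frequency, minor allele count and missing fraction are
#' computed on non-missing calls only, counting alleles (two per accession).
#'
#' @param panel A [genotype_panel()].
#' @return `data.frame` with columns `snp_id`, `n_called`, `alt_freq`, `maf`,
#'   `mac`, `missing_frac`.
#' @export
snp_stats <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$geno
  n_called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)            # non-reference allele count
  total <- 2 * n_called                      # alleles among called accessions
  alt_freq <- ifelse(total > 0, alt / total, NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  mac <- pmin(alt, total - alt)
  data.frame(snp_id = panel$snps$snp_id,
             n_called = n_called,
             alt_freq = alt_freq,
             maf = maf,
             mac = mac,
             missing_frac = 1 - n_called / nrow(g),
             row.names = NULL)
}
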