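#' Read / write the replicate phenotype CSV
#'
#' Tidy replicate format with columns `accession`, `trait`, `temperature_C`,
#' `replicate`, `value_numerator`, `value_denominator` (for EL rows the
#' numerator/denominator pair is initial/total conductivity; for LTSS rows it
#' is alive/initial seedling counts).
#'
#' @param path File path.
#' @return `data.frame` in the replicate format.
#' @export
read_phenotypes <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "trait", "temperature_C", "replicate",
            "value_numerator", "value_denominator")
  if (!all(need %in% names(raw)))
    stop("phenotype CSV must have columns ", paste(need, collapse = ", "))
  raw
}

#' @rdname read_phenotypes
#' @param raw Replicate table to write.
#' @export
write_phenotypes <- function(raw, path) {
  write.csv(raw, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a plain tab-separated genotype matrix
#'
#' SNPs as rows (`snp_id`, `chrom`, `pos`, then one 0/1/2/NA column per
#' accession). Cluster labels travel in an optional companion CSV
#' (`accession`, `cluster`).
#'
#' @param path Matrix file path.
#' @param cluster_path Optional accession-cluster CSV path.
#' @return A [genotype_panel()].
#' @export
read_genotype_matrix <- function(path, cluster_path = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("snp_id", "chrom", "pos")
  if (!all(meta %in% names(tab)))
    stop("genotype matrix must start with columns snp_id, chrom, pos")
  acc <- setdiff(names(tab), meta)
  geno <- t(as.matrix(tab[, acc, drop = FALSE]))
  storage.mode(geno) <- "double"
  clusters <- rep(NA_character_, length(acc))
  if (!is.null(cluster_path)) {
    cl <- read.csv(cluster_path, stringsAsFactors = FALSE)
    clusters <- cl$cluster[match(acc, cl$accession)]
  }
  genotype_panel(geno, tab[, meta],
                 data.frame(accession = acc, cluster = clusters))
}

#' @rdname read_genotype_matrix
#' @param panel Panel to write.
#' @export
write_genotype_matrix <- function(panel, path, cluster_path = NULL) {
  tab <- cbind(panel$snps[, c("snp_id", "chrom", "pos")],
               as.data.frame(t(panel$geno), check.names = FALSE))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(cluster_path))
    write.csv(panel$accessions, cluster_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a genotype panel as plain-text VCF v4.2
#'
#' One sample column per accession, GT field only; inbred 0/2 genotypes map
#' to `0/0` and `1/1`, heterozygotes to `0/1`, missing to `./.`. REF/ALT are
#' placeholder alleles (A/G) unless the panel's `snps` table carries `ref` /
#' `alt` columns.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path (plain text).
#' @export
write_vcf <- function(panel, path) {
  snps <- panel$snps
  ref <- if ("ref" %in% names(snps)) snps$ref else rep("A", nrow(snps))
  alt <- if ("alt" %in% names(snps)) snps$alt else rep("G", nrow(snps))
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(snps), ncol = nrow(panel$geno))
  gg <- t(panel$geno)
  ok <- !is.na(gg)
  gt[ok] <- gt_map[as.character(gg[ok])]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(snps$chrom)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$accessions$accession),
                     collapse = "\t")), con)
  body <- cbind(snps$chrom, snps$pos, snps$snp_id, ref, alt, ".", ".", ".",
                "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF into a genotype panel
#'
#' GT fields are mapped to non-reference allele counts: `0/0` (or `0|0`) to
#' 0, `0/1`/`1/0` to 1, `1/1` to 2, `./.` to missing.
#'
#' @param path VCF path (plain or gzipped; v4.x with GT).
#' @param clusters Optional named cluster-label vector keyed by accession.
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, clusters = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% "0/0"] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x %in% "1/1"] <- 2
    out
  }
  geno <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                 dimnames = list(colnames(gt), rownames(gt)))
  for (i in seq_len(ncol(gt))) geno[i, ] <- code(gt[, i])
  acc <- colnames(gt)
  cl <- if (is.null(clusters)) rep(NA_character_, length(acc))
        else unname(clusters[acc])
  snps <- data.frame(snp_id = rownames(gt),
                     chrom = as.character(v@fix[, "CHROM"]),
                     pos = as.integer(v@fix[, "POS"]),
                     ref = as.character(v@fix[, "REF"]),
                     alt = as.character(v@fix[, "ALT"]),
                     row.names = NULL)
  genotype_panel(geno, snps, data.frame(accession = acc, cluster = cl))
}

#' Read a BED interval file into 1-based inclusive coordinates
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive, so
#' `start` gains 1 and `end` is kept. The conversion round-trips losslessly
#' with [write_bed()].
#'
#' @param path BED path (3+ columns; 4th column taken as interval name).
#' @return `data.frame` with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(bed) < 3) stop("malformed BED: need at least 3 columns")
  if (!is.numeric(bed[[2]]) || !is.numeric(bed[[3]]) ||
      any(bed[[2]] < 0) || any(bed[[3]] <= bed[[2]]))
    stop("malformed BED: invalid interval coordinates")
  data.frame(chrom = as.character(bed[[1]]),
             start = as.integer(bed[[2]]) + 1L,
             end = as.integer(bed[[3]]),
             name = if (ncol(bed) >= 4) as.character(bed[[4]])
                    else sprintf("interval_%d", seq_len(nrow(bed))),
             row.names = NULL)
}

#' @rdname read_bed
#' @param intervals `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`.
#' @export
write_bed <- function(intervals, path) {
  name <- if ("name" %in% names(intervals)) intervals$name
          else if ("qtl" %in% names(intervals)) intervals$qtl
          else sprintf("interval_%d", seq_len(nrow(intervals)))
  bed <- data.frame(intervals$chrom, intervals$start - 1L, intervals$end, name)
  write.table(bed, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a gene annotation (GFF3) into a gene table
#'
#' Keeps `gene`-type records; the description is taken from the
#' `description` attribute (falling back to `Note`), and the
#' transposable-element flag is derived from it via [te_keywords()].
#'
#' @param path GFF3 path.
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `description`, `is_te`.
#' @export
read_gene_annotation <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == "gene"]
  if (!length(genes)) stop("no gene records in annotation")
  get_attr <- function(obj, field) {
    if (!field %in% names(S4Vectors::mcols(obj)))
      return(rep(NA_character_, length(obj)))
    v <- S4Vectors::mcols(obj)[[field]]
    if (methods::is(v, "List")) v <- vapply(v, function(x)
      if (length(x)) paste(x, collapse = " ") else NA_character_, character(1))
    as.character(v)
  }
  descr <- get_attr(genes, "description")
  note <- get_attr(genes, "Note")
  descr[is.na(descr)] <- note[is.na(descr)]
  descr[is.na(descr)] <- ""
  gene_id <- get_attr(genes, "ID")
  nm <- get_attr(genes, "Name")
  gene_id[is.na(gene_id)] <- nm[is.na(gene_id)]
  data.frame(gene_id = gene_id,
             chrom = as.character(GenomicRanges::seqnames(genes)),
             start = GenomicRanges::start(genes),
             end = GenomicRanges::end(genes),
             strand = as.character(GenomicRanges::strand(genes)),
             description = descr,
             is_te = is_te_description(descr),
             row.names = NULL)
}

#' Write an association scan as a tab-separated file
#'
#' @param scan [emmax_scan()] output.
#' @param path Output path.
#' @export
write_scan <- function(scan, path) {
  write.table(scan, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Q-Q plot data as CSV
#'
#' @param p P-value vector (passed to [qq_inflation()]).
#' @param path Output path.
#' @return The inflation factor lambda, invisibly.
#' @export
write_qq_data <- function(p, path) {
  qq <- qq_inflation(p)
  write.csv(qq$df, path, row.names = FALSE, quote = FALSE)
  invisible(qq$lambda)
}

#' Load the packaged multi-trait QTL reference table
#'
#' The curated 40-row table of multi-trait QTL (chromosome, interval, mapping
#' phenotype labels, cluster-overlap tag, peak LOD, peak-SNP gene, published
#' QTL names) shipped with the package; see the transcription note in the
#' file header. Validated on load.
#'
#' @return `data.frame` with columns `qtl`, `chr`, `start`, `end`,
#'   `phenotypes`, `cluster_overlap`, `peak_lod`, `peak_snp_gene`,
#'   `published_qtl`, plus a list-column `sources` of split phenotype labels.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_multitrait_qtl.csv",
                      package = "coldqtl", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                  na.strings = NULL)
  need <- c("qtl", "chr", "start", "end", "phenotypes", "cluster_overlap",
            "peak_lod", "peak_snp_gene", "published_qtl")
  if (!identical(names(tab), need) ||
      nrow(tab) != 40L ||
      !all(tab$chr %in% 1:12) ||
      !all(tab$start < tab$end) ||
      !is.numeric(tab$peak_lod) || any(is.na(tab$peak_lod)) ||
      any(tab$phenotypes == ""))
    stop("packaged multi-trait QTL table is corrupted")
  tab$sources <- I(strsplit(tab$phenotypes, "+", fixed = TRUE))
  tab
}
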