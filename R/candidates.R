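#' Transposable-element keyword set
#'
#' Case-insensitive substrings of gene descriptions that mark a gene model as
#' a transposable element.
#' @export
te_keywords <- function() c("transposon", "retrotransposon", "transposable")

is_te_description <- function(description, keywords = te_keywords()) {
  pat <- paste(keywords, collapse = "|")
  grepl(pat, description, ignore.case = TRUE)
}

gene_granges <- function(genes) {
  GenomicRanges::GRanges(seqnames = as.character(genes$chrom),
                         ranges = IRanges::IRanges(start = genes$start,
                                                   end = genes$end))
}

#' Genes overlapping QTL intervals
#'
#' A gene belongs to a QTL when gene body and QTL interval share at least
#' 1 bp (partial overlap counts); each retained gene is annotated with the
#' names of its QTL.
#'
#' @param qtls QTL table with `chrom`, `start`, `end` and optionally a `qtl`
#'   name column.
#' @param genes Gene table from [read_gene_annotation()] (columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `description`, `is_te`).
#' @return Subset of `genes` with an added `qtl_hits` column.
#' @export
genes_in_qtl <- function(qtls, genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (!nrow(qtls) || !nrow(genes)) return(genes[0, , drop = FALSE])
  qnames <- if ("qtl" %in% names(qtls)) qtls$qtl else
    sprintf("qtl_%s_%d_%d", qtls$chrom, qtls$start, qtls$end)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gene_granges(genes), qtl_granges(qtls),
                                minoverlap = 1L))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep <- sort(unique(qh))
  out <- genes[keep, , drop = FALSE]
  out$qtl_hits <- vapply(keep, function(i)
    paste(unique(qnames[sh[qh == i]]), collapse = ";"), character(1))
  rownames(out) <- NULL
  out
}

#' Remove transposable-element gene models
#'
#' Drops genes whose description matches the TE keyword set
#' (case-insensitive).
#'
#' @param genes Gene table with a `description` column (an `is_te` column is
#'   recomputed from the descriptions).
#' @param keywords Keyword set, defaults to [te_keywords()].
#' @return Gene table without TE genes.
#' @export
purge_transposable_elements <- function(genes, keywords = te_keywords()) {
  stopifnot("description" %in% names(genes))
  te <- is_te_description(genes$description, keywords)
  out <- genes[!te, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(te)
  out
}

#' Genes containing significant SNPs
#'
#' Retains genes with at least one SNP of `p < p_max` (strict) located inside
#' the gene body (`start <= pos <= end`; no promoter window). Supporting
#' SNPs are attached per gene.
#'
#' @param genes Gene table.
#' @param scan SNP table with columns `snp_id`, `chrom`, `pos`, `p` and, for
#'   downstream allele filtering, `trait`, `major_af`, `effect_direction`
#'   (several per-trait scans may be concatenated; add the `trait` column
#'   before `rbind`).
#' @param p_max Significance cutoff (strict `<`), default 1e-4.
#' @return Subset of `genes` with list-column `supporting` (a `data.frame` of
#'   supporting SNP rows per gene) and `n_supporting`.
#' @export
genes_with_significant_snps <- function(genes, scan, p_max = 1e-4) {
  stopifnot(all(c("snp_id", "chrom", "pos", "p") %in% names(scan)))
  sig <- scan[!is.na(scan$p) & scan$p < p_max, , drop = FALSE]
  sup <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    sig[sig$chrom == g$chrom & sig$pos >= g$start & sig$pos <= g$end, ,
        drop = FALSE]
  })
  n_sup <- vapply(sup, nrow, integer(1))
  out <- genes[n_sup > 0, , drop = FALSE]
  out$supporting <- I(sup[n_sup > 0])
  out$n_supporting <- n_sup[n_sup > 0]
  rownames(out) <- NULL
  out
}

#' Tolerant-cluster fraction of a panel
#'
#' @param clusters Vector of per-accession cluster labels; every accession
#'   must be labeled.
#' @param tolerant_label Label (prefix-insensitive match, e.g. `"tolerant"`
#'   matches `"TOL"`) identifying the Tolerant cluster.
#' @return List with `fraction` (unrounded), `percent` (rounded integer
#'   percent for display), `n_tolerant`, `n_total`.
#' @export
tolerant_fraction <- function(clusters, tolerant_label = "tolerant") {
  if (any(is.na(clusters) | clusters == "")) stop("unlabeled accessions")
  lab3 <- toupper(substr(as.character(clusters), 1, 3))
  tol <- lab3 == toupper(substr(tolerant_label, 1, 3))
  frac <- mean(tol)
  if (frac == 0)
    warning("no Tolerant accessions: the major-allele filter degenerates to ",
            "a direction-only filter")
  list(fraction = frac, percent = as.integer(round(100 * frac)),
       n_tolerant = sum(tol), n_total = length(tol))
}

# desired sign of the major allele's effect by trait label:
# EL must decrease (-1); LTSS must increase (+1); LT50 must decrease (-1),
# because a lower lethal temperature means higher tolerance.
trait_effect_rule <- function(trait) {
  ifelse(grepl("^LT50", trait), -1, ifelse(grepl("^E", trait), -1, 1))
}

#' Filter candidates by major-allele frequency and effect direction
#'
#' A gene survives when at least one of its supporting significant SNPs has
#' a major-allele frequency at least the Tolerant-cluster fraction (`>=`, on
#' the unrounded fraction) *and* the major allele moves the trait toward
#' tolerance: decreasing EL, increasing LTSS, decreasing LT50.
#'
#' @param candidates Output of [genes_with_significant_snps()]; supporting
#'   SNPs must carry `trait`, `major_af`, `effect_direction`.
#' @param tolerant_fraction Unrounded Tolerant-cluster fraction (see
#'   [tolerant_fraction()]).
#' @return Surviving subset of `candidates`; per-gene columns
#'   `passes_major_allele` and `passes_effect_direction` are added to the
#'   input semantics described in [candidate_funnel()].
#' @export
filter_by_allele <- function(candidates, tolerant_fraction) {
  stopifnot(is.numeric(tolerant_fraction), length(tolerant_fraction) == 1)
  flags <- allele_flags(candidates, tolerant_fraction)
  out <- candidates[flags$passes_effect_direction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

allele_flags <- function(candidates, tol_frac) {
  pm <- pe <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    s <- candidates$supporting[[i]]
    if (!all(c("major_af", "effect_direction", "trait") %in% names(s)))
      stop("supporting SNPs must carry trait, major_af and effect_direction")
    af_ok <- s$major_af >= tol_frac
    dir_ok <- s$effect_direction == trait_effect_rule(s$trait)
    pm[i] <- any(af_ok)
    pe[i] <- any(af_ok & dir_ok)   # same SNP must pass both
  }
  data.frame(passes_major_allele = pm, passes_effect_direction = pe)
}

#' Candidate-gene filtering cascade
#'
#' Runs the full funnel: genes overlapping QTL, transposable-element purge,
#' significant-SNP presence (`p < p_max` inside the gene body), and the
#' major-allele frequency + effect-direction filter. Each stage's output is
#' a subset of its input; stage counts are reported.
#'
#' @param qtls QTL table (e.g. [multi_trait()] output).
#' @param genes Gene annotation table.
#' @param scan Concatenated per-trait SNP table (see
#'   [genes_with_significant_snps()]).
#' @param clusters Per-accession cluster labels, used to compute the
#'   Tolerant-cluster fraction; alternatively pass `tol_frac` directly.
#' @param tol_frac Optional pre-computed Tolerant fraction.
#' @param p_max Significance cutoff for supporting SNPs.
#' @return List with `candidates` (final gene table), `flags` (per input
#'   gene: `in_qtl`, `is_te`, `has_significant_snp`, `passes_major_allele`,
#'   `passes_effect_direction`), and `counts` (named stage-count vector:
#'   `in_qtl`, `non_te`, `with_significant_snp`, `candidate`).
#' @export
candidate_funnel <- function(qtls, genes, scan, clusters = NULL,
                             tol_frac = NULL, p_max = 1e-4) {
  if (is.null(tol_frac)) {
    if (is.null(clusters)) stop("provide `clusters` or `tol_frac`")
    tol_frac <- tolerant_fraction(clusters)$fraction
  }
  stage1 <- genes_in_qtl(qtls, genes)
  stage2 <- purge_transposable_elements(stage1)
  stage3 <- genes_with_significant_snps(stage2, scan, p_max = p_max)
  fl3 <- allele_flags(stage3, tol_frac)
  final <- stage3[fl3$passes_effect_direction, , drop = FALSE]
  rownames(final) <- NULL

  flags <- data.frame(gene_id = genes$gene_id,
                      in_qtl = genes$gene_id %in% stage1$gene_id,
                      is_te = is_te_description(genes$description),
                      has_significant_snp = genes$gene_id %in% stage3$gene_id,
                      passes_major_allele =
                        genes$gene_id %in% stage3$gene_id[fl3$passes_major_allele],
                      passes_effect_direction =
                        genes$gene_id %in% final$gene_id)
  list(candidates = final,
       flags = flags,
       counts = c(in_qtl = nrow(stage1), non_te = nrow(stage2),
                  with_significant_snp = nrow(stage3),
                  candidate = nrow(final)))
}
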