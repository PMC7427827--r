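#' Select significant SNPs from an association scan
#'
#' A SNP is significant when `-log10(p)` strictly exceeds the threshold
#' (default 4, the Q-Q-plot-derived genome-wide cutoff).
#'
#' @param scan An [emmax_scan()] result (or any `data.frame` with a
#'   `neglog10p` column).
#' @param threshold LOD-style threshold on `-log10(p)` (strict `>`).
#' @return The significant subset of `scan`, position-sorted.
#' @export
significant_snps <- function(scan, threshold = 4) {
  sig <- scan[!is.na(scan$neglog10p) & scan$neglog10p > threshold, , drop = FALSE]
  sig[order(match(sig$chrom, unique(scan$chrom)), sig$pos), , drop = FALSE]
}

# Maximal qualifying windows over position-sorted SNPs of one chromosome:
# window i spans SNP indices i..reach(i) where reach(i) is the last SNP within
# `window` bp of SNP i; it qualifies with >= min_snps members; overlapping
# qualifying windows (sharing a SNP) are unioned into clusters.
call_qtl_chrom <- function(pos, lod, ids, window, min_snps) {
  m <- length(pos)
  reach <- findInterval(pos + window, pos)
  starts <- which(reach - seq_len(m) + 1 >= min_snps)
  # maximality: keep only the leftmost window for each distinct reach
  starts <- starts[c(TRUE, diff(reach[starts]) > 0)[seq_along(starts)]]
  if (!length(starts)) return(NULL)
  clusters <- list()
  cs <- starts[1]; ce <- reach[starts[1]]
  for (i in starts[-1]) {
    if (i <= ce) ce <- max(ce, reach[i])
    else { clusters[[length(clusters) + 1]] <- c(cs, ce); cs <- i; ce <- reach[i] }
  }
  clusters[[length(clusters) + 1]] <- c(cs, ce)
  lapply(clusters, function(cl) {
    memb <- seq(cl[1], cl[2])
    peak <- memb[which.max(lod[memb])]
    list(start = pos[cl[1]], end = pos[cl[2]], n_snps = length(memb),
         members = ids[memb], peak_snp = ids[peak], peak_lod = lod[peak])
  })
}

#' Call QTL intervals from significant SNP clusters
#'
#' A QTL is any maximal run of significant SNPs on one chromosome in which at
#' least `min_snps` SNPs fit inside a `window`-bp region: every maximal
#' window of `min_snps` or more significant SNPs spanning at most `window` bp
#' is found, and windows sharing a SNP are unioned. The interval is the span
#' of the member SNPs (1-based, inclusive).
#'
#' @param sig Significant SNPs from [significant_snps()]; must be
#'   position-sorted within chromosome (unsorted input is rejected).
#' @param window Window size in bp (default 1 Mb).
#' @param min_snps Minimum significant SNPs per QTL (default 3).
#' @param trait Optional trait-temperature label (e.g. `"E10"`, `"L12"`,
#'   `"LT50"`) recorded as the interval's source.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `n_snps`,
#'   `peak_snp`, `peak_lod`, `trait`, and a list-column `members` of member
#'   SNP ids. Zero rows when no cluster qualifies.
#' @export
call_qtl <- function(sig, window = 1e6, min_snps = 3, trait = NA_character_) {
  stopifnot(window > 0, min_snps >= 1)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_snps = integer(), peak_snp = character(),
                      peak_lod = numeric(), trait = character())
  empty$members <- list()
  if (!nrow(sig)) return(empty)
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    if (is.unsorted(s$pos)) stop("SNPs must be position-sorted within chromosome")
    cl <- call_qtl_chrom(s$pos, s$neglog10p, s$snp_id, window, min_snps)
    for (q in cl)
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = q$start,
                                           end = q$end, n_snps = q$n_snps,
                                           peak_snp = q$peak_snp,
                                           peak_lod = q$peak_lod,
                                           trait = trait,
                                           members = I(list(q$members)))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

qtl_granges <- function(qtls) {
  GenomicRanges::GRanges(seqnames = as.character(qtls$chrom),
                         ranges = IRanges::IRanges(start = qtls$start,
                                                   end = qtls$end))
}

#' Merge per-trait QTL into unique QTL regions
#'
#' Same-chromosome intervals sharing at least 1 bp are merged transitively;
#' the merged interval is the union span, member SNPs and trait labels are
#' unioned, and the peak is the member interval peak with the highest LOD.
#' Touching-but-not-overlapping intervals are kept apart. The operation is
#' idempotent and independent of input order.
#'
#' @param qtls QTL table from [call_qtl()] (rows from several traits may be
#'   concatenated with `rbind`).
#' @return `data.frame` with `chrom`, `start`, `end`, `n_sources`, `traits`
#'   (sorted, `+`-joined source labels), `peak_snp`, `peak_lod`, `n_snps`,
#'   plus list-columns `members` and `sources`.
#' @export
merge_unique <- function(qtls) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_sources = integer(), traits = character(),
                      peak_snp = character(), peak_lod = numeric(),
                      n_snps = integer())
  empty$members <- list(); empty$sources <- list()
  if (!nrow(qtls)) return(empty)
  gr <- qtl_granges(qtls)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  rows <- lapply(seq_along(red), function(i) {
    src_rows <- qtls[revmap[[i]], , drop = FALSE]
    members <- sort(unique(unlist(src_rows$members)))
    sources <- if ("sources" %in% names(src_rows))
      sort(unique(unlist(src_rows$sources)))
    else sort(unique(src_rows$trait[!is.na(src_rows$trait)]))
    top <- which.max(src_rows$peak_lod)
    data.frame(chrom = as.character(GenomicRanges::seqnames(red)[i]),
               start = GenomicRanges::start(red)[i],
               end = GenomicRanges::end(red)[i],
               n_sources = length(sources),
               traits = paste(sources, collapse = "+"),
               peak_snp = src_rows$peak_snp[top],
               peak_lod = src_rows$peak_lod[top],
               n_snps = length(members),
               members = I(list(members)),
               sources = I(list(sources)))
  })
  res <- do.call(rbind, rows)
  res <- res[order(match(res$chrom, unique(qtls$chrom)), res$start), ]
  rownames(res) <- NULL
  res
}

#' Multi-trait QTL
#'
#' Retains merged QTL regions supported by at least two distinct
#' trait-temperature sources and names them `qMT<chr>-<k>` by start position
#' (just `qMT<chr>` when a chromosome carries a single one).
#'
#' @param merged Output of [merge_unique()].
#' @return Subset of `merged` with a leading `qtl` name column.
#' @export
multi_trait <- function(merged) {
  mt <- merged[merged$n_sources >= 2, , drop = FALSE]
  if (!nrow(mt)) {
    mt$qtl <- character(0)
    return(mt[, c("qtl", setdiff(names(mt), "qtl"))])
  }
  mt <- mt[order(match(mt$chrom, unique(merged$chrom)), mt$start), , drop = FALSE]
  name <- character(nrow(mt))
  for (ch in unique(mt$chrom)) {
    i <- which(mt$chrom == ch)
    name[i] <- if (length(i) == 1) paste0("qMT", ch)
    else sprintf("qMT%s-%d", ch, seq_along(i))
  }
  mt$qtl <- name
  rownames(mt) <- NULL
  mt[, c("qtl", setdiff(names(mt), "qtl"))]
}

#' Fraction of the genome covered by QTL intervals
#'
#' Union length of the intervals divided by the summed chromosome lengths
#' (union semantics: duplicated or overlapping intervals count once).
#'
#' @param qtls QTL table with `chrom`, `start`, `end`.
#' @param chromosome_lengths Named vector of chromosome lengths in bp; every
#'   chromosome present in `qtls` must be listed.
#' @return Coverage fraction in \[0, 1\].
#' @export
genome_coverage <- function(qtls, chromosome_lengths) {
  chroms <- unique(as.character(qtls$chrom))
  if (!all(chroms %in% names(chromosome_lengths)))
    stop("missing chromosome lengths for: ",
         paste(setdiff(chroms, names(chromosome_lengths)), collapse = ", "))
  if (nrow(qtls)) {
    too_long <- qtls$end > chromosome_lengths[as.character(qtls$chrom)]
    if (any(too_long)) stop("interval exceeds its chromosome length")
  }
  if (!nrow(qtls)) return(0)
  red <- GenomicRanges::reduce(qtl_granges(qtls))
  sum(as.numeric(GenomicRanges::width(red))) / sum(as.numeric(chromosome_lengths))
}

#' Annotate QTL with overlapping legacy QTL names
#'
#' Each QTL is annotated with the names of previously published intervals
#' sharing at least 1 bp with it (inclusive 1-based coordinates on both
#' sides; intervals that merely touch do not overlap).
#'
#' @param qtls QTL table with `chrom`, `start`, `end`.
#' @param legacy `data.frame` with `chrom`, `start`, `end`, `name` in 1-based
#'   inclusive coordinates (see [read_bed()] for BED input).
#' @return `qtls` with added columns `legacy_hits` (`;`-joined names, `""`
#'   when none) and `n_legacy`.
#' @export
legacy_overlap <- function(qtls, legacy) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(legacy)))
  qtls$legacy_hits <- ""
  qtls$n_legacy <- 0L
  if (!nrow(qtls) || !nrow(legacy)) return(qtls)
  # disjoint chromosome sets are a legitimate "no overlap", not a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(qtl_granges(qtls), qtl_granges(legacy),
                                minoverlap = 1L))
  for (i in unique(S4Vectors::queryHits(hits))) {
    nm <- legacy$name[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
    qtls$legacy_hits[i] <- paste(unique(nm), collapse = ";")
    qtls$n_legacy[i] <- length(unique(nm))
  }
  qtls
}
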