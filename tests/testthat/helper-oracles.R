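# Independent oracles and small fixture builders shared across the suite.
# Each oracle is deliberately written with a different algorithm than the
# package implementation it checks.

# Build a genotype_panel from a plain matrix (one chromosome unless given).
make_panel <- function(geno, chrom = NULL, pos = NULL, clusters = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(clusters)) clusters <- rep("tolerant", n)
  genotype_panel(geno,
                 data.frame(snp_id = sprintf("s%03d", seq_len(m)),
                            chrom = chrom, pos = pos),
                 data.frame(accession = sprintf("a%03d", seq_len(n)),
                            cluster = clusters))
}

# Brute-force QTL caller: enumerate every contiguous SNP window whose span
# fits inside `window` with >= min_snps members, keep the inclusion-maximal
# ones, and union windows that share a SNP (transitively, via union-find).
oracle_call_qtl <- function(pos, window = 1e6, min_snps = 3) {
  m <- length(pos)
  wins <- list()
  for (i in seq_len(m)) for (j in seq(i, m)) {
    if (pos[j] - pos[i] <= window && j - i + 1 >= min_snps)
      wins[[length(wins) + 1]] <- c(i, j)
  }
  if (!length(wins)) return(list())
  W <- do.call(rbind, wins)
  keep <- vapply(seq_len(nrow(W)), function(k) {
    contains <- W[, 1] <= W[k, 1] & W[, 2] >= W[k, 2] &
      (W[, 1] < W[k, 1] | W[, 2] > W[k, 2])
    !any(contains)
  }, logical(1))
  W <- W[keep, , drop = FALSE]
  W <- unique(W)
  # union-find over windows sharing at least one SNP index
  parent <- seq_len(nrow(W))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(nrow(W))) for (b in seq_len(nrow(W))) {
    if (a < b && max(W[a, 1], W[b, 1]) <= min(W[a, 2], W[b, 2])) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  comp <- vapply(seq_len(nrow(W)), find, integer(1))
  lapply(split(seq_len(nrow(W)), comp), function(idx)
    sort(unique(unlist(lapply(idx, function(k) seq(W[k, 1], W[k, 2]))))))
}

# Sweep-line interval union per chromosome (merge on >= 1 bp overlap).
oracle_merge_intervals <- function(df) {
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cs <- d$start[1]; ce <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= ce) ce <- max(ce, d$end[i])
      else { out[[length(out) + 1]] <- data.frame(chrom = ch, start = cs, end = ce)
             cs <- d$start[i]; ce <- d$end[i] }
    }
    out[[length(out) + 1]] <- data.frame(chrom = ch, start = cs, end = ce)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Per-basepair bitmap coverage on a small genome.
oracle_coverage <- function(df, lengths) {
  covered <- 0
  for (ch in names(lengths)) {
    bit <- logical(lengths[[ch]])
    d <- df[df$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) bit[d$start[i]:d$end[i]] <- TRUE
    covered <- covered + sum(bit)
  }
  covered / sum(lengths)
}

# Toy QTL set matching the packaged toy annotation/scan fixture.
toy_qtls <- function() {
  data.frame(qtl = c("Q1", "Q2", "Q3"),
             chrom = c("1", "1", "2"),
             start = c(100000L, 600000L, 50000L),
             end = c(400000L, 800000L, 150000L))
}

toy_genes_path <- function()
  system.file("extdata", "toy_genes.gff3", package = "coldqtl", mustWork = TRUE)

toy_scan_path <- function()
  system.file("extdata", "toy_scan.tsv", package = "coldqtl", mustWork = TRUE)
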