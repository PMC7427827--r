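#' Settings for the synthetic structured-panel simulator
#'
#' The defaults emulate the study conditions of a rice diversity panel split
#' into three genetically diverged chilling-tolerance clusters (Tolerant 205,
#' Intermediate 20, Sensitive 129 accessions), phenotyped at five chilling
#' temperatures in up to 3 replicate boxes of up to 8 seedlings.
#'
#' @param n_per_cluster Named integer vector of accessions per cluster
#'   (Tolerant / Intermediate / Sensitive).
#' @param n_snps Number of simulated SNPs.
#' @param chromosome_lengths Named numeric vector of chromosome lengths in bp.
#'   Defaults to 12 rice-like chromosomes (about 373 Mb in total).
#' @param fst Balding-Nichols divergence parameter in (0, 1). The default 0.3
#'   creates strong subspecies-level divergence between clusters.
#' @param n_causal Number of planted causal SNPs.
#' @param causal_effect LT50 shift (degrees C) between the two homozygous
#'   genotype classes at a causal SNP; an accession's true LT50 gains
#'   `allele count * causal_effect / 2`. The default -2 makes the
#'   non-reference allele a tolerance allele (it lowers the lethal
#'   temperature by 2 degrees C).
#' @param cluster_lt50 Named numeric vector of cluster baseline LT50 values
#'   (degrees C); lower = more chilling tolerant. The defaults are
#'   calibrated so that with `slope = 0.8` the cluster survival curves hit
#'   the observed extremes of the emulated panel (Sensitive accessions
#'   almost all dead at 4 C, almost all clusters saturated alive at 16 C).
#' @param lt50_sd Accession-level LT50 noise standard deviation (degrees C).
#' @param temperatures Chilling treatment temperatures (degrees C), strictly
#'   increasing.
#' @param boxes Replicate boxes per accession and temperature (1-3).
#' @param seedlings_per_box Seedlings per box (1-8).
#' @param slope Logistic steepness of the survival curve (1 / degrees C).
#' @param el_base Baseline percent electrolyte leakage of unstressed tissue.
#' @param el_scale Fraction of mortality passed through to percent EL.
#' @param el_noise_sd Replicate-level EL noise standard deviation (percent).
#' @param missing_rate Fraction of genotype calls set missing (for testing the
#'   missingness filter).
#' @param causal_maf_min Minimum overall minor allele frequency required of a
#'   SNP to be eligible as a planted causal locus.
#' @param seed Integer RNG seed; all simulator randomness derives from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_cluster = c(tolerant = 205, intermediate = 20, sensitive = 129),
                       n_snps = 3000,
                       chromosome_lengths = NULL,
                       fst = 0.3,
                       n_causal = 1,
                       causal_effect = -2,
                       cluster_lt50 = c(tolerant = 8.5, intermediate = 10, sensitive = 11.8),
                       lt50_sd = 0.5,
                       temperatures = c(4, 8, 10, 12, 16),
                       boxes = 3,
                       seedlings_per_box = 8,
                       slope = 0.8,
                       el_base = 8,
                       el_scale = 0.30,
                       el_noise_sd = 5,
                       missing_rate = 0,
                       causal_maf_min = 0.2,
                       seed = 1) {
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- setNames(
      c(43.3, 35.9, 36.4, 35.5, 29.9, 31.2, 29.7, 28.4, 23.0, 23.2, 29.0, 27.5) * 1e6,
      as.character(1:12))
  }
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- as.character(seq_along(chromosome_lengths))
  stopifnot(length(n_per_cluster) >= 1, all(n_per_cluster > 0))
  if (is.null(names(n_per_cluster)))
    names(n_per_cluster) <- c("tolerant", "intermediate", "sensitive")[seq_along(n_per_cluster)]
  if (!(fst > 0 && fst < 1)) stop("`fst` must lie strictly inside (0, 1)")
  stopifnot(n_snps >= 1, all(chromosome_lengths > 0))
  if (n_causal < 0 || n_causal > n_snps) stop("`n_causal` must be in [0, n_snps]")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("`temperatures` must be strictly increasing")
  if (!(boxes %in% 1:3)) stop("`boxes` must be 1, 2 or 3")
  if (!(seedlings_per_box %in% 1:8)) stop("`seedlings_per_box` must be 1..8")
  stopifnot(slope > 0, lt50_sd >= 0, el_noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1,
            length(cluster_lt50) == length(n_per_cluster))
  names(cluster_lt50) <- names(n_per_cluster)
  structure(list(n_per_cluster = n_per_cluster, n_snps = as.integer(n_snps),
                 chromosome_lengths = chromosome_lengths, fst = fst,
                 n_causal = as.integer(n_causal), causal_effect = causal_effect,
                 cluster_lt50 = cluster_lt50, lt50_sd = lt50_sd,
                 temperatures = temperatures, boxes = as.integer(boxes),
                 seedlings_per_box = as.integer(seedlings_per_box),
                 slope = slope, el_base = el_base, el_scale = el_scale,
                 el_noise_sd = el_noise_sd, missing_rate = missing_rate,
                 causal_maf_min = causal_maf_min, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotypes for a structured inbred panel
#'
#' Balding-Nichols model: each SNP draws an ancestral allele frequency p
#' uniformly on (0.05, 0.95); each cluster then draws its own frequency from a
#' Beta distribution with mean p and variance `fst * p * (1 - p)`. Accessions
#' are fully inbred, so genotypes are 0 or 2 copies of the non-reference
#' allele. SNP positions are uniform over the chromosome lengths, sorted and
#' 1-based.
#'
#' @param config A [sim_config()].
#' @return A [genotype_panel()] whose `accessions$cluster` carries the
#'   simulated cluster labels.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_snps
  L <- config$chromosome_lengths
  F <- config$fst
  set.seed(config$seed)
  # Single RNG stream keyed by `seed`; draw order is fixed:
  #   (1) ancestral frequencies, (2) chromosome assignment, (3) positions,
  #   (4) per-cluster Beta frequencies (cluster order as in n_per_cluster),
  #   (5) genotypes cluster by cluster, (6) missing-call mask.
  p_anc <- runif(m, 0.05, 0.95)
  chrom <- sample(names(L), m, replace = TRUE, prob = L / sum(L))
  pos <- ceiling(runif(m) * L[chrom])
  ord <- order(match(chrom, names(L)), pos)
  chrom <- chrom[ord]; pos <- pos[ord]; p_anc <- p_anc[ord]
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                     chrom = chrom, pos = as.integer(pos), row.names = NULL)

  shape_scale <- (1 - F) / F
  clusters <- names(config$n_per_cluster)
  p_cluster <- matrix(NA_real_, nrow = length(clusters), ncol = m,
                      dimnames = list(clusters, NULL))
  for (k in clusters)
    p_cluster[k, ] <- rbeta(m, p_anc * shape_scale, (1 - p_anc) * shape_scale)

  n <- sum(config$n_per_cluster)
  geno <- matrix(NA_real_, nrow = n, ncol = m)
  acc_cluster <- rep(clusters, config$n_per_cluster)
  row0 <- 0L
  for (k in clusters) {
    nk <- config$n_per_cluster[[k]]
    # inbred lines: genotype is 2 * Bernoulli(cluster allele frequency)
    gk <- 2 * matrix(rbinom(nk * m, 1, rep(p_cluster[k, ], each = nk)),
                     nrow = nk, ncol = m)
    geno[row0 + seq_len(nk), ] <- gk
    row0 <- row0 + nk
  }
  if (config$missing_rate > 0) {
    drop <- runif(n * m) < config$missing_rate
    geno[matrix(drop, nrow = n)] <- NA_real_
  }
  abbrev <- toupper(substr(clusters, 1, 3))
  accession <- sprintf("%s%03d", rep(abbrev, config$n_per_cluster),
                       unlist(lapply(config$n_per_cluster, seq_len), use.names = FALSE))
  genotype_panel(geno, snps,
                 data.frame(accession = accession, cluster = acc_cluster,
                            row.names = NULL))
}

#' Simulate replicated multi-temperature phenotypes with planted causal loci
#'
#' Each accession's true LT50 is its cluster baseline plus
#' `allele count * causal_effect / 2` summed over planted causal SNPs plus
#' Normal accession noise. At temperature T the survival probability is
#' `plogis(slope * (T - LT50))`, so survival is non-decreasing in temperature
#' and crosses 50% exactly at LT50. Alive counts per replicate box are
#' Binomial; raw percent electrolyte leakage is a noisy monotone transform of
#' mortality, `clamp(el_base + 100 * (1 - p) * el_scale + noise, 0, 100)`,
#' which couples EL to survival most strongly at intermediate temperatures.
#'
#' @param panel A [genotype_panel()] from [simulate_genotypes()].
#' @param config The same [sim_config()] used to build the panel.
#' @return A list with `raw` (a tidy replicate table with columns `accession`,
#'   `trait` in \{"EL", "LTSS"\}, `temperature_C`, `replicate`,
#'   `value_numerator`, `value_denominator`) and `truth` (a list with
#'   `causal_snp_ids`, per-accession `lt50_true`, and `clusters`).
#' @export
simulate_phenotypes <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  if (!identical(names(config$n_per_cluster)[match(panel$accessions$cluster,
                                                   names(config$n_per_cluster))],
                 panel$accessions$cluster))
    stop("panel cluster labels do not match the configuration")
  n <- nrow(panel$geno)
  acc <- panel$accessions$accession
  # Phenotype stream keyed by seed + 1 so it never reuses genotype draws.
  # Draw order: (1) causal SNP choice, (2) accession LT50 noise,
  #   (3) alive counts, temperature-major then box, (4) EL noise, same order.
  set.seed(config$seed + 1L)
  freq <- colMeans(panel$geno, na.rm = TRUE) / 2
  eligible <- which(pmin(freq, 1 - freq) >= config$causal_maf_min)
  if (config$n_causal > 0 && length(eligible) < config$n_causal)
    stop("not enough SNPs pass `causal_maf_min` to plant causal loci")
  causal <- if (config$n_causal > 0) sort(sample(eligible, config$n_causal)) else integer(0)

  base <- config$cluster_lt50[panel$accessions$cluster]
  shift <- if (length(causal)) {
    g <- panel$geno[, causal, drop = FALSE]
    g[is.na(g)] <- 0
    as.vector(g %*% rep(config$causal_effect / 2, length(causal)))
  } else rep(0, n)
  lt50 <- as.vector(base) + shift + rnorm(n, 0, config$lt50_sd)
  names(lt50) <- acc

  temps <- config$temperatures
  nb <- config$boxes
  spb <- config$seedlings_per_box
  rows <- vector("list", length(temps) * nb)
  i <- 0L
  alive_all <- el_all <- NULL
  for (Tv in temps) {
    p <- plogis(config$slope * (Tv - lt50))
    for (b in seq_len(nb)) {
      i <- i + 1L
      alive <- rbinom(n, spb, p)
      rows[[i]] <- data.frame(accession = acc, temperature_C = Tv,
                              replicate = b, alive = alive, p = p,
                              row.names = NULL)
    }
  }
  blocks <- do.call(rbind, rows)
  el_noise <- rnorm(nrow(blocks), 0, config$el_noise_sd)
  el <- pmin(pmax(config$el_base + 100 * (1 - blocks$p) * config$el_scale +
                    el_noise, 0), 100)
  ltss_rows <- data.frame(accession = blocks$accession, trait = "LTSS",
                          temperature_C = blocks$temperature_C,
                          replicate = blocks$replicate,
                          value_numerator = blocks$alive,
                          value_denominator = spb, row.names = NULL)
  el_rows <- data.frame(accession = blocks$accession, trait = "EL",
                        temperature_C = blocks$temperature_C,
                        replicate = blocks$replicate,
                        value_numerator = el,
                        value_denominator = 100, row.names = NULL)
  raw <- rbind(el_rows, ltss_rows)
  raw <- raw[order(raw$accession, raw$trait, raw$temperature_C, raw$replicate), ]
  rownames(raw) <- NULL
  truth <- list(causal_snp_ids = panel$snps$snp_id[causal],
                lt50_true = lt50,
                clusters = setNames(panel$accessions$cluster, acc))
  list(raw = raw, truth = truth)
}
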