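small_cfg <- function(...) {
  sim_config(n_per_cluster = c(tolerant = 30, intermediate = 6, sensitive = 24),
             n_snps = 400, ...)
}

test_that("inbred coding, missingness switch and determinism hold", {
  cfg <- small_cfg(seed = 11)
  p <- simulate_genotypes(cfg)
  expect_true(all(p$geno %in% c(0, 2)))
  expect_equal(dim(p$geno), c(60, 400))
  expect_false(is.unsorted(p$snps$pos[p$snps$chrom == p$snps$chrom[1]]))

  p2 <- simulate_genotypes(cfg)
  expect_identical(p$geno, p2$geno)
  expect_identical(p$snps, p2$snps)
  p3 <- simulate_genotypes(small_cfg(seed = 12))
  expect_false(identical(p$geno, p3$geno))

  pm <- simulate_genotypes(small_cfg(seed = 11, missing_rate = 0.1))
  expect_gt(mean(is.na(pm$geno)), 0.05)
  expect_true(all(pm$geno[!is.na(pm$geno)] %in% c(0, 2)))
})

test_that("fst controls cluster divergence in the expected limits", {
  cfg0 <- sim_config(n_per_cluster = c(tolerant = 120, intermediate = 120,
                                       sensitive = 120),
                     n_snps = 2000, fst = 1e-6, seed = 5)
  p0 <- simulate_genotypes(cfg0)
  freq_by_cluster <- function(panel) {
    sapply(split(seq_len(nrow(panel$geno)), panel$accessions$cluster),
           function(i) colMeans(panel$geno[i, , drop = FALSE]) / 2)
  }
  f0 <- freq_by_cluster(p0)
  pairdiff <- function(f) mean(c(abs(f[, 1] - f[, 2]), abs(f[, 1] - f[, 3]),
                                 abs(f[, 2] - f[, 3])))
  # at fst -> 0 the residual difference is pure binomial sampling noise
  expect_lt(pairdiff(f0) - sqrt(2 / pi) *
              mean(sqrt(2 * f0[, 1] * (1 - f0[, 1]) / 120)), 0.02)

  cfg3 <- sim_config(n_per_cluster = c(tolerant = 120, intermediate = 120,
                                       sensitive = 120),
                     n_snps = 2000, fst = 0.3, seed = 5)
  f3 <- freq_by_cluster(simulate_genotypes(cfg3))
  expect_gt(pairdiff(f3), 5 * pairdiff(f0))
})

test_that("principal components of an fst=0.3 panel separate the clusters", {
  skip_if_not_installed("cluster")
  cfg <- sim_config(n_snps = 2000, fst = 0.3, seed = 1)
  p <- simulate_genotypes(cfg)
  pc <- prcomp(p$geno, rank. = 2)
  sil <- cluster::silhouette(as.integer(factor(p$accessions$cluster)),
                             dist(pc$x))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("phenotypes respect count bounds, EL range and survival monotonicity", {
  cfg <- small_cfg(seed = 21)
  p <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(p, cfg)
  raw <- ph$raw
  ltss <- raw[raw$trait == "LTSS", ]
  el <- raw[raw$trait == "EL", ]
  expect_true(all(ltss$value_numerator <= cfg$seedlings_per_box))
  expect_true(all(ltss$value_numerator >= 0))
  el_pct <- 100 * el$value_numerator / el$value_denominator
  expect_true(all(el_pct >= 0 & el_pct <= 100))
  # pooled survival must rise with temperature across the panel
  surv <- tapply(ltss$value_numerator / ltss$value_denominator,
                 ltss$temperature_C, mean)
  expect_false(is.unsorted(surv[order(as.numeric(names(surv)))]))
  # replicated call is bit-identical
  ph2 <- simulate_phenotypes(p, cfg)
  expect_identical(ph$raw, ph2$raw)
  expect_identical(ph$truth, ph2$truth)
})

test_that("no-variance and step-function limits behave", {
  cfg <- sim_config(n_per_cluster = c(tolerant = 20), n_snps = 50,
                    cluster_lt50 = c(tolerant = 10),
                    n_causal = 0, lt50_sd = 0, el_noise_sd = 0, seed = 2)
  p <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(p, cfg)
  expect_equal(length(unique(round(ph$truth$lt50_true, 10))), 1)
  # near-step logistic: LT50 = 10 C, steep slope
  steep <- sim_config(n_per_cluster = c(tolerant = 20), n_snps = 50,
                      n_causal = 0, lt50_sd = 0, slope = 25,
                      cluster_lt50 = c(tolerant = 10), seed = 2)
  ps <- simulate_genotypes(steep)
  phs <- simulate_phenotypes(ps, steep)
  ltss <- phs$raw[phs$raw$trait == "LTSS", ]
  expect_equal(mean(ltss$value_numerator[ltss$temperature_C == 8]) /
                 steep$seedlings_per_box, 0, tolerance = 1e-6)
  expect_equal(mean(ltss$value_numerator[ltss$temperature_C == 12]) /
                 steep$seedlings_per_box, 1, tolerance = 1e-6)
})

test_that("EL couples to mortality most strongly at intermediate temperature", {
  cfg <- sim_config(n_per_cluster = c(tolerant = 290, intermediate = 28,
                                      sensitive = 182),
                    n_snps = 500, seed = 7)
  p <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(p, cfg)
  tt <- average_replicates(ph$raw)
  r2_at <- function(temp) {
    trait_correlation(trait_values(tt, "EL", temp),
                      trait_values(tt, "LTSS", temp))$r_squared
  }
  expect_gt(r2_at(8), r2_at(16))
})

test_that("regression on planted causal alleles recovers the effect size", {
  cfg <- sim_config(n_snps = 500, n_causal = 3, causal_effect = 2, seed = 13)
  p <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(p, cfg)
  g <- p$geno[, ph$truth$causal_snp_ids, drop = FALSE]
  cl <- factor(ph$truth$clusters)
  fit <- lm(ph$truth$lt50_true ~ cl + g)
  est <- coef(summary(fit))[paste0("g", ph$truth$causal_snp_ids), ]
  expect_true(all(abs(est[, "Estimate"] - cfg$causal_effect / 2) <=
                    2 * est[, "Std. Error"]))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(fst = 0), "fst")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(temperatures = c(4, 4, 8)), "increasing")
  expect_error(sim_config(boxes = 4), "boxes")
  expect_error(sim_config(seedlings_per_box = 9), "seedlings")
  expect_error(sim_config(n_snps = 10, n_causal = 11), "n_causal")
})
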