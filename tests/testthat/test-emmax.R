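structured_panel <- function(n_per = c(tolerant = 60, intermediate = 10,
                                       sensitive = 50),
                             n_snps = 600, seed = 1) {
  simulate_genotypes(sim_config(n_per_cluster = n_per, n_snps = n_snps,
                                seed = seed))
}

test_that("REML variance components behave in the identifiable limits", {
  panel <- structured_panel(seed = 4)
  K <- ibs_kinship(panel)
  acc <- panel$accessions$accession

  # pure-genetic limit: trait built from K's leading eigenvector
  u1 <- eigen(K, symmetric = TRUE)$vectors[, 1]
  nm <- fit_null_model(setNames(u1, acc), K)
  expect_gt(nm$h2, 0.99)
  expect_true(nm$identifiable)

  # pure noise: heritability estimate collapses
  set.seed(6)
  h2 <- replicate(30, fit_null_model(setNames(rnorm(length(acc)), acc), K)$h2)
  expect_lt(median(h2), 0.1)

  # K = I: only the total variance is identified, and it matches var(y)
  set.seed(7)
  y <- setNames(rnorm(length(acc)), acc)
  Ki <- diag(length(acc)); dimnames(Ki) <- list(acc, acc)
  nmi <- fit_null_model(y, Ki)
  expect_false(nmi$identifiable)
  expect_equal(nmi$sigma_g2 + nmi$sigma_e2, var(y), tolerance = 1e-6)

  expect_error(fit_null_model(setNames(rep(1, length(acc)), acc), K),
               "variance")
})

test_that("with identity kinship the scan reproduces OLS exactly", {
  panel <- structured_panel(n_snps = 200, seed = 9)
  panel <- filter_snps(panel)
  acc <- panel$accessions$accession
  set.seed(10)
  y <- setNames(rnorm(length(acc)) + panel$geno[, 5] * 0.3, acc)
  Ki <- diag(length(acc)); dimnames(Ki) <- list(acc, acc)
  mixed <- emmax_scan(panel, y, K = Ki)
  ols <- emmax_scan(panel, y, K = NULL)
  expect_lt(max(abs(mixed$neglog10p - ols$neglog10p), na.rm = TRUE), 1e-6)
  expect_equal(mixed$beta, ols$beta, tolerance = 1e-8)

  # and the OLS path itself agrees with lm()
  g1 <- panel$geno[, 1]
  ref <- summary(lm(y ~ g1))$coefficients[2, ]
  expect_equal(ols$beta[1], unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(ols$p[1], unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("scan statistics are invariant to allele-coding flips", {
  panel <- structured_panel(n_snps = 150, seed = 12)
  panel <- filter_snps(panel)
  acc <- panel$accessions$accession
  K <- ibs_kinship(panel)
  set.seed(13)
  y <- setNames(rnorm(length(acc)) + 0.2 * panel$geno[, 3], acc)
  s1 <- emmax_scan(panel, y, K = K)

  flipped <- panel
  flip <- seq(1, ncol(panel$geno), by = 2)
  flipped$geno[, flip] <- 2 - flipped$geno[, flip]
  s2 <- emmax_scan(flipped, y, K = ibs_kinship(flipped))

  expect_equal(s1$p, s2$p, tolerance = 1e-8)
  expect_equal(s1$beta[flip], -s2$beta[flip], tolerance = 1e-8)
  expect_equal(s1$maf, s2$maf)
  expect_equal(s1$major_af, s2$major_af)
  # the major allele's effect direction is coding-independent wherever a
  # major allele exists (exact 0.5 frequencies have none and are excluded)
  tie <- abs(s1$major_af - 0.5) < 1e-12
  expect_equal(s1$effect_direction[!tie], s2$effect_direction[!tie])
})

test_that("missing genotypes drop accessions per SNP and match a direct GLS fit", {
  panel <- structured_panel(n_snps = 300, seed = 14)
  acc <- panel$accessions$accession
  set.seed(15)
  panel$geno[sample(length(panel$geno), 400)] <- NA
  panel <- filter_snps(panel)
  K <- ibs_kinship(panel)
  y <- setNames(rnorm(length(acc)), acc)
  null <- fit_null_model(y, K)
  sc <- emmax_scan(panel, y, K = K, null = null)
  j <- which(colSums(is.na(panel$geno)) > 0)[1]
  obs <- which(!is.na(panel$geno[, j]))
  V <- K[obs, obs] + null$delta * diag(length(obs))
  Vi <- solve(V)
  X <- cbind(1, panel$geno[obs, j])
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y[obs])
  expect_equal(sc$beta[j], b[2], tolerance = 1e-8)
  # zero-variance SNP is skipped and logged
  panel2 <- panel
  panel2$geno[, 2] <- 2
  sc2 <- emmax_scan(panel2, y, K = K, null = null)
  expect_true(is.na(sc2$p[2]))
  expect_true(panel2$snps$snp_id[2] %in% attr(sc2, "skipped_snps"))
})

test_that("kinship correction restores calibration on a structured null trait", {
  panel <- structured_panel(n_per = c(tolerant = 90, intermediate = 15,
                                      sensitive = 65),
                            n_snps = 1500, seed = 16)
  panel <- filter_snps(panel)
  K <- ibs_kinship(panel)
  acc <- panel$accessions$accession
  base <- c(tolerant = 9, intermediate = 11, sensitive = 13)
  set.seed(17)
  lam <- replicate(5, {
    y <- setNames(base[panel$accessions$cluster] + rnorm(length(acc)), acc)
    c(mixed = qq_inflation(emmax_scan(panel, y, K = K)$p)$lambda,
      ols = qq_inflation(emmax_scan(panel, y, K = NULL)$p)$lambda)
  })
  expect_lt(median(lam["mixed", ]), 1.2)
  expect_gt(median(lam["ols", ]), median(lam["mixed", ]) + 0.2)
})

test_that("a planted causal locus dominates the scan", {
  cfg <- sim_config(n_per_cluster = c(tolerant = 60, intermediate = 10,
                                      sensitive = 50),
                    n_snps = 600, n_causal = 1, causal_effect = 2, seed = 11)
  panel <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(panel, cfg)
  lt <- lt50_table(ph$raw)
  filtered <- filter_snps(panel)
  sc <- emmax_scan(filtered, trait_values(lt, "LT50"), K = ibs_kinship(filtered))
  expect_identical(sc$snp_id[which.max(sc$neglog10p)], ph$truth$causal_snp_ids)
})

test_that("genomic inflation factor is calibrated and handles edge cases", {
  set.seed(18)
  p <- runif(10000)
  qq <- qq_inflation(p)
  expect_equal(qq$lambda, 1, tolerance = 0.05)
  expect_false(qq$degenerate)
  expect_equal(qq$df$observed, sort(-log10(p), decreasing = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)

  ones <- qq_inflation(rep(1, 200))
  expect_equal(ones$lambda, 0)
  expect_true(ones$degenerate)

  # observed equal to expected quantiles exactly -> identity line
  pe <- ppoints(500)
  qe <- qq_inflation(pe)
  expect_equal(qe$df$observed, qe$df$expected, tolerance = 1e-12)

  expect_error(qq_inflation(runif(50)), "at least 100")
})
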