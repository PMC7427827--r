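#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the mean over loci non-missing in both accessions of
#' `1 - |g_i - g_j| / 2`, i.e. the average fraction of alleles shared by
#' state. Values lie in \[0, 1\]; the diagonal is 1; a pair with no shared
#' non-missing locus is an error.
#'
#' @param panel A [genotype_panel()], or a 0/1/2 genotype matrix
#'   (accessions x SNPs).
#' @return Symmetric accession x accession matrix.
#' @export
ibs_kinship <- function(panel) {
  g <- if (inherits(panel, "genotype_panel")) panel$geno else panel
  stopifnot(is.matrix(g))
  if (nrow(g) < 2) stop("need at least 2 accessions")
  if (ncol(g) < 1) stop("need at least 1 SNP")
  # |a-b| over {0,1,2} decomposed through genotype-class indicators so the
  # pairwise sum is a handful of matrix products.
  V <- !is.na(g)
  I0 <- (g == 0) & V; I1 <- (g == 1) & V; I2 <- (g == 2) & V
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  storage.mode(V) <- "double"
  shared <- tcrossprod(V)
  if (any(shared == 0))
    stop("some accession pairs share no non-missing locus")
  mism <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1) +
    2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  K <- 1 - mism / (2 * shared)
  dimnames(K) <- list(rownames(g), rownames(g))
  K
}

#' Allele-filtering policy
#'
#' Default thresholds: minor allele frequency strictly greater than 10%,
#' minor allele count strictly greater than 1, missing-call fraction strictly
#' below 30%.
#'
#' @param maf_min MAF threshold (strict `>`).
#' @param mac_min MAC threshold (strict `>`).
#' @param missing_max Missing-fraction threshold (strict `<`).
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(maf_min = 0.10, mac_min = 1, missing_max = 0.30) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, mac_min >= 0,
            missing_max > 0, missing_max <= 1)
  structure(list(maf_min = maf_min, mac_min = mac_min,
                 missing_max = missing_max), class = "filter_policy")
}

#' Filter SNPs by allele frequency, count and missingness
#'
#' Retains exactly the SNPs with `MAF > maf_min`, `MAC > mac_min` and
#' `missing fraction < missing_max`, all computed on non-missing calls.
#'
#' @param panel A [genotype_panel()].
#' @param policy A [filter_policy()].
#' @return Filtered `genotype_panel`; attribute `filter_counts` records how
#'   many SNPs each rule removed (marginally) and the total kept.
#' @export
filter_snps <- function(panel, policy = filter_policy()) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(policy, "filter_policy"))
  st <- snp_stats(panel)
  maf_ok <- !is.na(st$maf) & st$maf > policy$maf_min
  mac_ok <- st$mac > policy$mac_min
  miss_ok <- st$missing_frac < policy$missing_max
  keep <- maf_ok & mac_ok & miss_ok
  out <- subset_panel(panel, snp_idx = which(keep))
  attr(out, "filter_counts") <- c(input = nrow(st),
                                  fail_maf = sum(!maf_ok),
                                  fail_mac = sum(!mac_ok),
                                  fail_missing = sum(!miss_ok),
                                  kept = sum(keep))
  out
}

# Kinship spectra are clamped at 1e-10 for numerical PSD-ness. Pairwise
# missing-data IBS can carry small negative eigenvalues; those are tolerated
# (and clamped) up to 10% of the leading eigenvalue, beyond which the matrix
# is rejected as not positive semi-definite.
clamp_eigenvalues <- function(ev) {
  if (min(ev) < -0.1 * max(ev))
    stop("kinship matrix is not positive semi-definite")
  pmax(ev, 1e-10)
}

# REML log-likelihood profile in delta = sigma_e^2 / sigma_g^2 for the
# intercept-only model, on the eigenbasis of the projected kinship (EMMA).
reml_loglik <- function(log10_delta, xi, eta2) {
  delta <- 10^log10_delta
  nq <- length(xi)
  R <- sum(eta2 / (xi + delta))
  0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(R) - sum(log(xi + delta)))
}

#' REML variance components of the kinship null model
#'
#' Fits `y = mu + u + e` with `Var(u) = sigma_g^2 K`, `Var(e) = sigma_e^2 I`
#' by restricted maximum likelihood: the intercept is projected out, the
#' projected kinship is eigendecomposed once, and the REML log-likelihood is
#' maximized in the single ratio `delta = sigma_e^2 / sigma_g^2` (grid search
#' over `log10(delta)` in \[-6, 6\] refined by golden-section optimization).
#'
#' @param y Named numeric trait vector (names = accessions matching `K`).
#' @param K Kinship matrix from [ibs_kinship()].
#' @return List with `sigma_g2`, `sigma_e2`, `delta`, `h2`
#'   (`sigma_g2 / (sigma_g2 + sigma_e2)`), `loglik`, `identifiable` (FALSE
#'   when the projected kinship spectrum is flat, e.g. `K = I`, in which case
#'   only `sigma_g2 + sigma_e2` is determined), and `n`.
#' @export
fit_null_model <- function(y, K) {
  if (!is.null(names(y)) && !is.null(rownames(K))) {
    common <- intersect(names(y)[!is.na(y)], rownames(K))
    y <- y[common]; K <- K[common, common, drop = FALSE]
  } else {
    keep <- !is.na(y)
    y <- y[keep]; K <- K[keep, keep, drop = FALSE]
  }
  n <- length(y)
  if (n < 10) stop("need trait values for at least 10 accessions present in K")
  if (var(y) == 0) stop("trait has no variance")
  S <- diag(n) - matrix(1 / n, n, n)
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- es$values[seq_len(n - 1)]
  xi <- clamp_eigenvalues(xi)
  eta2 <- as.vector(crossprod(es$vectors[, seq_len(n - 1), drop = FALSE], y))^2
  grid <- seq(-6, 6, length.out = 121)
  ll <- vapply(grid, reml_loglik, numeric(1), xi = xi, eta2 = eta2)
  i <- which.max(ll)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- optimize(reml_loglik, c(lo, hi), xi = xi, eta2 = eta2, maximum = TRUE)
  delta <- 10^opt$maximum
  sigma_g2 <- sum(eta2 / (xi + delta)) / (n - 1)
  sigma_e2 <- delta * sigma_g2
  identifiable <- (max(xi) - min(xi)) > 1e-8 * max(max(xi), 1)
  list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
       h2 = sigma_g2 / (sigma_g2 + sigma_e2), loglik = opt$objective,
       identifiable = identifiable, n = n)
}

#' EMMAX-style single-marker mixed-model association scan
#'
#' Variance components are estimated once under the null ([fit_null_model()])
#' and held fixed for every SNP (the EMMAX approximation). The kinship is
#' eigendecomposed (eigenvalues clamped at 1e-10), trait, intercept and
#' genotypes are rotated into the eigenbasis, and each SNP is tested by
#' weighted least squares there — equivalent to generalized least squares
#' under `Var(y) = sigma_g2 K + sigma_e2 I`. Two-sided p-values come from the
#' t distribution with `n - 2` degrees of freedom. With `K = NULL` the scan
#' reduces exactly to ordinary least squares.
#'
#' Accessions missing a genotype call are dropped for that SNP only (the GLS
#' system is then solved exactly on the kinship submatrix). SNPs with zero
#' genotype variance among scored accessions are skipped and logged.
#'
#' @param panel A (filtered) [genotype_panel()].
#' @param trait Named numeric trait vector keyed by accession.
#' @param K Kinship matrix, or `NULL` for plain OLS.
#' @param null Optional pre-fitted [fit_null_model()] result.
#' @return `data.frame` with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `maf`, `mac`, `missing_frac`, `beta` (effect of one copy of the
#'   non-reference allele), `se`, `p`, `neglog10p`, `major_allele`
#'   (`"ref"`/`"alt"`), `major_af`, `effect_direction` (sign of the major
#'   allele's effect on the trait). Attributes `null_model`, `n_used` and
#'   `skipped_snps`.
#' @export
emmax_scan <- function(panel, trait, K = NULL, null = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  common <- intersect(panel$accessions$accession, names(trait)[!is.na(trait)])
  if (length(common) < 10) stop("fewer than 10 accessions with trait values")
  panel <- subset_panel(panel, acc_idx = match(common, panel$accessions$accession))
  y <- unname(trait[common])
  n <- length(y)
  G <- panel$geno
  m <- ncol(G)
  st <- snp_stats(panel)

  if (!is.null(K)) {
    K <- K[common, common, drop = FALSE]
    if (is.null(null)) null <- fit_null_model(setNames(y, common), K)
    delta <- null$delta
    eig <- eigen(K, symmetric = TRUE)
    d <- clamp_eigenvalues(eig$values)
    U <- eig$vectors
    w <- 1 / (d + delta)
    yt <- as.vector(crossprod(U, y))
    ot <- as.vector(crossprod(U, rep(1, n)))
  } else {
    null <- NULL; delta <- NA_real_
    U <- NULL
    w <- rep(1, n)
    yt <- y
    ot <- rep(1, n)
  }

  beta <- se <- pval <- rep(NA_real_, m)
  complete <- colSums(is.na(G)) == 0L
  gvar <- apply(G, 2, function(col) var(col[!is.na(col)]))
  testable <- !is.na(gvar) & gvar > 0

  idx <- which(complete & testable)
  if (length(idx)) {
    Gc <- G[, idx, drop = FALSE]
    Gt <- if (is.null(U)) Gc else crossprod(U, Gc)
    A11 <- sum(w * ot^2)
    b1 <- sum(w * ot * yt)
    Syy <- sum(w * yt^2)
    A12 <- colSums(w * ot * Gt)
    A22 <- colSums(w * Gt^2)
    b2 <- colSums(w * Gt * yt)
    det <- A11 * A22 - A12^2
    bb <- (A11 * b2 - A12 * b1) / det
    aa <- (b1 - A12 * bb) / A11
    rss <- Syy - aa * b1 - bb * b2
    sig2 <- rss / (n - 2)
    vb <- sig2 * A11 / det
    beta[idx] <- bb
    se[idx] <- sqrt(pmax(vb, 0))
    pval[idx] <- 2 * pt(-abs(bb / se[idx]), df = n - 2)
  }

  # missing-genotype SNPs: exact GLS on the kinship submatrix
  for (j in which(!complete & testable)) {
    obs <- which(!is.na(G[, j]))
    ns <- length(obs)
    if (ns < 3) next
    gj <- G[obs, j]
    if (var(gj) == 0) { testable[j] <- FALSE; next }
    X <- cbind(1, gj)
    yj <- y[obs]
    if (!is.null(K)) {
      V <- K[obs, obs, drop = FALSE] + delta * diag(ns)
      ee <- eigen(V, symmetric = TRUE)
      Wj <- t(ee$vectors) / sqrt(clamp_eigenvalues(ee$values))
      Xs <- Wj %*% X
      ys <- as.vector(Wj %*% yj)
    } else { Xs <- X; ys <- yj }
    XtX <- crossprod(Xs)
    bhat <- solve(XtX, crossprod(Xs, ys))
    r <- ys - Xs %*% bhat
    sig2 <- sum(r^2) / (ns - 2)
    vb <- sig2 * solve(XtX)[2, 2]
    beta[j] <- bhat[2]
    se[j] <- sqrt(max(vb, 0))
    pval[j] <- 2 * pt(-abs(beta[j] / se[j]), df = ns - 2)
  }

  major_is_alt <- st$alt_freq >= 0.5
  out <- data.frame(snp_id = panel$snps$snp_id, chrom = panel$snps$chrom,
                    pos = panel$snps$pos, maf = st$maf, mac = st$mac,
                    missing_frac = st$missing_frac,
                    beta = beta, se = se, p = pval,
                    neglog10p = -log10(pval),
                    major_allele = ifelse(major_is_alt, "alt", "ref"),
                    major_af = pmax(st$alt_freq, 1 - st$alt_freq),
                    effect_direction = sign(beta) * ifelse(major_is_alt, 1, -1),
                    row.names = NULL)
  attr(out, "null_model") <- null
  attr(out, "n_used") <- n
  attr(out, "skipped_snps") <- panel$snps$snp_id[!testable]
  out
}

#' Genomic inflation factor and Q-Q plot data
#'
#' Observed `-log10(p)` quantiles against uniform expectation, and the
#' inflation factor `lambda` = median observed 1-df chi-square statistic over
#' its null median.
#'
#' @param p Vector of p-values from a scan (at least 100).
#' @return List with `lambda`, `df` (a `data.frame` of `expected` and
#'   `observed` `-log10(p)` pairs), and `degenerate` (TRUE when all p = 1, in
#'   which case `lambda` is 0).
#' @export
qq_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100) stop("need at least 100 tested SNPs")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(chisq) / qchisq(0.5, df = 1, lower.tail = FALSE)
  df <- data.frame(expected = -log10(ppoints(length(p))),
                   observed = -log10(sort(p)))
  list(lambda = lambda, df = df, degenerate = all(p == 1))
}
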