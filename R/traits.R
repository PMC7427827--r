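#' Percent electrolyte leakage
#'
#' `%EL = 100 * initial / total`, where `initial` is the conductivity of the
#' bathing solution after chilling stress and `total` the conductivity after
#' boiling the tissue (complete lysis). When the initial conductivity is read
#' twice, average the two readings before calling this function.
#'
#' @param initial Initial conductivity (uS/cm), `0 <= initial <= total`.
#' @param total Total conductivity (uS/cm), `> 0`.
#' @return Percent EL in \[0, 100\]. Vectorized.
#' @export
percent_el <- function(initial, total) {
  if (any(total <= 0)) stop("`total` conductivity must be positive")
  if (any(initial < 0)) stop("`initial` conductivity must be non-negative")
  if (any(initial > total)) stop("`initial` conductivity cannot exceed `total`")
  100 * initial / total
}

#' Percent low-temperature seedling survivability
#'
#' `%LTSS = 100 * alive / initial`: green, healthy-looking seedlings after one
#' week of recovery divided by the initial healthy seedling count.
#'
#' @param alive Count of surviving seedlings, `0 <= alive <= initial`.
#' @param initial Initial seedling count, `> 0`.
#' @return Percent LTSS in \[0, 100\]. Vectorized.
#' @export
percent_ltss <- function(alive, initial) {
  if (any(initial <= 0)) stop("`initial` seedling count must be positive")
  if (any(alive < 0)) stop("`alive` count must be non-negative")
  if (any(alive > initial)) stop("`alive` cannot exceed `initial`")
  100 * alive / initial
}

#' Average replicate measurements into a trait table
#'
#' Each replicate row is first converted to a percentage
#' (`100 * value_numerator / value_denominator`); the trait value for a cell
#' (accession, trait, temperature) is the unweighted mean of its replicate
#' percentages. Replicates with a missing numerator are skipped, never
#' imputed.
#'
#' @param raw Replicate table with columns `accession`, `trait`,
#'   `temperature_C`, `replicate`, `value_numerator`, `value_denominator`.
#' @return `data.frame` with columns `accession`, `trait`, `temperature_C`,
#'   `value` (percent), one row per cell that has at least one replicate.
#' @export
average_replicates <- function(raw) {
  need <- c("accession", "trait", "temperature_C", "replicate",
            "value_numerator", "value_denominator")
  if (!all(need %in% names(raw)))
    stop("`raw` must have columns ", paste(need, collapse = ", "))
  raw <- raw[!is.na(raw$value_numerator), , drop = FALSE]
  if (!nrow(raw)) stop("no non-missing replicate measurements")
  if (any(raw$value_denominator <= 0)) stop("denominators must be positive")
  if (any(raw$value_numerator < 0 | raw$value_numerator > raw$value_denominator))
    stop("numerators must lie in [0, denominator]")
  pct <- 100 * raw$value_numerator / raw$value_denominator
  out <- aggregate(pct,
                   by = list(accession = raw$accession, trait = raw$trait,
                             temperature_C = raw$temperature_C),
                   FUN = mean)
  names(out)[4] <- "value"
  out <- out[order(out$trait, out$temperature_C, out$accession), ]
  rownames(out) <- NULL
  out
}

#' Extract one trait as a named accession vector
#'
#' @param trait_table Output of [average_replicates()] or [lt50_table()].
#' @param trait Trait name, e.g. `"EL"`, `"LTSS"`, `"LT50"`.
#' @param temperature Temperature to select, or `NULL` for temperature-free
#'   traits such as LT50.
#' @return Named numeric vector of trait values keyed by accession.
#' @export
trait_values <- function(trait_table, trait, temperature = NULL) {
  sel <- trait_table$trait == trait
  if (!is.null(temperature)) sel <- sel & trait_table$temperature_C == temperature
  sub <- trait_table[sel, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for the requested trait slice")
  if (anyDuplicated(sub$accession))
    stop("more than one value per accession in the requested slice")
  setNames(sub$value, sub$accession)
}

#' Linear correlation between two trait slices
#'
#' Ordinary least-squares fit of `y` on `x` with the squared Pearson
#' correlation as the coefficient of determination. When `x` has no variance
#' the slope is undefined: the fit is flagged degenerate and `r_squared` is
#' returned as `NA`, not 0.
#'
#' @param x,y Numeric vectors; if named, they are matched by name.
#' @return List with `slope`, `intercept`, `r_squared`, `n`, `degenerate`.
#' @export
trait_correlation <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (var(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                n = n, degenerate = TRUE))
  fit <- lm(y ~ x)
  r2 <- if (var(y) == 0) NA_real_ else cor(x, y)^2
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = n, degenerate = FALSE)
}

star_label <- function(p) {
  # figure-caption convention: * p<0.05, ** p<0.01, *** p<0.001
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Welch's ANOVA with Games-Howell post hoc comparisons
#'
#' Group differences are tested with Welch's heteroscedasticity-robust ANOVA
#' (Satterthwaite denominator degrees of freedom). All unordered group pairs
#' are then compared with the Games-Howell procedure: the pairwise statistic
#' `t = diff / sqrt(v1/n1 + v2/n2)` is referred to the studentized-range
#' distribution with `q = t * sqrt(2)`, `k` means, and Welch-corrected
#' degrees of freedom. Suitable for groups of unequal size and variance.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`.
#' @return List with `groups` (per-group n, mean, variance), `welch`
#'   (statistic, df1, df2, p_value), and `pairwise` (group pair, difference,
#'   standard error, t, df, p_value, stars).
#' @export
welch_games_howell <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups")
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, var)
  if (any(n < 2)) stop("every group needs at least 2 observations")
  if (any(v == 0)) stop("every group needs non-zero variance")
  w <- oneway.test(values ~ groups, var.equal = FALSE)
  pairs <- utils::combn(levels(groups), 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
  se2 <- v[pw$group1] / n[pw$group1] + v[pw$group2] / n[pw$group2]
  pw$diff <- unname(m[pw$group1] - m[pw$group2])
  pw$se <- unname(sqrt(se2))
  pw$t <- pw$diff / pw$se
  pw$df <- unname(se2^2 /
    ((v[pw$group1] / n[pw$group1])^2 / (n[pw$group1] - 1) +
     (v[pw$group2] / n[pw$group2])^2 / (n[pw$group2] - 1)))
  pw$p_value <- ptukey(abs(pw$t) * sqrt(2), nmeans = k, df = pw$df,
                       lower.tail = FALSE)
  pw$stars <- star_label(pw$p_value)
  list(groups = data.frame(group = levels(groups), n = as.vector(n),
                           mean = as.vector(m), variance = as.vector(v)),
       welch = list(statistic = unname(w$statistic),
                    df1 = unname(w$parameter[1]), df2 = unname(w$parameter[2]),
                    p_value = unname(w$p.value)),
       pairwise = pw)
}
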