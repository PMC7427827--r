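#' Fit a survival-vs-temperature curve and extract LT50
#'
#' Maximum-likelihood logistic regression (binomial GLM, logit link, fitted by
#' iteratively reweighted least squares: deviance tolerance 1e-8, at most 100
#' iterations) of alive/total counts on temperature. The median lethal
#' temperature is the 50% crossing, `LT50 = -beta0 / beta1`.
#'
#' Degenerate data are flagged instead of silently estimated:
#' * `all_alive` / `all_dead`: no mortality gradient, LT50 undefined;
#' * `separated`: alive fractions form a clean 0/1 step, LT50 is reported as
#'   the midpoint of the two bracketing temperatures (documented fallback);
#' * `non_positive_slope`: survival does not increase with temperature;
#' * `not_converged`: IRLS failed to converge;
#' * `out_of_range`: LT50 falls outside the tested range extended by one full
#'   temperature span on either side (still reported).
#'
#' @param temperature Treatment temperatures (degrees C); at least two
#'   distinct values with positive totals.
#' @param alive Surviving seedling counts per observation.
#' @param total Total seedling counts per observation.
#' @return List with `beta0`, `beta1`, `lt50`, `fit_status`.
#' @export
fit_survival_curve <- function(temperature, alive, total) {
  stopifnot(length(temperature) == length(alive),
            length(alive) == length(total))
  if (any(total < 0) || any(alive < 0)) stop("counts must be non-negative")
  if (any(alive > total)) stop("`alive` cannot exceed `total`")
  keep <- total > 0
  temperature <- temperature[keep]; alive <- alive[keep]; total <- total[keep]
  if (length(unique(temperature)) < 2)
    stop("need counts at >= 2 distinct temperatures")

  res <- list(beta0 = NA_real_, beta1 = NA_real_, lt50 = NA_real_,
              fit_status = "ok")
  if (sum(alive) == sum(total)) { res$fit_status <- "all_alive"; return(res) }
  if (sum(alive) == 0) { res$fit_status <- "all_dead"; return(res) }

  # pooled fraction per distinct temperature, used for the separation rule
  agg_a <- tapply(alive, temperature, sum)
  agg_t <- tapply(total, temperature, sum)
  tt <- as.numeric(names(agg_a))
  ord <- order(tt)
  tt <- tt[ord]; frac <- (agg_a / agg_t)[ord]
  step_like <- all(frac %in% c(0, 1)) && !is.unsorted(frac) &&
    any(frac == 0) && any(frac == 1)
  if (step_like) {
    lo <- max(tt[frac == 0]); hi <- min(tt[frac == 1])
    res$fit_status <- "separated"
    res$lt50 <- (lo + hi) / 2
    return(res)
  }

  fit <- suppressWarnings(glm(cbind(alive, total - alive) ~ temperature,
                              family = binomial(),
                              control = glm.control(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged) { res$fit_status <- "not_converged"; return(res) }
  b <- coef(fit)
  res$beta0 <- unname(b[1]); res$beta1 <- unname(b[2])
  if (abs(res$beta1) > 100) {
    # quasi-separation without a clean step: deterministic midpoint fallback
    below <- tt[frac < 0.5]; above <- tt[frac >= 0.5]
    res$fit_status <- "separated"
    res$lt50 <- if (length(below) && length(above))
      (max(below) + min(above)) / 2 else NA_real_
    return(res)
  }
  if (res$beta1 <= 0) { res$fit_status <- "non_positive_slope"; return(res) }
  res$lt50 <- -res$beta0 / res$beta1
  span <- max(tt) - min(tt)
  if (res$lt50 < min(tt) - span || res$lt50 > max(tt) + span)
    res$fit_status <- "out_of_range"
  res
}

#' LT50 mapping phenotype for a whole panel
#'
#' Replicate alive/dead counts are pooled per (accession, temperature) into
#' binomial totals before fitting one survival curve per accession with
#' [fit_survival_curve()]. Only accessions with `fit_status == "ok"` enter the
#' mapping phenotype; the rest are excluded and logged.
#'
#' @param raw Replicate table as produced by [simulate_phenotypes()] (the
#'   `trait == "LTSS"` rows are used: `value_numerator` = alive,
#'   `value_denominator` = seedlings per box).
#' @return Trait table with columns `accession`, `trait` (`"LT50"`),
#'   `temperature_C` (`NA`), `value` (degrees C). Attributes: `curves` (all
#'   per-accession fits) and `exclusions` (accessions with non-ok status).
#' @export
lt50_table <- function(raw) {
  ltss <- raw[raw$trait == "LTSS" & !is.na(raw$value_numerator), , drop = FALSE]
  if (!nrow(ltss)) stop("no LTSS replicate counts in `raw`")
  pooled <- aggregate(cbind(alive = value_numerator, total = value_denominator)
                      ~ accession + temperature_C, data = ltss, FUN = sum)
  fits <- lapply(split(pooled, pooled$accession), function(d) {
    f <- fit_survival_curve(d$temperature_C, d$alive, d$total)
    data.frame(accession = d$accession[1], beta0 = f$beta0, beta1 = f$beta1,
               lt50 = f$lt50, fit_status = f$fit_status, row.names = NULL)
  })
  curves <- do.call(rbind, fits)
  rownames(curves) <- NULL
  ok <- curves[curves$fit_status == "ok", , drop = FALSE]
  out <- data.frame(accession = ok$accession, trait = "LT50",
                    temperature_C = NA_real_, value = ok$lt50,
                    row.names = NULL)
  attr(out, "curves") <- curves
  attr(out, "exclusions") <- curves[curves$fit_status != "ok",
                                    c("accession", "fit_status"), drop = FALSE]
  out
}

#' Fitted survival-curve evaluation grid
#'
#' Convenience generator of plot data for one fitted curve: survival
#' probability over a temperature grid.
#'
#' @param curve A fit from [fit_survival_curve()] with status `"ok"`.
#' @param temperatures Grid of temperatures (degrees C).
#' @return `data.frame` with `temperature_C` and `survival`.
#' @export
survival_curve_grid <- function(curve, temperatures) {
  if (!identical(curve$fit_status, "ok"))
    stop("curve grid is only defined for status 'ok'")
  data.frame(temperature_C = temperatures,
             survival = plogis(curve$beta0 + curve$beta1 * temperatures))
}
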