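#' Per-SNP Wald ratios
#'
#' The building block of every two-sample MR estimator: for each
#' harmonized pair, the ratio estimate `beta_outcome / beta_exposure`
#' with first-order standard error `se_outcome / |beta_exposure|` and
#' inverse-variance weight.  First-order weights are the dominant
#' convention and ignore exposure-side sampling noise, which is
#' negligible when instruments are strong (see the methods vignette for
#' the resulting variance understatement with a nonzero causal effect).
#'
#' @param h a `harmonized_set` from [harmonize()].
#' @return an object of class `wald_ratios`: data frame with columns
#'   `snp_id`, `ratio`, `ratio_se`, `weight`, plus the harmonized betas
#'   and SEs (used by the Egger regression, which works on the raw
#'   effect pairs).
#' @export
wald_ratios <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  p <- h$pairs
  if (nrow(p) == 0L) stop("no harmonized pairs", call. = FALSE)
  zero <- p$snp_id[p$beta_exposure == 0]
  if (length(zero)) {
    stop("degenerate instrument(s) with zero exposure effect: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    snp_id = p$snp_id,
    ratio = p$beta_outcome / p$beta_exposure,
    ratio_se = p$se_outcome / abs(p$beta_exposure),
    beta_exposure = p$beta_exposure, se_exposure = p$se_exposure,
    beta_outcome = p$beta_outcome, se_outcome = p$se_outcome,
    stringsAsFactors = FALSE)
  out$weight <- 1 / out$ratio_se^2
  if (any(!is.finite(out$weight) | out$weight <= 0)) {
    stop("non-finite Wald-ratio weights", call. = FALSE)
  }
  structure(out, exposure_label = h$exposure_label,
            outcome_label = h$outcome_label,
            class = c("wald_ratios", "data.frame"))
}

# Normal-theory 95% multiplier used for all OR confidence intervals.
Z95 <- 1.959964

#' Transform a log-scale effect to an odds ratio with CI
#'
#' `or = exp(beta)` with `ci = exp(beta -/+ z*se)`.
#'
#' @param beta,se effect and standard error on the log-odds scale
#'   (vectorised); `se >= 0`.
#' @param z normal multiplier (default 1.959964 for a 95% interval).
#' @return data frame with columns `or`, `ci_low`, `ci_high`.
#' @export
beta_to_or <- function(beta, se, z = Z95) {
  stopifnot(all(se >= 0, na.rm = TRUE))
  data.frame(or = exp(beta), ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se))
}

# Common MrResult container; `extra` carries method-specific pieces
# (Egger intercept triple, bootstrap settings).
new_mr_result <- function(method, nsnp, beta, se, pvalue, extra = list()) {
  ci <- beta_to_or(beta, se)
  structure(list(method = method, nsnp = as.integer(nsnp),
                 beta = beta, se = se, or = ci$or,
                 ci_low = ci$ci_low, ci_high = ci$ci_high,
                 pvalue = pvalue, extra = extra),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s (nsnp = %d): beta %s (se %s), OR %s (95%% CI %s-%s), p %s\n",
              x$method, x$nsnp, signif(x$beta, digits), signif(x$se, digits),
              signif(x$or, digits), signif(x$ci_low, digits),
              signif(x$ci_high, digits), format.pval(x$pvalue, digits)))
  invisible(x)
}

# p-value from a (possibly degenerate) z or t statistic.  An exact fit
# (se == 0) gives p = 1 for a zero estimate and p = 0 otherwise.
two_sided_p <- function(est, se, df = Inf) {
  if (se == 0) return(if (est == 0) 1 else 0)
  t <- est / se
  if (is.finite(df)) 2 * stats::pt(-abs(t), df) else 2 * stats::pnorm(-abs(t))
}

#' Inverse-variance weighted estimator
#'
#' Precision-weighted average of the per-SNP Wald ratios,
#' `beta = sum(w * ratio) / sum(w)` with `w = 1/ratio_se^2` — equivalent
#' to weighted least squares of the outcome on the exposure effects
#' through the origin.  The fixed-effect SE is `(sum w)^(-1/2)`; the
#' multiplicative random-effects SE inflates it by
#' `sqrt(max(1, Q/(J-1)))` where Q is Cochran's heterogeneity statistic.
#' A single instrument returns its Wald ratio labelled `ivw_fixed`.
#'
#' @param r a `wald_ratios` object.
#' @param effects_model `"fixed"` or `"random"`.
#' @return an `mr_result`.
#' @export
mr_ivw <- function(r, effects_model = c("fixed", "random")) {
  effects_model <- match.arg(effects_model)
  r <- as_wald_ratios(r)
  J <- nrow(r)
  if (J == 0L) stop("no instruments", call. = FALSE)
  w <- r$weight
  beta <- sum(w * r$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  method <- "ivw_fixed"
  if (J == 1L) {
    return(new_mr_result(method, 1L, r$ratio, r$ratio_se,
                         two_sided_p(r$ratio, r$ratio_se)))
  }
  if (effects_model == "random") {
    q <- sum(w * (r$ratio - beta)^2)
    se <- se * sqrt(max(1, q / (J - 1)))
    method <- "ivw_random"
  }
  new_mr_result(method, J, beta, se, two_sided_p(beta, se))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with a free intercept, weights `1/se_outcome^2`, after
#' orienting every instrument to a non-negative exposure effect (the
#' orientation required for the estimator's identification; it is
#' internal and recorded in `extra$n_flipped`).  The slope is the causal
#' estimate; a nonzero intercept indicates directional horizontal
#' pleiotropy.  Slope and intercept p-values use the t distribution with
#' J-2 degrees of freedom.
#'
#' @param r a `wald_ratios` object with at least 3 instruments.
#' @return an `mr_result`; `extra` holds `egger_intercept`,
#'   `intercept_se`, `intercept_p`, `sigma2` and `n_flipped`.
#' @export
mr_egger <- function(r) {
  r <- as_wald_ratios(r)
  J <- nrow(r)
  if (J < 3L) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  s <- ifelse(r$beta_exposure < 0, -1, 1)
  x <- s * r$beta_exposure
  y <- s * r$beta_outcome
  w <- 1 / r$se_outcome^2
  fit <- wls_line(x, y, w)
  df <- J - 2L
  new_mr_result("egger", J, fit$slope, fit$slope_se,
                two_sided_p(fit$slope, fit$slope_se, df),
                extra = list(egger_intercept = fit$intercept,
                             intercept_se = fit$intercept_se,
                             intercept_p = two_sided_p(fit$intercept,
                                                       fit$intercept_se, df),
                             sigma2 = fit$sigma2,
                             n_flipped = sum(s < 0)))
}

# Closed-form weighted least squares of y on x with intercept; variance
# from the usual residual estimate s^2 (X'WX)^-1 with J-2 df.
wls_line <- function(x, y, w) {
  W <- sum(w); Sx <- sum(w * x); Sy <- sum(w * y)
  Sxx <- sum(w * x^2); Sxy <- sum(w * x * y)
  det <- W * Sxx - Sx^2
  if (det <= 0) stop("degenerate design in weighted regression", call. = FALSE)
  slope <- (W * Sxy - Sx * Sy) / det
  intercept <- (Sy - slope * Sx) / W
  e <- y - intercept - slope * x
  sigma2 <- sum(w * e^2) / (length(x) - 2)
  # an exact linear fit leaves only rounding noise in the residuals;
  # snap it to zero so downstream p-values are 0/1, not noise ratios
  yscale <- max(abs(y), .Machine$double.xmin)
  if (max(abs(e)) <= 1e-10 * yscale) {
    sigma2 <- 0
    e[] <- 0
    if (abs(intercept) <= 1e-10 * yscale) intercept <- 0
    if (abs(slope) <= 1e-10 * yscale / max(abs(x))) slope <- 0
  }
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(sigma2 * W / det),
       intercept_se = sqrt(sigma2 * Sxx / det),
       sigma2 = sigma2, residuals = e)
}

# Interpolated weighted median of `values` with weights `w`: with
# normalized weights sorted by value, the cumulative midpoints
# p_j = cumsum(w')_j - w'_j/2 bracket 0.5 and the estimate interpolates
# linearly between the bracketing values.
weighted_median_estimate <- function(values, w) {
  o <- order(values)
  v <- values[o]
  wn <- w[o] / sum(w)
  p <- cumsum(wn) - wn / 2
  if (p[1] >= 0.5) return(v[1])
  if (p[length(p)] < 0.5) return(v[length(v)])
  j <- max(which(p < 0.5))
  v[j] + (v[j + 1] - v[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

#' Weighted median estimator
#'
#' The interpolated weighted median of the Wald ratios: consistent when
#' at least half the weight comes from valid instruments.  The SE comes
#' from a seeded parametric bootstrap — each ratio is resampled from a
#' normal with its first-order SE, the weighted median recomputed, and
#' the standard deviation over replicates taken.
#'
#' @param r a `wald_ratios` object with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap; results are reproducible given
#'   `(n_boot, seed)`.
#' @return an `mr_result`; `extra` records `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(r, n_boot = 1000, seed = 1) {
  r <- as_wald_ratios(r)
  J <- nrow(r)
  if (J < 3L) stop("weighted median requires at least 3 instruments",
                   call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  beta <- weighted_median_estimate(r$ratio, r$weight)
  se <- boot_se(function(ratios) weighted_median_estimate(ratios, r$weight),
                r$ratio, r$ratio_se, n_boot, seed)
  new_mr_result("weighted_median", J, beta, se, two_sided_p(beta, se),
                extra = list(n_boot = n_boot, seed = seed))
}

# Parametric bootstrap SE: resample each ratio from Normal(ratio, se),
# recompute the estimator, return the SD over replicates.  RNG state of
# the caller is left untouched.
boot_se <- function(estimator, ratios, ratio_se, n_boot, seed) {
  J <- length(ratios)
  reps <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      estimator(stats::rnorm(J, ratios, ratio_se))
    }, numeric(1))
  })
  stats::sd(reps)
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Weighted gaussian-kernel density mode of `values`; bandwidth per the
# modified Silverman rule h = factor * 0.9 * min(sd, mad) * J^(-1/5).
# The maximizer is located on a 512-point grid then refined by
# golden-section search (stats::optimize) in the bracketing cells.
weighted_mode_estimate <- function(values, w, bandwidth_factor = 1) {
  if (max(values) == min(values)) return(values[1])
  s <- stats::sd(values)
  m <- stats::mad(values)  # normalized (constant 1.4826)
  h <- bandwidth_factor * 0.9 * min(s, if (m > 0) m else s) *
    length(values)^(-1 / 5)
  wn <- w / sum(w)
  dens <- function(x) {
    vapply(x, function(xi) sum(wn * stats::dnorm((xi - values) / h)) / h,
           numeric(1))
  }
  grid <- seq(min(values), max(values), length.out = 512L)
  i <- which.max(dens(grid))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) return(grid[i])
  stats::optimize(dens, c(lo, hi), maximum = TRUE,
                  tol = .Machine$double.eps^0.5)$maximum
}

#' Weighted mode estimator
#'
#' The mode-based estimate: the maximizer of a weighted gaussian kernel
#' density over the Wald ratios, consistent when the largest cluster of
#' instruments is valid.  Bandwidth follows the modified Silverman rule
#' `h = bandwidth_factor * 0.9 * min(sd, mad) * J^(-1/5)`; when all
#' ratios coincide the common value is returned with SE 0.  SE by seeded
#' parametric bootstrap as in [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor multiplier on the Silverman bandwidth
#'   (default 1).
#' @return an `mr_result`; `extra` records `bandwidth_factor`, `n_boot`
#'   and `seed`.
#' @export
mr_weighted_mode <- function(r, bandwidth_factor = 1, n_boot = 1000,
                             seed = 1) {
  r <- as_wald_ratios(r)
  J <- nrow(r)
  if (J < 3L) stop("weighted mode requires at least 3 instruments",
                   call. = FALSE)
  if (max(r$ratio) == min(r$ratio)) {
    return(new_mr_result("weighted_mode", J, r$ratio[1], 0, 1,
                         extra = list(bandwidth_factor = bandwidth_factor,
                                      n_boot = n_boot, seed = seed)))
  }
  beta <- weighted_mode_estimate(r$ratio, r$weight, bandwidth_factor)
  se <- boot_se(function(ratios) {
    weighted_mode_estimate(ratios, r$weight, bandwidth_factor)
  }, r$ratio, r$ratio_se, n_boot, seed)
  new_mr_result("weighted_mode", J, beta, se, two_sided_p(beta, se),
                extra = list(bandwidth_factor = bandwidth_factor,
                             n_boot = n_boot, seed = seed))
}

as_wald_ratios <- function(r) {
  if (inherits(r, "harmonized_set")) r <- wald_ratios(r)
  if (!inherits(r, "wald_ratios")) {
    stop("expected a wald_ratios (or harmonized_set) object", call. = FALSE)
  }
  r
}
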