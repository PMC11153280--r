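#' Cochran's Q heterogeneity statistic
#'
#' Heterogeneity among per-SNP causal estimates.  Under the IVW model,
#' `Q = sum(w_j * (ratio_j - beta_ivw)^2)` with J-1 degrees of freedom;
#' under the Egger model, Q is the weighted residual sum of squares of
#' the intercept regression with J-2 degrees of freedom.  The p-value is
#' the upper chi-square tail and `I2 = max(0, (Q - df)/Q) * 100` (the
#' standard meta-analysis inconsistency index, truncated at 0).  With a
#' single instrument Q = 0 with df = 0 and the p-value is undefined
#' (`NA`), not 1.
#'
#' @param r a `wald_ratios` object (or `harmonized_set`).
#' @param model `"ivw"` (default) or `"egger"`.
#' @return object of class `heterogeneity_result`: list with `q`, `df`,
#'   `pvalue`, `i2`.
#' @export
cochran_q <- function(r, model = c("ivw", "egger")) {
  model <- match.arg(model)
  r <- as_wald_ratios(r)
  J <- nrow(r)
  if (model == "ivw") {
    if (J < 1L) stop("no instruments", call. = FALSE)
    if (J == 1L) {
      return(new_heterogeneity(0, 0L, NA_real_))
    }
    w <- r$weight
    beta <- sum(w * r$ratio) / sum(w)
    q <- sum(w * (r$ratio - beta)^2)
    df <- J - 1L
  } else {
    if (J < 3L) stop("Egger heterogeneity requires at least 3 instruments",
                     call. = FALSE)
    s <- ifelse(r$beta_exposure < 0, -1, 1)
    w <- 1 / r$se_outcome^2
    fit <- wls_line(s * r$beta_exposure, s * r$beta_outcome, w)
    q <- sum(w * fit$residuals^2)
    df <- J - 2L
  }
  new_heterogeneity(q, df, stats::pchisq(q, df, lower.tail = FALSE))
}

new_heterogeneity <- function(q, df, pvalue) {
  structure(list(q = q, df = as.integer(df), pvalue = pvalue,
                 i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %s, I2 = %.1f%%\n",
              x$q, x$df,
              if (is.na(x$pvalue)) "NA" else format.pval(x$pvalue, 4),
              x$i2))
  invisible(x)
}

#' Choose the IVW effects model from the heterogeneity test
#'
#' The standard decision rule: a heterogeneity p-value below `alpha`
#' selects multiplicative random effects, otherwise fixed effects (a
#' p-value exactly at `alpha`, or undefined, keeps fixed effects).
#'
#' @param h a `heterogeneity_result`.
#' @param alpha significance level in (0, 1), default 0.05.
#' @return `"fixed"` or `"random"`.
#' @export
choose_effects_model <- function(h, alpha = 0.05) {
  stopifnot(inherits(h, "heterogeneity_result"),
            alpha > 0, alpha < 1)
  if (!is.na(h$pvalue) && h$pvalue < alpha) "random" else "fixed"
}

#' Egger intercept test for directional pleiotropy
#'
#' Re-exports the intercept triple of the [mr_egger()] regression: the
#' intercept estimate, its standard error, and a two-sided p-value on the
#' t distribution with J-2 degrees of freedom.  An intercept compatible
#' with zero means no evidence of directional horizontal pleiotropy.
#'
#' @inheritParams cochran_q
#' @return list with `intercept`, `se`, `pvalue`.
#' @export
egger_intercept_test <- function(r) {
  fit <- mr_egger(r)
  list(intercept = fit$extra$egger_intercept,
       se = fit$extra$intercept_se,
       pvalue = fit$extra$intercept_p)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate J times, each time dropping one
#' instrument.  When every leave-one-out estimate lies on the same side
#' of zero the result is considered robust to any single SNP
#' (`all_same_side`).
#'
#' @param h a `harmonized_set` (or `wald_ratios`) with at least 3
#'   instruments.
#' @param effects_model effects model passed to [mr_ivw()] for each
#'   reduced set (the study's chosen model; default `"fixed"`).
#' @return object of class `loo_result`: `rows` (data frame with one row
#'   per dropped SNP: `snp_id`, `beta`, `se`, `pvalue`) and
#'   `all_same_side`.
#' @export
leave_one_out <- function(h, effects_model = c("fixed", "random")) {
  effects_model <- match.arg(effects_model)
  r <- as_wald_ratios(h)
  J <- nrow(r)
  if (J < 3L) stop("leave-one-out requires at least 3 instruments",
                   call. = FALSE)
  rows <- do.call(rbind, lapply(seq_len(J), function(i) {
    fit <- mr_ivw(r[-i, , drop = FALSE], effects_model)
    data.frame(snp_id = r$snp_id[i], beta = fit$beta, se = fit$se,
               pvalue = fit$pvalue, stringsAsFactors = FALSE)
  }))
  structure(list(rows = rows,
                 all_same_side = all(rows$beta > 0) || all(rows$beta < 0)),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("leave-one-out over %d instruments: %s\n", nrow(x$rows),
              if (x$all_same_side) "all estimates on the same side of 0"
              else "estimates change sign"))
  print.data.frame(x$rows, digits = 4)
  invisible(x)
}
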