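#' Fit the two-sample Mendelian randomization estimators
#'
#' The package's central fitting function.  Given harmonized
#' exposure/outcome effect pairs it computes the per-SNP Wald ratios and
#' runs the requested estimators — inverse-variance weighted, MR-Egger,
#' weighted median and weighted mode — together with the heterogeneity
#' diagnostics that drive the IVW effects-model choice.
#'
#' With `effects_model = "auto"` (the default) the IVW effects model
#' follows the conventional rule: Cochran's Q p-value below `alpha`
#' selects multiplicative random effects, otherwise fixed effects.
#'
#' @param h a `harmonized_set` from [harmonize()].
#' @param methods any of `"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"weighted_mode"`.
#' @param effects_model `"auto"`, `"fixed"` or `"random"` (IVW only).
#' @param alpha significance level used by the auto rule (default 0.05).
#' @param n_boot,seed,bandwidth_factor settings for the bootstrap methods
#'   (see [mr_weighted_median()], [mr_weighted_mode()]).
#' @return An object of class `mr_fit` with components:
#'   \describe{
#'     \item{results}{data frame, one row per method: `exposure`,
#'       `outcome`, `method`, `nsnp`, `beta`, `se`, `or`, `ci_low`,
#'       `ci_high`, `pvalue`.}
#'     \item{fits}{the underlying `mr_result` objects.}
#'     \item{ratios}{the `wald_ratios` used.}
#'     \item{heterogeneity}{list of `heterogeneity_result` for the IVW
#'       and (when fitted) Egger models.}
#'     \item{pleiotropy}{the Egger intercept triple, when Egger ran.}
#'     \item{effects_model}{the model actually used for IVW.}
#'   }
#'   Methods: `print`, `summary`, `coef`, `confint`, `plot`, `predict`,
#'   `fitted`, `residuals`.
#' @examples
#' cfg <- sim_config(seed = 7)
#' sim <- generate_two_sample(cfg)
#' iv <- select_instruments(sim$exposure, ld = sim$ld)
#' h <- harmonize(iv, sim$outcome)
#' fit <- mr_fit(h, seed = 7)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(h, methods = c("ivw", "egger", "weighted_median",
                                  "weighted_mode"),
                   effects_model = c("auto", "fixed", "random"),
                   alpha = 0.05, n_boot = 1000, seed = 1,
                   bandwidth_factor = 1) {
  effects_model <- match.arg(effects_model)
  methods <- match.arg(methods, several.ok = TRUE)
  r <- wald_ratios(h)
  J <- nrow(r)
  het <- list(ivw = cochran_q(r, "ivw"))
  if (J >= 3L) {
    # a constant exposure-effect design has no Egger model; skip its Q
    het$egger <- tryCatch(cochran_q(r, "egger"), error = function(e) NULL)
  }
  used_model <- if (effects_model == "auto") {
    choose_effects_model(het$ivw, alpha)
  } else effects_model
  fits <- list()
  for (m in methods) {
    fits[[m]] <- switch(m,
      ivw = mr_ivw(r, used_model),
      egger = mr_egger(r),
      weighted_median = mr_weighted_median(r, n_boot, seed),
      weighted_mode = mr_weighted_mode(r, bandwidth_factor, n_boot, seed))
  }
  results <- do.call(rbind, lapply(fits, function(f) {
    data.frame(exposure = attr(r, "exposure_label") %||% "exposure",
               outcome = attr(r, "outcome_label") %||% "outcome",
               method = f$method, nsnp = f$nsnp, beta = f$beta, se = f$se,
               or = f$or, ci_low = f$ci_low, ci_high = f$ci_high,
               pvalue = f$pvalue, stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL
  structure(list(results = results, fits = fits, ratios = r,
                 heterogeneity = het,
                 pleiotropy = if ("egger" %in% names(fits)) {
                   list(intercept = fits$egger$extra$egger_intercept,
                        se = fits$egger$extra$intercept_se,
                        pvalue = fits$egger$extra$intercept_p)
                 },
                 effects_model = used_model, alpha = alpha,
                 nsnp = J),
            class = "mr_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d instruments, %s-effect IVW)\n",
              x$results$exposure[1], x$results$outcome[1], x$nsnp,
              x$effects_model))
  df <- x$results[c("method", "nsnp", "beta", "se", "or", "ci_low",
                    "ci_high", "pvalue")]
  print.data.frame(df, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(object, class = c("summary.mr_fit", "mr_fit"))
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  print.mr_fit(x, digits = digits)
  h <- x$heterogeneity$ivw
  cat(sprintf("\nHeterogeneity (IVW): Q = %.4g on %d df, p = %s, I2 = %.1f%%\n",
              h$q, h$df, if (is.na(h$pvalue)) "NA" else
                format.pval(h$pvalue, digits), h$i2))
  if (!is.null(x$heterogeneity$egger)) {
    he <- x$heterogeneity$egger
    cat(sprintf("Heterogeneity (Egger): Q = %.4g on %d df, p = %s\n",
                he$q, he$df, format.pval(he$pvalue, digits)))
  }
  if (!is.null(x$pleiotropy)) {
    cat(sprintf("Egger intercept: %.4g (se %.4g), p = %s\n",
                x$pleiotropy$intercept, x$pleiotropy$se,
                format.pval(x$pleiotropy$pvalue, digits)))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$results$beta, object$results$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  res <- object$results
  out <- cbind(res$beta - z * res$se, res$beta + z * res$se)
  dimnames(out) <- list(res$method,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
fitted.mr_fit <- function(object, ...) {
  ivw <- object$results$beta[grepl("^ivw", object$results$method)][1]
  stats::setNames(ivw * object$ratios$beta_exposure, object$ratios$snp_id)
}

#' @export
residuals.mr_fit <- function(object, ...) {
  stats::setNames(object$ratios$beta_outcome - fitted(object),
                  object$ratios$snp_id)
}

#' @export
predict.mr_fit <- function(object, newdata = NULL,
                           method = NULL, ...) {
  beta <- if (is.null(method)) {
    object$results$beta[grepl("^ivw", object$results$method)][1]
  } else {
    object$results$beta[object$results$method == method][1]
  }
  if (is.null(newdata)) return(fitted(object))
  beta * newdata
}

#' Plot an MR fit
#'
#' `type = "forest"` draws the per-method odds ratios with 95% CIs;
#' `type = "scatter"` draws the harmonized effect pairs with the fitted
#' method lines (IVW through the origin, Egger with its intercept).
#'
#' @param x an `mr_fit`.
#' @param type `"forest"` or `"scatter"`.
#' @param ... passed to the underlying base-graphics calls.
#' @export
plot.mr_fit <- function(x, type = c("forest", "scatter"), ...) {
  type <- match.arg(type)
  res <- x$results
  if (type == "forest") {
    k <- nrow(res)
    ylim <- c(0.5, k + 0.5)
    xlim <- range(c(res$ci_low, res$ci_high, 1))
    graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
                   xlab = "odds ratio (95% CI)", ylab = "",
                   main = sprintf("%s -> %s", res$exposure[1],
                                  res$outcome[1]), ...)
    graphics::abline(v = 1, lty = 2, col = "grey60")
    ys <- rev(seq_len(k))
    graphics::segments(res$ci_low, ys, res$ci_high, ys)
    graphics::points(res$or, ys, pch = 15)
    graphics::axis(2, at = ys, labels = res$method, las = 1, cex.axis = 0.8)
  } else {
    r <- x$ratios
    graphics::plot(r$beta_exposure, r$beta_outcome,
                   xlab = "SNP effect on exposure",
                   ylab = "SNP effect on outcome", pch = 19, ...)
    graphics::arrows(r$beta_exposure, r$beta_outcome - Z95 * r$se_outcome,
                     r$beta_exposure, r$beta_outcome + Z95 * r$se_outcome,
                     angle = 90, code = 3, length = 0.02, col = "grey50")
    ivw <- res$beta[grepl("^ivw", res$method)][1]
    if (!is.na(ivw)) graphics::abline(0, ivw, col = "steelblue")
    if ("egger" %in% res$method) {
      graphics::abline(x$pleiotropy$intercept,
                       res$beta[res$method == "egger"], col = "firebrick",
                       lty = 2)
    }
  }
  invisible(x)
}

#' Forest-plot data table
#'
#' Emits the per-method (or per-analysis) odds ratios and confidence
#' intervals as a plain table, the forest-figure companion of the result
#' tables.
#'
#' @param fits an `mr_fit` or a named list of them.
#' @return data frame with `analysis`, `method`, `nsnp`, `or`, `ci_low`,
#'   `ci_high`, `pvalue`.
#' @export
forest_data <- function(fits) {
  if (inherits(fits, "mr_fit")) fits <- list(main = fits)
  do.call(rbind, lapply(names(fits), function(nm) {
    res <- fits[[nm]]$results
    data.frame(analysis = nm, method = res$method, nsnp = res$nsnp,
               or = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
               pvalue = res$pvalue, stringsAsFactors = FALSE)
  }))
}
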