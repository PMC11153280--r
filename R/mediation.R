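#' Prerequisite gate for two-step mediation
#'
#' Mediation is decomposed only when every MR leg shows a causal signal:
#' each leg's IVW p-value must be strictly below `alpha`.  The returned
#' reason names every failing leg.
#'
#' @param leg_pvalues named numeric vector of per-leg IVW p-values
#'   (e.g. `c(total = ..., exposure_mediator = ..., mediator_outcome =
#'   ...)`).
#' @param alpha significance level (default 0.05).
#' @return list with `pass` (logical) and `reason` (`NULL` when passing,
#'   otherwise a message naming the failing legs).
#' @export
check_prerequisite <- function(leg_pvalues, alpha = 0.05) {
  stopifnot(is.numeric(leg_pvalues), alpha > 0, alpha < 1)
  nm <- names(leg_pvalues)
  if (is.null(nm)) nm <- paste0("leg", seq_along(leg_pvalues))
  fail <- which(!(leg_pvalues < alpha))
  if (!length(fail)) return(list(pass = TRUE, reason = NULL))
  list(pass = FALSE,
       reason = sprintf(
         "prerequisite P_IVW < %g not met for leg(s): %s", alpha,
         paste(sprintf("%s (p = %g)", nm[fail], leg_pvalues[fail]),
               collapse = ", ")))
}

as_leg <- function(x, what) {
  if (inherits(x, "mr_result")) {
    x <- list(beta = x$beta, se = x$se, pvalue = x$pvalue)
  }
  if (inherits(x, "mr_fit")) {
    i <- grep("^ivw", x$results$method)[1]
    x <- list(beta = x$results$beta[i], se = x$results$se[i],
              pvalue = x$results$pvalue[i])
  }
  if (is.numeric(x) && is.null(names(x)) && length(x) <= 3) {
    x <- stats::setNames(as.list(x), c("beta", "se", "pvalue")[seq_along(x)])
  }
  if (is.null(x$beta) || !is.finite(x$beta)) {
    stop(what, " leg needs a finite beta", call. = FALSE)
  }
  if (is.null(x$se)) x$se <- NA_real_
  if (!is.na(x$se) && x$se <= 0) {
    stop(what, " leg needs a positive se (or NA when unknown)",
         call. = FALSE)
  }
  if (is.null(x$pvalue)) x$pvalue <- NA_real_
  x[c("beta", "se", "pvalue")]
}

#' Two-step MR mediation decomposition
#'
#' Product-of-coefficients decomposition of a total causal effect `b`
#' into an indirect path through a mediator and a direct remainder:
#' mediation effect `b1 * b2` (exposure-to-mediator times
#' mediator-to-outcome), direct effect `b - b1*b2`, and — when the
#' mediation and total effects share a sign — the proportion mediated
#' `b1*b2 / b` as a percentage.  When the signs disagree the
#' decomposition is classified inconsistent and no proportion is
#' reported.
#'
#' Two reporting paths are provided.  The exact path (default) carries
#' full precision, so mediation + direct equals the total to machine
#' precision.  With `rounding = R` the product is rounded to R decimal
#' places *before* the direct effect and proportion are derived — the
#' arithmetic convention of published mediation tables that print rounded
#' legs.
#'
#' A delta-method SE for the mediated effect,
#' `sqrt(b2^2 se_b1^2 + b1^2 se_b2^2)`, is reported when both leg SEs
#' are available (an extension beyond the usual printed tables, flagged
#' in the output).
#'
#' @param total the exposure-to-outcome leg: an `mr_fit`, `mr_result`,
#'   or list/vector with `beta`, optional `se`, `pvalue`.
#' @param exposure_mediator,mediator_outcome the two mediation legs, in
#'   the same forms (betas `b1` and `b2`).
#' @param alpha prerequisite significance level (default 0.05).
#' @param rounding decimal places for the rounded reporting path, or
#'   `NULL` (default) for exact arithmetic.
#' @param force compute the decomposition even when the prerequisite
#'   gate fails; the result is marked exploratory.
#' @param labels optional character vector of the three trait labels
#'   (exposure, mediator, outcome).
#' @return An object of class `mr_mediation`: `b`, `b1`, `b2`,
#'   `mediation_effect`, `direct_effect`, `proportion_mediated` (percent,
#'   `NA` when suppressed), `se_mediation`, `consistent`, `gated`,
#'   `gate_reason`, `exploratory`.
#' @export
mr_mediate <- function(total, exposure_mediator, mediator_outcome,
                       alpha = 0.05, rounding = NULL, force = FALSE,
                       labels = c("exposure", "mediator", "outcome")) {
  lt <- as_leg(total, "total")
  l1 <- as_leg(exposure_mediator, "exposure->mediator")
  l2 <- as_leg(mediator_outcome, "mediator->outcome")
  gate <- check_prerequisite(
    c(total = lt$pvalue, exposure_mediator = l1$pvalue,
      mediator_outcome = l2$pvalue), alpha)
  base <- list(b = lt$beta, b1 = l1$beta, b2 = l2$beta,
               labels = labels, alpha = alpha, rounding = rounding,
               gated = !gate$pass, gate_reason = gate$reason,
               exploratory = !gate$pass && force,
               legs = list(total = lt, exposure_mediator = l1,
                           mediator_outcome = l2))
  if (!gate$pass && !force) {
    out <- c(base, list(mediation_effect = NA_real_,
                        direct_effect = NA_real_,
                        proportion_mediated = NA_real_,
                        se_mediation = NA_real_, consistent = NA))
    return(structure(out, class = "mr_mediation"))
  }
  med <- l1$beta * l2$beta
  if (!is.null(rounding)) med <- round(med, rounding)
  direct <- lt$beta - med
  consistent <- med == 0 || lt$beta == 0 || sign(med) == sign(lt$beta)
  prop <- NA_real_
  if (consistent && lt$beta != 0) prop <- med / lt$beta * 100
  se_med <- if (!is.na(l1$se) && !is.na(l2$se)) {
    sqrt(l2$beta^2 * l1$se^2 + l1$beta^2 * l2$se^2)
  } else NA_real_
  out <- c(base, list(mediation_effect = med, direct_effect = direct,
                      proportion_mediated = prop, se_mediation = se_med,
                      consistent = consistent))
  structure(out, class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, digits = 4, ...) {
  cat(sprintf("Two-step MR mediation: %s -> %s -> %s\n",
              x$labels[1], x$labels[2], x$labels[3]))
  if (x$gated && is.na(x$mediation_effect)) {
    cat("  gated: ", x$gate_reason, "\n", sep = "")
    return(invisible(x))
  }
  if (x$exploratory) {
    cat("  [exploratory: prerequisite gate overridden — ",
        x$gate_reason, "]\n", sep = "")
  }
  cat(sprintf("  total effect b      = %s\n", signif(x$b, digits)))
  cat(sprintf("  mediation (b1*b2)   = %s", signif(x$mediation_effect,
                                                   digits)))
  if (!is.na(x$se_mediation)) {
    cat(sprintf("  (delta-method se %s)", signif(x$se_mediation, digits)))
  }
  cat("\n")
  cat(sprintf("  direct (b - b1*b2)  = %s\n", signif(x$direct_effect,
                                                     digits)))
  if (x$consistent) {
    cat(sprintf("  proportion mediated = %.2f%%\n", x$proportion_mediated))
  } else {
    cat("  mediation and direct effects inconsistent in sign:",
        "no proportion reported\n")
  }
  invisible(x)
}

# Canonical table rows for write_result_table().
mediation_table <- function(x) {
  stopifnot(inherits(x, "mr_mediation"))
  data.frame(
    exposure = x$labels[1], outcome = x$labels[3],
    method = c("total", "mediation", "direct"),
    nsnp = NA_integer_,
    beta = c(x$b, x$mediation_effect, x$direct_effect),
    se = c(x$legs$total$se, x$se_mediation, NA_real_),
    or = exp(c(x$b, x$mediation_effect, x$direct_effect)),
    ci_low = NA_real_, ci_high = NA_real_,
    pvalue = c(x$legs$total$pvalue, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
}
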