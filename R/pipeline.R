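#' Study configuration
#'
#' Reads (or validates) the configuration driving [run_study()]: dataset
#' paths with column maps, the gene region, selection thresholds, method
#' settings and the output directory.  The file format is YAML; an
#' annotated example ships in `inst/extdata/example_config.yaml`.
#'
#' Required blocks: `exposure`, `outcome`, `positive_control` (each with
#' `path` and optionally `label`, `column_map`, `trait_type`);
#' `gene_region` (`gene_name`, `chrom`, `start`, `end`, `flank_kb`);
#' `ld_matrix` (path).  Optional: `mediators`, a list of blocks each
#' with `label`, `path` (the mediator GWAS, used both as the outcome of
#' the first leg and the exposure of the second) and optionally its own
#' `ld_matrix`; `thresholds` (`p_instrument`, `r2`, `alpha`); `methods`
#' (`n_boot`, `seed`, `bandwidth_factor`).
#'
#' @param x path to a YAML file, or an equivalent named list.
#' @return a validated list of class `study_config` (with `config_hash`,
#'   the md5 of the file when read from disk).
#' @export
study_config <- function(x) {
  hash <- NA_character_
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    hash <- unname(tools::md5sum(x))
    x <- yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  for (block in c("exposure", "outcome", "positive_control")) {
    if (is.null(x[[block]]$path)) {
      stop("config block '", block, "' needs a dataset path", call. = FALSE)
    }
    if (!file.exists(x[[block]]$path)) {
      stop("dataset for '", block, "' not found: ", x[[block]]$path,
           call. = FALSE)
    }
  }
  if (is.null(x$gene_region)) stop("config needs a gene_region block",
                                   call. = FALSE)
  th <- x$thresholds %||% list()
  x$thresholds <- list(p_instrument = th$p_instrument %||% 5e-8,
                       r2 = th$r2 %||% 0.3,
                       alpha = th$alpha %||% 0.05)
  if (x$thresholds$alpha <= 0 || x$thresholds$alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  me <- x$methods %||% list()
  x$methods <- list(n_boot = me$n_boot %||% 1000,
                    seed = me$seed %||% 1,
                    bandwidth_factor = me$bandwidth_factor %||% 1)
  x$config_hash <- hash
  structure(x, class = "study_config")
}

load_dataset <- function(block, default_label,
                         default_type = "continuous") {
  cm <- block$column_map
  if (!is.null(cm)) cm <- unlist(cm)
  read_summary_stats(block$path, column_map = cm,
                     trait_label = block$label %||% default_label,
                     trait_type = block$trait_type %||% default_type)
}

#' Positive-control gate
#'
#' The study proceeds to the outcome analysis only when the
#' positive-control MR shows the expected causal signal: IVW p-value
#' strictly below `alpha`.
#'
#' @param results an `mr_fit` (or single `mr_result`) for the
#'   positive-control pair.
#' @param alpha significance level (default 0.05).
#' @return logical.
#' @export
positive_control_gate <- function(results, alpha = 0.05) {
  p <- ivw_pvalue(results)
  isTRUE(p < alpha)
}

ivw_pvalue <- function(results) {
  if (inherits(results, "mr_result")) return(results$pvalue)
  stopifnot(inherits(results, "mr_fit"))
  i <- grep("^ivw", results$results$method)[1]
  if (is.na(i)) stop("no IVW result present", call. = FALSE)
  results$results$pvalue[i]
}

#' Direction-concordance rule
#'
#' A causal relationship is declared when the IVW p-value is below
#' `alpha` *and* every other fitted method's beta shares the IVW beta's
#' sign (the supporting methods need not themselves be significant).
#'
#' @param results an `mr_fit` containing IVW plus at least one other
#'   method.
#' @param alpha significance level (default 0.05).
#' @return logical.
#' @export
concordance_check <- function(results, alpha = 0.05) {
  stopifnot(inherits(results, "mr_fit"))
  res <- results$results
  i <- grep("^ivw", res$method)[1]
  if (is.na(i)) stop("no IVW result present", call. = FALSE)
  others <- res$beta[-i]
  if (!length(others)) stop("concordance needs at least one non-IVW method",
                            call. = FALSE)
  res$pvalue[i] < alpha && all(sign(others) == sign(res$beta[i]))
}

#' Run a full drug-target MR + mediation study
#'
#' Executes the study decision flow end to end: cis instrument selection
#' on the exposure GWAS, the positive-control gate, the main MR with
#' heterogeneity/pleiotropy/leave-one-out diagnostics and the
#' direction-concordance rule, then for each configured mediator the two
#' MR legs and the gated product-of-coefficients mediation.  Every drop,
#' gate and model choice is recorded in a structured audit log; the run
#' is deterministic given the configured seed.
#'
#' Gate failures are recorded outcomes (the report says what was skipped
#' and why); I/O and validation failures abort.
#'
#' @param config a [study_config()] (or path to one).
#' @param override_positive_control proceed to the outcome analysis even
#'   if the positive-control gate fails (logged).
#' @return An object of class `study_report`; see the components in the
#'   examples and [write_study_report()] for serialisation.
#' @export
run_study <- function(config, override_positive_control = FALSE) {
  if (!inherits(config, "study_config")) config <- study_config(config)
  th <- config$thresholds
  me <- config$methods
  audit <- character(0)
  note <- function(...) audit <<- c(audit, sprintf(...))

  exposure <- load_dataset(config$exposure, "exposure")
  outcome <- load_dataset(config$outcome, "outcome", "binary")
  control <- load_dataset(config$positive_control, "positive_control",
                          "binary")
  reg <- do.call(gene_region, config$gene_region)
  ld <- read_ld_matrix(config$ld_matrix$path %||% config$ld_matrix)
  note("loaded exposure (%d SNPs), outcome (%d), positive control (%d)",
       nrow(exposure), nrow(outcome), nrow(control))

  iv <- select_instruments(exposure, region = reg, ld = ld,
                           p_threshold = th$p_instrument,
                           r2_threshold = th$r2)
  note("instrument selection: %d kept of %d (p < %g, r2 < %g, %s +/- %g kb)",
       nrow(iv$records), nrow(iv$selection_log), th$p_instrument, th$r2,
       reg$gene_name, reg$flank_kb)

  fit_pair <- function(instruments, out_ds) {
    h <- harmonize(instruments, out_ds)
    list(h = h, fit = mr_fit(h, effects_model = "auto", alpha = th$alpha,
                             n_boot = me$n_boot, seed = me$seed,
                             bandwidth_factor = me$bandwidth_factor))
  }

  pc <- fit_pair(iv, control)
  pc_pass <- positive_control_gate(pc$fit, th$alpha)
  note("positive control '%s': IVW p = %.3g -> %s",
       attr(control, "trait_label"), ivw_pvalue(pc$fit),
       if (pc_pass) "pass" else "fail")
  report <- list(positive_control_pass = pc_pass,
                 positive_control = pc$fit,
                 instrument_log = iv$selection_log,
                 thresholds = th,
                 provenance = list(config_hash = config$config_hash,
                                   seed = me$seed,
                                   package_version =
                                     as.character(utils::packageVersion("targetmr")),
                                   r_version = R.version.string))
  if (!pc_pass && !override_positive_control) {
    note("stopping: positive-control gate failed")
    report$audit_log <- audit
    return(structure(report, class = "study_report"))
  }
  if (!pc_pass) note("positive-control gate overridden by caller")

  main <- fit_pair(iv, outcome)
  note("main MR: %d harmonized pairs, %s-effect IVW (Q p = %.3g)",
       nrow(main$h$pairs), main$fit$effects_model,
       main$fit$heterogeneity$ivw$pvalue)
  loo <- leave_one_out(main$h, main$fit$effects_model)
  conc <- concordance_check(main$fit, th$alpha)
  note("concordance rule: %s", if (conc) "causal (IVW significant, all betas same-signed)"
       else "not causal")
  note("leave-one-out: %s",
       if (loo$all_same_side) "robust (all estimates same side of 0)"
       else "sign flips when some SNP removed")
  report$main <- main$fit
  report$main_harmonized <- main$h
  report$concordance <- conc
  report$leave_one_out <- loo

  mediation <- list()
  for (mb in config$mediators %||% list()) {
    lab <- mb$label %||% basename(mb$path)
    med_ds <- load_dataset(mb, lab, "binary")
    leg1 <- fit_pair(iv, med_ds)
    # mediator's own instruments for the second leg
    med_ld <- if (!is.null(mb$ld_matrix)) {
      read_ld_matrix(mb$ld_matrix$path %||% mb$ld_matrix)
    }
    # the mediator's own instruments must not include the exposure's cis
    # SNPs: those act on the outcome through the exposure's direct path
    # as well, violating the exclusion restriction for this leg
    med_pool <- ds_subset(med_ds,
                          !(med_ds$snp_id %in% iv$records$snp_id))
    med_iv <- select_instruments(med_pool, ld = med_ld,
                                 p_threshold = th$p_instrument,
                                 r2_threshold = th$r2)
    note("mediator '%s': %d mediator-specific instruments for the outcome leg",
         lab, nrow(med_iv$records))
    leg2 <- fit_pair(med_iv, outcome)
    med <- mr_mediate(main$fit, leg1$fit, leg2$fit, alpha = th$alpha,
                      labels = c(attr(exposure, "trait_label"), lab,
                                 attr(outcome, "trait_label")))
    if (med$gated) {
      note("mediator '%s': gated — %s", lab, med$gate_reason)
    } else {
      note("mediator '%s': mediation %.4g, direct %.4g%s", lab,
           med$mediation_effect, med$direct_effect,
           if (med$consistent) sprintf(", proportion %.2f%%",
                                       med$proportion_mediated)
           else " (signs inconsistent; proportion suppressed)")
    }
    mediation[[lab]] <- list(legs = list(exposure_mediator = leg1$fit,
                                         mediator_outcome = leg2$fit),
                             result = med)
  }
  report$mediation <- mediation
  report$audit_log <- audit
  structure(report, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Drug-target MR study report\n")
  cat(sprintf("positive control: %s\n",
              if (x$positive_control_pass) "pass" else "FAIL"))
  if (!is.null(x$main)) {
    print(x$main)
    cat(sprintf("concordance rule: %s\n",
                if (x$concordance) "causal" else "not causal"))
  }
  for (lab in names(x$mediation)) {
    cat("\n")
    print(x$mediation[[lab]]$result)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Serialises the result tables (tab-delimited), the audit log and a
#' human-readable report document into `dir`.  Content is deterministic
#' given the study seed (no timestamps).
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(audit = file.path(dir, "audit.log"),
             report = file.path(dir, "report.txt"))
  writeLines(report$audit_log, paths[["audit"]])
  tabs <- list(positive_control = report$positive_control)
  if (!is.null(report$main)) tabs$main <- report$main
  for (lab in names(report$mediation)) {
    m <- report$mediation[[lab]]
    tabs[[paste0("leg_", lab)]] <- m$legs$exposure_mediator
    tabs[[paste0("leg_", lab, "_outcome")]] <- m$legs$mediator_outcome
    if (!m$result$gated) tabs[[paste0("mediation_", lab)]] <- m$result
  }
  results_path <- file.path(dir, "results.tsv")
  write_result_table(tabs, results_path)
  paths <- c(paths, results = results_path)
  if (!is.null(report$instrument_log)) {
    p <- file.path(dir, "instrument_log.tsv")
    utils::write.table(report$instrument_log, p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, instrument_log = p)
  }
  if (!is.null(report$main)) {
    p <- file.path(dir, "forest_data.tsv")
    fl <- list(main = report$main)
    for (lab in names(report$mediation)) {
      fl[[paste0(lab, ":exposure_mediator")]] <-
        report$mediation[[lab]]$legs$exposure_mediator
      fl[[paste0(lab, ":mediator_outcome")]] <-
        report$mediation[[lab]]$legs$mediator_outcome
    }
    utils::write.table(forest_data(fl), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, forest = p)
  }
  con <- file(paths[["report"]], "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(report)
  cat("\nnote: no multiple-testing correction is applied across mediators\n")
  cat(sprintf("provenance: config %s, seed %s, targetmr %s, %s\n",
              report$provenance$config_hash, report$provenance$seed,
              report$provenance$package_version,
              report$provenance$r_version))
  invisible(paths)
}
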