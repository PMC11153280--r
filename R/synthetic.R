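#' Simulation configuration for synthetic GWAS summary statistics
#'
#' Defines the generative model used throughout the test suite: a set of
#' cis instruments inside a synthetic gene window, two independent GWAS
#' samples (the two-sample assumption), optional horizontal pleiotropy,
#' block LD structure, palindromic alleles, and optionally a three-trait
#' mediator chain with known leg effects.
#'
#' Per SNP j: minor-allele frequency `maf_j ~ U(maf_range)`, true
#' exposure effect `gamma_j ~ N(gamma_mean, gamma_sd^2)`, standard errors
#' from the standardized-trait model `se = 1/sqrt(2 n maf (1-maf))`, and
#' observed effects `bx_j ~ N(gamma_j, se_x^2)`,
#' `by_j ~ N(theta*gamma_j + alpha_j, se_y^2)` with pleiotropic effects
#' `alpha_j` equal to 0 (`none`), `N(0, pleiotropy_sd^2)` (`balanced`) or
#' `N(pleiotropy_mean, pleiotropy_sd^2)` (`directional`).  Binary traits
#' are mimicked by the same SE model with an effective sample size.
#'
#' Defaults mirror the motivating study design: 13 cis instruments of
#' which 3/13 palindromic, exposure/outcome/mediator GWAS sizes 173,082 /
#' 462,933 / 66,628, large cis effects (`gamma_mean = 0.3`), a modest
#' causal effect (`theta = 0.1`) and a partial-mediation chain
#' (`b1 = 0.162`, `b2 = -0.016`, `direct = -0.0034`).
#'
#' @param n_snps number of cis instruments (default 13).
#' @param theta true causal effect of exposure on outcome.
#' @param gamma_mean,gamma_sd distribution of true instrument effects on
#'   the exposure.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_mean,pleiotropy_sd pleiotropic effect distribution.
#' @param maf_range interval within (0, 0.5].
#' @param n_exposure,n_outcome,n_mediator GWAS sample sizes.
#' @param ld_block_size,ld_block_rho instruments are grouped in blocks of
#'   `ld_block_size` with within-block correlation `ld_block_rho` (the
#'   emitted LD matrix has off-diagonal r-squared `ld_block_rho^2`).
#' @param palindromic_fraction fraction of SNPs assigned A/T or C/G
#'   alleles (count rounded).
#' @param mediator_chain list with `b1`, `b2`, `direct` for
#'   [generate_mediation_chain()]; the implied total is
#'   `b1*b2 + direct`.
#' @param region the synthetic gene region instruments are placed in.
#' @param seed RNG seed; all generation is reproducible from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 13, theta = 0.1,
                       gamma_mean = 0.3, gamma_sd = 0.05,
                       pleiotropy_mode = c("none", "balanced",
                                           "directional"),
                       pleiotropy_mean = 0.005, pleiotropy_sd = 0.002,
                       maf_range = c(0.1, 0.5),
                       n_exposure = 173082, n_outcome = 462933,
                       n_mediator = 66628,
                       ld_block_size = 1, ld_block_rho = 0.3,
                       palindromic_fraction = 3 / 13,
                       mediator_chain = list(b1 = 0.162, b2 = -0.016,
                                             direct = -0.0034),
                       region = gene_region("GENE1", "1", 1000000L,
                                            1025000L, flank_kb = 100),
                       seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, gamma_sd >= 0,
            length(maf_range) == 2, maf_range[1] > 0,
            maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            n_exposure > 0, n_outcome > 0, n_mediator > 0,
            ld_block_size >= 1, ld_block_rho >= 0, ld_block_rho <= 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            pleiotropy_sd >= 0)
  if (!is.null(mediator_chain)) {
    stopifnot(all(c("b1", "b2", "direct") %in% names(mediator_chain)))
  }
  structure(list(n_snps = as.integer(n_snps), theta = theta,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 maf_range = maf_range, n_exposure = n_exposure,
                 n_outcome = n_outcome, n_mediator = n_mediator,
                 ld_block_size = as.integer(ld_block_size),
                 ld_block_rho = ld_block_rho,
                 palindromic_fraction = palindromic_fraction,
                 mediator_chain = mediator_chain, region = region,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Standardized-trait GWAS standard error.
gwas_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

# Draw the shared instrument scaffolding: ids, positions inside the gene
# window, alleles (palindromic first k), maf, true effects.
draw_instruments <- function(cfg, prefix = "snp") {
  J <- cfg$n_snps
  reg <- cfg$region
  lo <- reg$start - reg$flank_kb * 1000
  hi <- reg$end + reg$flank_kb * 1000
  pos <- sort(sample(seq(lo, hi), J))
  k <- round(cfg$palindromic_fraction * J)
  pal_pairs <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)
  nonpal <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                     "G", "A", "C", "A", "G", "T", "C", "T"),
                   ncol = 2, byrow = TRUE)
  ai <- sample(nrow(pal_pairs), k, replace = TRUE)
  bi <- sample(nrow(nonpal), J - k, replace = TRUE)
  alleles <- rbind(pal_pairs[ai, , drop = FALSE],
                   nonpal[bi, , drop = FALSE])
  # palindromic SNPs are scattered, not clustered at the start
  ord <- sample(J)
  alleles <- alleles[ord, , drop = FALSE]
  list(snp_id = sprintf("%s%03d", prefix, seq_len(J)),
       chrom = rep(reg$chrom, J), pos = pos,
       effect_allele = alleles[, 1], other_allele = alleles[, 2],
       maf = stats::runif(J, cfg$maf_range[1], cfg$maf_range[2]),
       gamma = stats::rnorm(J, cfg$gamma_mean, cfg$gamma_sd))
}

pleiotropy_effects <- function(cfg, J) {
  switch(cfg$pleiotropy_mode,
         none = rep(0, J),
         balanced = stats::rnorm(J, 0, cfg$pleiotropy_sd),
         directional = stats::rnorm(J, cfg$pleiotropy_mean,
                                    cfg$pleiotropy_sd))
}

make_dataset <- function(base, beta, se, n, label, type) {
  summary_dataset(data.frame(
    snp_id = base$snp_id, chrom = base$chrom, pos = base$pos,
    effect_allele = base$effect_allele, other_allele = base$other_allele,
    eaf = base$maf, beta = beta, se = se,
    pvalue = 2 * stats::pnorm(-abs(beta / se)), n = n,
    stringsAsFactors = FALSE), trait_label = label, trait_type = type)
}

block_ld <- function(snp_ids, block_size, rho) {
  J <- length(snp_ids)
  r2 <- diag(J)
  if (block_size > 1 && rho > 0) {
    blocks <- split(seq_len(J), ceiling(seq_len(J) / block_size))
    for (b in blocks) r2[b, b] <- rho^2
    diag(r2) <- 1
  }
  ld_matrix(r2, snp_ids)
}

#' Generate a two-sample GWAS summary-statistic pair with known truth
#'
#' Simulates exposure and outcome summary datasets over a shared cis
#' instrument set under the model described in [sim_config()], together
#' with the block LD matrix and the generating truth.  Exposure- and
#' outcome-side noise are independent (two separate cohorts).
#'
#' @param cfg a [sim_config()].
#' @return list with `exposure` and `outcome` ([summary_dataset]s), `ld`
#'   (an [ld_matrix]), and `truth` (class `synthetic_truth`: `theta`,
#'   per-SNP `gamma`, `alpha`, `maf`).
#' @export
generate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_preserved_seed(cfg$seed, {
    base <- draw_instruments(cfg)
    J <- cfg$n_snps
    se_x <- gwas_se(cfg$n_exposure, base$maf)
    se_y <- gwas_se(cfg$n_outcome, base$maf)
    alpha <- pleiotropy_effects(cfg, J)
    bx <- stats::rnorm(J, base$gamma, se_x)
    by <- stats::rnorm(J, cfg$theta * base$gamma + alpha, se_y)
    list(
      exposure = make_dataset(base, bx, se_x, cfg$n_exposure,
                              "exposure", "continuous"),
      outcome = make_dataset(base, by, se_y, cfg$n_outcome,
                             "outcome", "binary"),
      ld = block_ld(base$snp_id, cfg$ld_block_size, cfg$ld_block_rho),
      truth = structure(list(theta = cfg$theta, gamma = base$gamma,
                             alpha = alpha, maf = base$maf),
                        class = "synthetic_truth"))
  })
}

#' Generate a three-trait mediator chain with known leg effects
#'
#' Builds the summary statistics for a two-step mediation study with
#' truth `(b1, b2, direct)` and total effect `b1*b2 + direct`:
#'
#' * `exposure_outcome` — the total-effect pair over the cis instruments
#'   (outcome effects `(b1*b2 + direct) * gamma_j`);
#' * `exposure_mediator` — the first leg over the same cis instruments
#'   (mediator effects `b1 * gamma_j`);
#' * `mediator_outcome` — the second leg over a *separate* set of
#'   instruments for the mediator itself (SNPs associated with the
#'   mediator are the instruments for its effect on the outcome, as in
#'   standard two-step MR practice; reusing the exposure's cis
#'   instruments would contaminate this leg with the direct path).
#'
#' Every pair is harmonizable as-is and each leg carries its own LD
#' matrix.
#'
#' @param cfg a [sim_config()] with `mediator_chain` set.
#' @return list with the three legs (each `exposure`, `outcome`, `ld`)
#'   and `truth` (`b1`, `b2`, `direct`, `total`, `proportion_mediated`
#'   in percent).
#' @export
generate_mediation_chain <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$mediator_chain)) {
    stop("cfg$mediator_chain must be configured", call. = FALSE)
  }
  ch <- cfg$mediator_chain
  total <- ch$b1 * ch$b2 + ch$direct
  with_preserved_seed(cfg$seed, {
    J <- cfg$n_snps
    base <- draw_instruments(cfg, prefix = "snp")
    se_x <- gwas_se(cfg$n_exposure, base$maf)
    se_y <- gwas_se(cfg$n_outcome, base$maf)
    se_m <- gwas_se(cfg$n_mediator, base$maf)
    bx1 <- stats::rnorm(J, base$gamma, se_x)
    bx2 <- stats::rnorm(J, base$gamma, se_x)
    by <- stats::rnorm(J, total * base$gamma, se_y)
    bm <- stats::rnorm(J, ch$b1 * base$gamma, se_m)
    # mediator's own instruments, drawn from the same effect model
    mbase <- draw_instruments(cfg, prefix = "msnp")
    mse_m <- gwas_se(cfg$n_mediator, mbase$maf)
    mse_y <- gwas_se(cfg$n_outcome, mbase$maf)
    mbm <- stats::rnorm(J, mbase$gamma, mse_m)
    mby <- stats::rnorm(J, ch$b2 * mbase$gamma, mse_y)
    list(
      exposure_outcome = list(
        exposure = make_dataset(base, bx1, se_x, cfg$n_exposure,
                                "exposure", "continuous"),
        outcome = make_dataset(base, by, se_y, cfg$n_outcome,
                               "outcome", "binary"),
        ld = block_ld(base$snp_id, cfg$ld_block_size, cfg$ld_block_rho)),
      exposure_mediator = list(
        exposure = make_dataset(base, bx2, se_x, cfg$n_exposure,
                                "exposure", "continuous"),
        outcome = make_dataset(base, bm, se_m, cfg$n_mediator,
                               "mediator", "binary"),
        ld = block_ld(base$snp_id, cfg$ld_block_size, cfg$ld_block_rho)),
      mediator_outcome = list(
        exposure = make_dataset(mbase, mbm, mse_m, cfg$n_mediator,
                                "mediator", "binary"),
        outcome = make_dataset(mbase, mby, mse_y, cfg$n_outcome,
                               "outcome", "binary"),
        ld = block_ld(mbase$snp_id, cfg$ld_block_size, cfg$ld_block_rho)),
      truth = structure(list(b1 = ch$b1, b2 = ch$b2, direct = ch$direct,
                             total = total,
                             proportion_mediated =
                               ch$b1 * ch$b2 / total * 100),
                        class = "synthetic_truth"))
  })
}

#' Write a simulated two-sample study to disk
#'
#' Serialises the exposure/outcome datasets and LD matrix of a
#' [generate_two_sample()] result in the tab-delimited dialect that
#' [read_summary_stats()] and [read_ld_matrix()] read back.
#'
#' @param sim result of [generate_two_sample()] (or one leg of
#'   [generate_mediation_chain()]).
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld.tsv"))
  write_dataset <- function(ds, path) {
    out <- as.data.frame(ds)
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v) sprintf("%.15g", v))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_dataset(sim$exposure, paths[["exposure"]])
  write_dataset(sim$outcome, paths[["outcome"]])
  ldm <- as.data.frame(unclass(sim$ld))
  utils::write.table(cbind(snp_id = rownames(sim$ld), ldm),
                     paths[["ld"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
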