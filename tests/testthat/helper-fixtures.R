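# Programmatic fixtures shared across the test files.

# A minimal well-formed summary table as a data frame.
snp_table <- function(n = 3, chrom = "1", pos = NULL, beta = NULL,
                      se = NULL, pvalue = NULL, prefix = "rs") {
  data.frame(
    snp_id = paste0(prefix, seq_len(n)),
    chrom = chrom,
    pos = if (is.null(pos)) seq(1e6, by = 1000, length.out = n) else pos,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = 0.3,
    beta = if (is.null(beta)) seq(0.1, by = 0.05, length.out = n) else beta,
    se = if (is.null(se)) rep(0.01, n) else se,
    pvalue = if (is.null(pvalue)) rep(1e-10, n) else pvalue,
    n = 10000L,
    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# A 13-instrument exposure set containing the three named palindromic
# SNPs, plus a matching outcome dataset with identical alleles; mirrors
# the instrument accounting of the motivating study.
fixture_13_instruments <- function() {
  pal <- c("rs12067569", "rs11591147", "rs11583974")
  ids <- c(paste0("rs", 1:10), pal)
  ea <- c(rep(c("A", "C", "G", "T", "A"), 2), "A", "C", "T")
  oa <- c(rep(c("G", "T", "A", "C", "C"), 2), "T", "G", "A")
  exposure <- summary_dataset(data.frame(
    snp_id = ids, chrom = "1", pos = seq(1e6, by = 5000, length.out = 13),
    effect_allele = ea, other_allele = oa, eaf = 0.3,
    beta = seq(0.2, 0.44, length.out = 13), se = 0.01, pvalue = 1e-12,
    n = 173082, stringsAsFactors = FALSE),
    trait_label = "LDL-C", trait_type = "continuous")
  outcome <- summary_dataset(data.frame(
    snp_id = ids, chrom = "1", pos = seq(1e6, by = 5000, length.out = 13),
    effect_allele = ea, other_allele = oa, eaf = 0.3,
    beta = -0.01 * seq_len(13) / 13, se = 0.004, pvalue = 0.01,
    n = 462933, stringsAsFactors = FALSE),
    trait_label = "osteoporosis", trait_type = "binary")
  list(exposure = exposure, outcome = outcome, palindromic = pal)
}

# Hand-built wald_ratios object from explicit per-SNP values, bypassing
# harmonization (for estimator unit tests).
ratios_fixture <- function(ratio, ratio_se, beta_exposure = NULL,
                           beta_outcome = NULL, se_outcome = NULL) {
  J <- length(ratio)
  if (is.null(beta_exposure)) beta_exposure <- rep(1, J)
  if (is.null(beta_outcome)) beta_outcome <- ratio * beta_exposure
  if (is.null(se_outcome)) se_outcome <- ratio_se * abs(beta_exposure)
  structure(data.frame(
    snp_id = paste0("s", seq_len(J)), ratio = ratio, ratio_se = ratio_se,
    beta_exposure = beta_exposure, se_exposure = 0.01,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    weight = 1 / ratio_se^2, stringsAsFactors = FALSE),
    class = c("wald_ratios", "data.frame"))
}

# Harmonized set built directly from effect pairs.
harmonized_fixture <- function(beta_exposure, se_exposure, beta_outcome,
                               se_outcome) {
  J <- length(beta_exposure)
  structure(list(
    pairs = data.frame(
      snp_id = paste0("s", seq_len(J)),
      effect_allele = "A", other_allele = "G",
      beta_exposure = beta_exposure, se_exposure = se_exposure,
      beta_outcome = beta_outcome, se_outcome = se_outcome,
      pvalue_exposure = 1e-10, pvalue_outcome = 0.01,
      stringsAsFactors = FALSE),
    removal_log = data.frame(snp_id = paste0("s", seq_len(J)),
                             status = "kept", stringsAsFactors = FALSE),
    exposure_label = "exposure", outcome_label = "outcome",
    orientation = "as_is"), class = "harmonized_set")
}

# Builds a complete on-disk synthetic study (exposure, outcome, positive
# control, one mediator, LD, YAML config) and returns the config path.
write_study_fixture <- function(dir, seed = 31, control_theta = 0.3,
                                mediator_chain = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (is.null(mediator_chain)) sim_config(seed = seed)
         else sim_config(seed = seed, mediator_chain = mediator_chain)
  chain <- generate_mediation_chain(cfg)
  xo <- chain$exposure_outcome
  # positive control shares the exposure instruments with a strong signal
  set.seed(seed + 1)
  ctrl <- xo$exposure
  se_c <- 1 / sqrt(2 * 184305 * ctrl$eaf * (1 - ctrl$eaf))
  ctrl_beta <- stats::rnorm(nrow(ctrl), control_theta * ctrl$beta, se_c)
  control <- summary_dataset(data.frame(
    snp_id = ctrl$snp_id, chrom = ctrl$chrom, pos = ctrl$pos,
    effect_allele = ctrl$effect_allele, other_allele = ctrl$other_allele,
    eaf = ctrl$eaf, beta = ctrl_beta, se = se_c,
    pvalue = 2 * stats::pnorm(-abs(ctrl_beta / se_c)), n = 184305),
    trait_label = "CHD", trait_type = "binary")
  paths <- write_simulation(xo, dir)
  # genome-wide outcome GWAS: covers the cis instruments and the
  # mediator's own instruments
  outcome_all <- rbind(as.data.frame(xo$outcome),
                       as.data.frame(chain$mediator_outcome$outcome))
  utils::write.table(outcome_all, paths[["outcome"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ctrl_path <- file.path(dir, "control.tsv")
  utils::write.table(as.data.frame(control), ctrl_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # the mediator GWAS must cover both the cis instruments (first leg)
  # and its own instruments (second leg): concatenate the two tables
  med_all <- rbind(as.data.frame(chain$exposure_mediator$outcome),
                   as.data.frame(chain$mediator_outcome$exposure))
  med_path <- file.path(dir, "mediator.tsv")
  utils::write.table(med_all, med_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  config <- list(
    exposure = list(path = paths[["exposure"]], label = "exposure"),
    outcome = list(path = paths[["outcome"]], label = "outcome",
                   trait_type = "binary"),
    positive_control = list(path = ctrl_path, label = "CHD",
                            trait_type = "binary"),
    ld_matrix = list(path = paths[["ld"]]),
    gene_region = list(gene_name = "GENE1", chrom = "1",
                       start = 1000000, end = 1025000, flank_kb = 100),
    mediators = list(list(label = "mediator", path = med_path)),
    thresholds = list(p_instrument = 5e-8, r2 = 0.3, alpha = 0.05),
    methods = list(n_boot = 100, seed = seed))
  cfg_path <- file.path(dir, "study.yaml")
  yaml::write_yaml(config, cfg_path)
  list(config = cfg_path, truth = chain$truth)
}
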