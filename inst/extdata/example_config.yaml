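# Example study configuration for targetmr::run_study().
#
# Paths are resolved relative to the working directory at run time; all
# referenced files must exist before the run starts.  Generate a fully
# synthetic study to try the pipeline (see the package README), or point
# the blocks at your own GWAS summary-statistic exports.

# Exposure GWAS (the trait the drug target modulates, e.g. LDL-C).
exposure:
  path: data/exposure.tsv
  label: LDL-C
  trait_type: continuous
  # column_map translates your file's column names onto the canonical
  # fields; omit it when the file already uses the canonical names
  # (snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
  # pvalue, n).
  column_map:
    snp_id: SNP
    chrom: CHR
    pos: BP
    effect_allele: EA
    other_allele: OA
    eaf: EAF
    beta: BETA
    se: SE
    pvalue: P
    n: N

# Outcome GWAS (binary effects on the log-odds scale).
outcome:
  path: data/outcome.tsv
  label: osteoporosis
  trait_type: binary

# Positive control: an outcome with established causality for the same
# exposure; the study proceeds only if its IVW p-value < alpha.
positive_control:
  path: data/chd.tsv
  label: CHD
  trait_type: binary

# Pairwise squared LD correlations for the candidate instruments
# (square table, header row and leading column of SNP ids).
ld_matrix:
  path: data/ld.tsv

# The drug-target gene span; instruments are restricted to
# [start - flank_kb*1000, end + flank_kb*1000] on this chromosome.
gene_region:
  gene_name: PCSK9
  chrom: "1"
  start: 55505221
  end: 55530525
  flank_kb: 100

# Candidate mediators: each mediator GWAS is used as the outcome of the
# exposure->mediator leg and as the exposure of the mediator->outcome
# leg (with its own genome-wide significant instruments, excluding the
# drug-target cis SNPs).  An optional per-mediator ld_matrix enables
# clumping of the mediator instruments.
mediators:
  - label: total-body BMD (45-60y)
    path: data/bmd_45_60.tsv
  - label: T25(OH)D
    path: data/vitd.tsv

# Selection and testing thresholds (these are the defaults).
thresholds:
  p_instrument: 5.0e-8   # genome-wide significance, strict <
  r2: 0.3                # LD clumping threshold, drop at r2 >= 0.3
  alpha: 0.05            # significance level used by every gate

# Estimator settings.
methods:
  n_boot: 1000           # bootstrap replicates for median/mode SEs
  seed: 1                # seed for all stochastic steps
  bandwidth_factor: 1    # multiplier on the modified-Silverman bandwidth
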