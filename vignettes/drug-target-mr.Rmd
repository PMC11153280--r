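---
title: "Drug-target Mendelian randomization with two-step mediation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with two-step mediation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The problem

Drug-target Mendelian randomization (MR) asks whether pharmacological
modulation of a protein would change a disease outcome, using only GWAS
summary statistics. Variants in or near the gene encoding the drug's
target (for example *PCSK9* for PCSK9 inhibitors) shift the drug's
biomarker (LDL-C) the way the drug does; if those same variants also
shift the outcome (osteoporosis risk), and the usual instrumental-variable
assumptions hold, the ratio of the two effects estimates the causal
effect of target modulation. Two-step MR mediation then decomposes that
total effect into a path through a candidate mediator (bone mineral
density, vitamin D status) and a direct remainder.

`targetmr` implements the full workflow: cis instrument selection,
two-sample harmonization, four complementary causal estimators with
diagnostics, the study-level decision rules (positive control, effects
model, direction concordance), and the gated product-of-coefficients
mediation — plus a synthetic GWAS generator with known truth so that every
stage is testable without external data.

## Model and estimators

For instrument $j$, let $\hat\beta_{Xj}, \sigma_{Xj}$ be its estimated
effect and standard error on the exposure and
$\hat\beta_{Yj}, \sigma_{Yj}$ on the outcome, measured in two
non-overlapping samples. The per-SNP Wald ratio is
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order standard
error $\sigma_{Yj}/|\hat\beta_{Xj}|$ and weight
$w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$. The estimators are:

* **IVW**: $\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$, identical
  to weighted least squares of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
  through the origin. Fixed-effect SE $(\sum_j w_j)^{-1/2}$;
  multiplicative random effects inflate it by
  $\sqrt{\max(1, Q/(J-1))}$.
* **MR-Egger**: weighted regression with a free intercept, weights
  $1/\sigma_{Yj}^2$, after orienting every instrument to
  $\hat\beta_{Xj} \ge 0$ (required for identification; the flip count is
  recorded). The slope estimates the causal effect under the InSIDE
  assumption; the intercept estimates the average directional
  pleiotropy. Inference uses the $t$ distribution on $J-2$ df.
* **Weighted median**: the interpolated weighted median of the
  $\hat\theta_j$ (cumulative weight midpoints
  $p_j = \sum_{k\le j} w'_k - w'_j/2$, linear interpolation at $1/2$),
  consistent when at least half the weight is valid.
* **Weighted mode**: the maximizer of a weighted gaussian kernel density
  over the $\hat\theta_j$, bandwidth
  $h = c \cdot 0.9\,\min(\mathrm{sd}, \mathrm{mad})\,J^{-1/5}$
  (normalized MAD; `bandwidth_factor` $c$ defaults to 1), consistent
  when the largest cluster is valid.

Median and mode SEs come from a seeded parametric bootstrap (each ratio
resampled from a normal with its first-order SE, default `n_boot = 1000`);
results are bit-reproducible given `(n_boot, seed)` and the caller's RNG
stream is left untouched.

First-order Wald weights ignore exposure-side sampling noise. For strong
cis instruments this is negligible — the neglected term inflates the true
ratio variance by roughly
$1 + \theta^2\sigma_X^2/\sigma_Y^2$, about 2–3% under this package's
default simulation — but it is the reason fixed-effect IVW coverage sits
slightly below the nominal 95% (the test suite checks it stays within
[0.92, 0.97]).

## Diagnostics and decision rules

* **Cochran's Q** on the ratios (df $J-1$) or on the Egger residuals
  (df $J-2$), with $I^2 = \max(0, (Q-\mathrm{df})/Q)\times 100$
  truncated at zero as in standard meta-analysis. A single instrument
  reports $Q=0$ on 0 df with an undefined (`NA`) p-value, not 1.
* **Effects-model rule**: heterogeneity $p < \alpha$ selects
  multiplicative random-effects IVW, otherwise fixed ($\alpha = 0.05$
  everywhere, configurable once; comparisons with $\alpha$ are strict).
* **Egger intercept test** for directional pleiotropy, $t$ on $J-2$ df.
* **Leave-one-out**: IVW recomputed dropping each SNP; the result is
  flagged robust when every reduced estimate keeps the same sign.
* **Positive control**: the pipeline first runs the same instruments
  against an outcome with established causality and proceeds only when
  its IVW $p < \alpha$ (an override flag exists and is logged).
* **Concordance**: a causal claim requires IVW significance plus every
  other method's beta sharing the IVW sign; the supporting methods need
  not be individually significant.

## Mediation

With total effect $b$ (exposure→outcome), first leg $b_1$
(exposure→mediator) and second leg $b_2$ (mediator→outcome), the mediated
effect is $b_1 b_2$, the direct effect $b - b_1 b_2$, and — only when the
mediated and total effects share a sign — the proportion mediated
$b_1 b_2 / b$. Every leg must pass the prerequisite gate
($P_{IVW} < \alpha$); a failing leg suppresses the decomposition with a
reason naming the leg (an explicit `force` flag computes it anyway,
marked exploratory).

Two reporting paths exist by design. The exact path (default) conserves
$b$ to machine precision. The rounded path (`rounding = 4`) rounds the
product to four decimals *before* deriving the direct effect and
proportion — this is how tables that print rounded betas arrive at
figures like a 43.33% proportion from $b_1 b_2 = -0.0026$ and
$b = -0.006$, and the package reproduces that arithmetic exactly. A
delta-method SE for the mediated effect,
$\sqrt{b_2^2\sigma_{b_1}^2 + b_1^2\sigma_{b_2}^2}$, is reported whenever
both leg SEs are available; it is an extension beyond the usual printed
tables and is flagged as such. Leg SEs may be absent (`NA`) because
published mediation tables often print only betas and p-values.

The mediator→outcome leg uses the mediator's *own* genome-wide
significant instruments, and the pipeline explicitly excludes the
exposure's cis SNPs from that pool: a cis SNP acts on the outcome
through the exposure's direct path as well, so keeping it would
contaminate $b_2$ with $\mathrm{direct}/b_1$. This mirrors standard
two-step MR practice of instrumenting each leg with SNPs associated
with its own exposure.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `generate_two_sample()` and
`generate_mediation_chain()` draw from them reproducibly. Per SNP:
$\mathrm{maf}_j \sim U(0.1, 0.5)$,
true exposure effect $\gamma_j \sim N(0.3, 0.05^2)$, standard errors
from the standardized-trait model $1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$,
observed effects normal around $\gamma_j$ (exposure side) and
$\theta\gamma_j + \alpha_j$ (outcome side) with independent noise — the
two-sample assumption. Pleiotropic effects $\alpha_j$ are zero,
balanced ($N(0, sd^2)$) or directional ($N(\mathrm{mean}, sd^2)$).

Default choices, made once:

* **13 instruments, 3/13 palindromic** — the instrument accounting of a
  typical cis drug-target analysis, so harmonization exercises the
  palindrome drop en route to 10 usable pairs.
* **Sample sizes 173,082 / 462,933 / 66,628** (exposure / outcome /
  mediator) — large-biobank scale, which puts per-SNP standard errors in
  the few-per-thousand range that real lipid and osteoporosis GWAS show.
* **$\gamma$ around 0.3** — cis variants at a drug-target locus are
  selected for large biomarker effects (the strongest *PCSK9* LDL
  variants reach 0.3–0.5 SD); this keeps instruments far above the
  $5\times10^{-8}$ threshold and makes weak-instrument bias negligible.
* **$\theta = 0.1$** — a modest log-odds effect, small enough that the
  first-order-weight approximation stays accurate (see above).
* **Pleiotropy sd 0.002** — the same order as the outcome-side SE, so
  balanced pleiotropy produces detectable but not overwhelming
  heterogeneity.
* **Mediator chain $b_1 = 0.162$, $b_2 = -0.016$, direct $= -0.0034$** —
  a realistic partial-mediation configuration whose implied total
  ($\approx -0.006$) and proportion mediated ($\approx 43\%$) sit at the
  scale the mediation module is designed to resolve.
* Instruments are placed inside a synthetic gene ± flank window, and the
  emitted LD matrix is block-diagonal with off-diagonal
  $r^2 = \rho^2$ (blocks of size 1 by default, so clumping is exercised
  by tests that set larger blocks).

What the generator does **not** emulate: realistic LD from reference
panels (blocks are exchangeable and flat), winner's curse in instrument
discovery, sample overlap between the two GWAS, allele-frequency
mismatch between cohorts, population stratification, and the upstream
continuous-to-binary phenotype recoding that happens at the genotype
level before summary statistics exist. Passing tests therefore
demonstrate correctness of the estimators and decision logic under the
stated model, not robustness to those real-data complications.

## Numerical choices

* Clumping ties in p-value break by ascending position then lexicographic
  SNP id, making selection deterministic and order-invariant.
* Window and threshold comparisons follow the conventions stated above:
  keep at $p <$ threshold (strict), drop at $r^2 \ge$ threshold, window
  inclusive at both ends.
* The Egger fit snaps residuals to zero when they are pure rounding noise
  (max residual $\le 10^{-10}$ of the response scale), so an exactly
  linear configuration reports $p = 1$ for a zero intercept rather than
  a ratio of rounding errors; a zero SE with a nonzero estimate reports
  $p = 0$.
* The weighted-mode maximizer is located on a 512-point grid and refined
  by golden-section search; identical ratios short-circuit to the common
  value with SE 0 (zero bandwidth), and a zero MAD with positive SD
  falls back to the SD in the bandwidth rule.
* Missing optional fields (`eaf`, `n`, leg SEs) are explicit `NA`
  markers, never 0.
* Checking that Q is chi-square distributed uses $\theta = 0$: with a
  nonzero causal effect the first-order SE understates the ratio
  variance by the factor given earlier and Q is correspondingly
  inflated, while at $\theta = 0$ the standardized ratios are exactly
  standard normal. This is a property of first-order weights, not of the
  implementation.

## Validation problem sizes

The test suite validates calibration by simulation at sizes chosen to
balance Monte-Carlo resolution against a quick default run: 1,000
replicates for fixed-effect IVW coverage, 2,000 for the chi-square
distribution of Q, 500 for end-to-end mediation-chain recovery (each leg
within 2 Monte-Carlo SEs, pooled proportion mediated within 2 delta-method
Monte-Carlo SEs and within 10 percentage points), 200 for Egger-intercept
recovery under directional pleiotropy, and 400 for its type-I calibration
under balanced pleiotropy. Oracle-equivalence checks (IVW vs weighted
least squares through the origin, Egger vs closed-form normal equations,
weighted median vs interpolation) run on 50–100 random instances at
$10^{-10}$ tolerance.

## Known limitations

* Only the drop-all-palindromes policy is implemented; frequency-based
  strand inference is out of scope. Opposite-strand allele matching
  exists behind `strand_flip = TRUE` but is off by default — silent
  complement matching can mask real mismatches.
* Effect-direction conventions differ between published exposures
  (per-unit biomarker increase vs per-unit drug-style lowering); the
  package never guesses, exposing `orient = "lowering"` to negate the
  exposure side explicitly.
* The LD matrix is an input; the package does not compute LD from
  genotypes or manage reference panels.
* No MR-PRESSO outlier correction, Steiger filtering, multivariable MR,
  or confidence intervals for the proportion mediated (the delta-method
  SE applies to the mediated effect only).
* Positions are treated as build-agnostic integers; no liftover.
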