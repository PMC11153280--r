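#' Palindromic allele test
#'
#' A SNP is palindromic when its two alleles are complementary — the
#' unordered pair is {A,T} or {C,G} — so the strand cannot be resolved
#' from the alleles alone.  Such SNPs are removed during harmonization.
#'
#' @param effect_allele,other_allele single bases in `{A,C,G,T}`
#'   (vectorised).
#' @return logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele); b <- toupper(other_allele)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

complement_allele <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[toupper(a)]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns each exposure instrument with the same SNP in the outcome
#' dataset on a common effect-allele orientation.  For every exposure
#' SNP, in order:
#'
#' * absent from the outcome — dropped (`dropped:absent_in_outcome`);
#' * palindromic (A/T or C/G) — dropped (`dropped:palindromic`; the only
#'   implemented policy, matching the conservative drop-all convention);
#' * outcome alleles identical in the same orientation — outcome effect
#'   copied as is;
#' * outcome alleles identical but swapped — outcome beta negated and its
#'   alleles swapped to the exposure orientation;
#' * with `strand_flip = TRUE`, an outcome record whose alleles match
#'   only after complementing both (opposite-strand report) is treated as
#'   the same SNP, then oriented as above.  Off by default, in which case
#'   complement-only matches are dropped as `dropped:allele_mismatch`;
#' * any other allele pair — dropped (`dropped:allele_mismatch`).
#'
#' The removal log accounts for every input instrument exactly once.
#' Exposure orientation is preserved as is; `orient = "lowering"` negates
#' every exposure beta so effects are expressed per unit of exposure
#' *lowering* (drug mimicry for an inhibitor).  The orientation is an
#' explicit choice, never inferred.
#'
#' @param exposure an `instrument_set` (from [select_instruments()] /
#'   [ld_clump()]) or a [summary_dataset] of exposure-side records.
#' @param outcome a [summary_dataset].
#' @param palindrome_policy only `"drop"` is supported.
#' @param strand_flip resolve opposite-strand reports by allele
#'   complement (default `FALSE`).
#' @param orient `"as_is"` (default) or `"lowering"`.
#' @return a `harmonized_set`: list with `pairs` (data frame of aligned
#'   effect pairs), `removal_log`, and the two trait labels.
#' @export
harmonize <- function(exposure, outcome, palindrome_policy = "drop",
                      strand_flip = FALSE,
                      orient = c("as_is", "lowering")) {
  orient <- match.arg(orient)
  palindrome_policy <- match.arg(palindrome_policy, "drop")
  if (inherits(exposure, "instrument_set")) exposure <- exposure$records
  stopifnot(is_summary_dataset(exposure), is_summary_dataset(outcome))
  m <- match(exposure$snp_id, outcome$snp_id)
  n <- nrow(exposure)
  status <- rep("kept", n)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    ea <- exposure$effect_allele[i]; oa <- exposure$other_allele[i]
    if (is.na(m[i])) {
      status[i] <- "dropped:absent_in_outcome"
      next
    }
    if (is_palindromic(ea, oa)) {
      status[i] <- "dropped:palindromic"
      next
    }
    j <- m[i]
    oea <- outcome$effect_allele[j]; ooa <- outcome$other_allele[j]
    flip <- NA  # FALSE: same orientation; TRUE: swapped
    if (oea == ea && ooa == oa) {
      flip <- FALSE
    } else if (oea == oa && ooa == ea) {
      flip <- TRUE
    } else if (strand_flip) {
      cea <- complement_allele(oea); coa <- complement_allele(ooa)
      if (cea == ea && coa == oa) flip <- FALSE
      else if (cea == oa && coa == ea) flip <- TRUE
    }
    if (is.na(flip)) {
      status[i] <- "dropped:allele_mismatch"
      next
    }
    pairs[[i]] <- data.frame(
      snp_id = exposure$snp_id[i],
      effect_allele = ea, other_allele = oa,
      beta_exposure = exposure$beta[i], se_exposure = exposure$se[i],
      beta_outcome = if (flip) -outcome$beta[j] else outcome$beta[j],
      se_outcome = outcome$se[j],
      pvalue_exposure = exposure$pvalue[i],
      pvalue_outcome = outcome$pvalue[j],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- data.frame(snp_id = character(0), effect_allele = character(0),
                        other_allele = character(0),
                        beta_exposure = numeric(0), se_exposure = numeric(0),
                        beta_outcome = numeric(0), se_outcome = numeric(0),
                        pvalue_exposure = numeric(0),
                        pvalue_outcome = numeric(0),
                        stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  if (orient == "lowering") pairs$beta_exposure <- -pairs$beta_exposure
  structure(list(
    pairs = pairs,
    removal_log = data.frame(snp_id = exposure$snp_id, status = status,
                             stringsAsFactors = FALSE),
    exposure_label = attr(exposure, "trait_label"),
    outcome_label = attr(outcome, "trait_label"),
    orientation = orient),
    class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("harmonized set: %s -> %s, %d pairs kept of %d instruments\n",
              x$exposure_label, x$outcome_label, nrow(x$pairs),
              nrow(x$removal_log)))
  drops <- x$removal_log$status[x$removal_log$status != "kept"]
  if (length(drops)) {
    tab <- table(drops)
    for (nm in names(tab)) cat(sprintf("  %-28s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' Write the harmonization removal log
#'
#' Serialises the per-SNP disposition table (kept / dropped with reason)
#' as a tab-delimited audit file.
#'
#' @param h a `harmonized_set`.
#' @param path output file path.
#' @export
write_removal_log <- function(h, path) {
  stopifnot(inherits(h, "harmonized_set"))
  utils::write.table(h$removal_log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(h$removal_log)
}
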