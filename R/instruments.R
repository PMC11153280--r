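#' Genome-wide significance filter
#'
#' Keeps the records whose exposure p-value is strictly below the
#' threshold (default 5e-8, the conventional genome-wide significance
#' level).  Record order is preserved; an empty result is legal.
#'
#' @param dataset a [summary_dataset].
#' @param p_threshold significance threshold in (0, 1]; kept records
#'   satisfy `pvalue < p_threshold` (strict).
#' @return a [summary_dataset] with the significant records.
#' @export
filter_significant <- function(dataset, p_threshold = 5e-8) {
  stopifnot(is_summary_dataset(dataset))
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must lie in (0, 1]", call. = FALSE)
  }
  ds_subset(dataset, dataset$pvalue < p_threshold)
}

#' Restrict to a cis gene window
#'
#' Keeps the records on the region's chromosome with position inside
#' `[start - flank_kb*1000, end + flank_kb*1000]`, both ends inclusive —
#' the flank is applied to the gene's genomic span, not to individual
#' index SNPs.
#'
#' @param dataset a [summary_dataset].
#' @param region a [gene_region].
#' @return a [summary_dataset] with the cis records.
#' @export
restrict_to_region <- function(dataset, region) {
  stopifnot(is_summary_dataset(dataset), inherits(region, "gene_region"))
  lo <- region$start - region$flank_kb * 1000
  hi <- region$end + region$flank_kb * 1000
  keep <- dataset$chrom == region$chrom &
    dataset$pos >= lo & dataset$pos <= hi
  ds_subset(dataset, keep)
}

#' Greedy LD clumping
#'
#' Prunes instruments so that no kept pair has squared LD correlation at
#' or above `r2_threshold`.  The algorithm is the standard greedy one:
#' sort by ascending p-value (ties broken by ascending position, then
#' lexicographic SNP id, so the result is invariant to input order),
#' repeatedly keep the best remaining SNP and drop every remaining SNP in
#' LD with it.  Each drop records the kept SNP responsible
#' (`dropped:ld_with:<snp_id>`) in the selection log.
#'
#' @param dataset a [summary_dataset]; every `snp_id` must be present in
#'   `ld`.
#' @param ld an [ld_matrix].
#' @param r2_threshold drop threshold in (0, 1]; pairs with
#'   `r2 >= r2_threshold` conflict (the paper-style rule keeps pairs with
#'   r-squared strictly below it).
#' @return an `instrument_set`: list with `records` (a [summary_dataset],
#'   original order) and `selection_log` (data frame of per-SNP
#'   dispositions).
#' @export
ld_clump <- function(dataset, ld, r2_threshold = 0.3) {
  stopifnot(is_summary_dataset(dataset), inherits(ld, "ld_matrix"))
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must lie in (0, 1]", call. = FALSE)
  }
  absent <- setdiff(dataset$snp_id, rownames(ld))
  if (length(absent)) {
    stop("SNP(s) absent from the LD matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ids <- dataset$snp_id
  ord <- order(dataset$pvalue, dataset$pos, dataset$snp_id)
  status <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (i in ord) {
    id <- ids[i]
    if (!is.na(status[[id]])) next
    status[[id]] <- "kept"
    r2row <- ld[id, ids]
    conflict <- ids[r2row >= r2_threshold & ids != id]
    conflict <- conflict[is.na(status[conflict])]
    status[conflict] <- paste0("dropped:ld_with:", id)
  }
  new_instrument_set(dataset,
                     data.frame(snp_id = ids, status = unname(status[ids]),
                                stringsAsFactors = FALSE))
}

new_instrument_set <- function(dataset, selection_log) {
  kept <- selection_log$snp_id[selection_log$status == "kept"]
  structure(list(records = ds_subset(dataset, dataset$snp_id %in% kept),
                 selection_log = selection_log),
            class = "instrument_set")
}

#' Select cis instruments for a drug target
#'
#' The full instrument-selection stage in one call: genome-wide
#' significance filter, restriction to the gene window, then greedy LD
#' clumping.  The selection log accounts for every input SNP exactly once
#' with its disposition: `kept`, `dropped:p_threshold`,
#' `dropped:outside_window`, or `dropped:ld_with:<snp_id>`.
#'
#' @inheritParams ld_clump
#' @inheritParams filter_significant
#' @param region optional [gene_region]; when `NULL` no window
#'   restriction is applied.
#' @param ld optional [ld_matrix]; when `NULL` no clumping is applied.
#' @return an `instrument_set`.
#' @export
select_instruments <- function(dataset, region = NULL, ld = NULL,
                               p_threshold = 5e-8, r2_threshold = 0.3) {
  stopifnot(is_summary_dataset(dataset))
  log <- data.frame(snp_id = dataset$snp_id,
                    status = NA_character_, stringsAsFactors = FALSE)
  sig <- filter_significant(dataset, p_threshold)
  log$status[!(log$snp_id %in% sig$snp_id)] <- "dropped:p_threshold"
  current <- sig
  if (!is.null(region)) {
    cis <- restrict_to_region(current, region)
    log$status[is.na(log$status) &
                 !(log$snp_id %in% cis$snp_id)] <- "dropped:outside_window"
    current <- cis
  }
  if (!is.null(ld) && nrow(current) > 0L) {
    clumped <- ld_clump(current, ld, r2_threshold)
    m <- match(clumped$selection_log$snp_id, log$snp_id)
    log$status[m] <- clumped$selection_log$status
  } else {
    log$status[is.na(log$status)] <- "kept"
  }
  new_instrument_set(dataset, log)
}

#' @export
print.instrument_set <- function(x, ...) {
  n_kept <- sum(x$selection_log$status == "kept")
  cat(sprintf("instrument set: %d kept of %d candidate SNPs\n",
              n_kept, nrow(x$selection_log)))
  drops <- table(sub(":rs.*$|:snp.*$", "", x$selection_log$status))
  for (nm in names(drops)) cat(sprintf("  %-24s %d\n", nm, drops[[nm]]))
  invisible(x)
}
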