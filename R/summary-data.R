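#' GWAS summary-statistic datasets
#'
#' A `summary_dataset` is a validated data frame of per-SNP GWAS summary
#' records — one trait's identifier, location, alleles, effect estimate and
#' precision — and is the raw material for every downstream stage
#' (instrument selection, harmonization, estimation).
#'
#' Required columns: `snp_id`, `chrom`, `pos` (1-based base pairs),
#' `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`.  Optional:
#' `eaf` (effect-allele frequency) and `n` (sample size); when absent they
#' are stored as `NA`, never as 0.  Alleles are uppercased on construction
#' and must be single bases in `{A,C,G,T}` (the design targets SNPs only;
#' indels are rejected).  Coordinates are 1-based inclusive throughout the
#' package and are never converted silently.
#'
#' @param x a data frame with the columns above.
#' @param trait_label short human-readable trait name.
#' @param trait_type `"continuous"` or `"binary"` (binary effects are on
#'   the log-odds scale).
#'
#' @return An object of class `summary_dataset` (a data frame with
#'   `trait_label` and `trait_type` attributes).  Construction fails if
#'   any row violates the record invariants; use [read_summary_stats()]
#'   for file input with row-level error collection.
#' @seealso [read_summary_stats()], [select_instruments()], [harmonize()]
#' @export
summary_dataset <- function(x, trait_label = "trait",
                            trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pvalue")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("summary dataset is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(x$eaf)) x$eaf <- NA_real_
  if (is.null(x$n)) x$n <- NA_real_
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("pos", "beta", "se", "pvalue", "eaf", "n")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  errs <- validate_summary_records(x)
  if (length(errs)) {
    stop("invalid summary records:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  dup <- unique(x$snp_id[duplicated(x$snp_id)])
  if (length(dup)) {
    stop("duplicated snp_id in dataset: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  x <- x[c(required, "eaf", "n")]
  rownames(x) <- NULL
  structure(x,
            trait_label = trait_label,
            trait_type = trait_type,
            class = c("summary_dataset", "data.frame"))
}

#' @rdname summary_dataset
#' @export
is_summary_dataset <- function(x) inherits(x, "summary_dataset")

# Per-row invariant checks; returns a character vector of messages, one per
# offending row, each prefixed with the row index within `x`.
validate_summary_records <- function(x) {
  bases <- c("A", "C", "G", "T")
  msg <- character(0)
  bad <- function(cond, what) {
    i <- which(cond %in% TRUE)
    if (length(i)) sprintf("row %d: %s", i, what) else character(0)
  }
  msg <- c(msg,
    bad(is.na(x$snp_id) | !nzchar(x$snp_id), "empty snp_id"),
    bad(!(x$effect_allele %in% bases), "effect_allele not in {A,C,G,T}"),
    bad(!(x$other_allele %in% bases), "other_allele not in {A,C,G,T}"),
    bad(x$effect_allele == x$other_allele, "effect_allele equals other_allele"),
    bad(is.na(x$pos) | x$pos < 1, "pos must be >= 1"),
    bad(is.na(x$beta), "beta missing or non-numeric"),
    bad(is.na(x$se) | x$se <= 0, "se must be > 0"),
    bad(is.na(x$pvalue) | x$pvalue < 0 | x$pvalue > 1,
        "pvalue must be in [0, 1]"),
    bad(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf must be in [0, 1]"),
    bad(!is.na(x$n) & x$n <= 0, "n must be positive"))
  sort(msg)
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("GWAS summary dataset '%s' (%s): %d SNPs\n",
              attr(x, "trait_label"), attr(x, "trait_type"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

trait_label <- function(x) attr(x, "trait_label")

# Row subset that preserves the summary_dataset class and attributes.
ds_subset <- function(ds, idx) {
  out <- as.data.frame(ds)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_label = attr(ds, "trait_label"),
            trait_type = attr(ds, "trait_type"),
            class = c("summary_dataset", "data.frame"))
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited table with a header (the delimiter is
#' auto-detected from the header line, ties broken in favour of tab) and
#' maps source columns onto the canonical record fields via `column_map`.
#' Rows violating the record invariants (non-positive SE, p-value outside
#' \[0,1\], indel alleles, ...) are rejected individually; their file line
#' numbers and reasons are reported in a warning and attached as the
#' `"rejected"` attribute.  A duplicated `snp_id` among the surviving rows
#' is a dataset-level error.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical field names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `pvalue`, and optionally `eaf`, `n`) to the source column
#'   names.  Defaults to the canonical names themselves.
#' @inheritParams summary_dataset
#' @return a [summary_dataset].
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_label = "trait",
                               trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- detect_delimiter(header)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  fields <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
              "beta", "se", "pvalue", "eaf", "n")
  if (is.null(column_map)) {
    column_map <- stats::setNames(fields, fields)
  }
  mandatory <- setdiff(fields, c("eaf", "n"))
  need <- intersect(names(column_map), fields)
  map <- column_map[need]
  absent <- setdiff(mandatory, names(map))
  if (length(absent)) {
    stop("column_map does not name source columns for: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  missing_src <- map[!(map %in% names(raw))]
  if (any(names(missing_src) %in% mandatory)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_src[names(missing_src) %in% mandatory],
               collapse = ", "), call. = FALSE)
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in fields) {
    df[[f]] <- if (f %in% names(map) && map[[f]] %in% names(raw)) {
      raw[[map[[f]]]]
    } else NA_character_
  }
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  numeric_fields <- c("pos", "beta", "se", "pvalue", "eaf", "n")
  parse_errs <- character(0)
  for (f in numeric_fields) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(!is.na(df[[f]]) & nzchar(trimws(df[[f]])) & is.na(v))
    if (length(bad) && !(f %in% c("eaf", "n"))) {
      parse_errs <- c(parse_errs,
                      sprintf("row %d: unparseable %s '%s'", bad, f, df[[f]][bad]))
    }
    df[[f]] <- v
  }
  inv_errs <- validate_summary_records(df)
  all_errs <- c(parse_errs, inv_errs)
  bad_rows <- unique(as.integer(sub("^row (\\d+):.*$", "\\1", all_errs)))
  if (length(bad_rows)) {
    # +1 converts data row index to file line number (header is line 1)
    lines <- sprintf("line %d: %s", bad_rows + 1L,
                     vapply(bad_rows, function(i) {
                       paste(sub("^row \\d+: ", "",
                                 grep(sprintf("^row %d:", i), all_errs,
                                      value = TRUE)),
                             collapse = "; ")
                     }, character(1)))
    warning(sprintf("rejected %d row(s) of %s:\n  %s", length(bad_rows),
                    basename(path), paste(lines, collapse = "\n  ")),
            call. = FALSE)
    df <- df[-bad_rows, , drop = FALSE]
  } else {
    lines <- character(0)
  }
  ds <- summary_dataset(df, trait_label = trait_label, trait_type = trait_type)
  attr(ds, "rejected") <- lines
  ds
}

# Header-line delimiter sniffing; ties (and neither present) favour tab.
detect_delimiter <- function(header) {
  n_tab <- lengths(gregexpr("\t", header, fixed = TRUE))
  n_com <- lengths(gregexpr(",", header, fixed = TRUE))
  if (regexpr("\t", header, fixed = TRUE) < 0L) n_tab <- 0L
  if (regexpr(",", header, fixed = TRUE) < 0L) n_com <- 0L
  if (n_com > n_tab) "," else "\t"
}

#' LD correlation matrices
#'
#' Pairwise squared correlations (r-squared) between candidate
#' instruments, used by [ld_clump()].  The matrix must be square and
#' symmetric with unit diagonal and entries in \[0,1\]; rows/columns are
#' named by SNP identifier.  The package never computes LD from genotypes
#' — the matrix is an input, typically derived from an external reference
#' panel.
#'
#' @param r2 square numeric matrix of squared correlations.
#' @param snp_ids SNP identifiers; defaults to `rownames(r2)`.
#' @return a validated matrix of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) stop("ld_matrix requires snp_ids", call. = FALSE)
  snp_ids <- as.character(snp_ids)
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(snp_ids)) {
    stop("ld matrix dimensions do not match snp_ids", call. = FALSE)
  }
  if (anyNA(r2) || any(r2 < 0) || any(r2 > 1)) {
    stop("ld matrix entries must be in [0, 1]", call. = FALSE)
  }
  if (max(abs(r2 - t(r2))) > 1e-8) {
    stop("ld matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    stop("ld matrix diagonal must equal 1", call. = FALSE)
  }
  dimnames(r2) <- list(snp_ids, snp_ids)
  class(r2) <- c("ld_matrix", class(matrix()))
  r2
}

#' @rdname ld_matrix
#' @param path square numeric text table (tab- or comma-delimited) with a
#'   header row and a leading column of SNP identifiers.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_delimiter(readLines(path, n = 1L))
  m <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                         check.names = FALSE)
  ld_matrix(as.matrix(m))
}

#' Gene regions
#'
#' The genomic span of the drug-target gene plus a symmetric flank, used
#' to restrict instruments to cis variants.  Coordinates are 1-based
#' inclusive; the flank is in kilobases and is applied to both ends by
#' [restrict_to_region()].
#'
#' @param gene_name gene symbol.
#' @param chrom chromosome label (matched as a string).
#' @param start,end 1-based inclusive span of the gene, `start <= end`.
#' @param flank_kb non-negative flank in kb (default 100).
#' @return an object of class `gene_region`.
#' @export
gene_region <- function(gene_name, chrom, start, end, flank_kb = 100) {
  start <- as.numeric(start); end <- as.numeric(end)
  flank_kb <- as.numeric(flank_kb)
  if (is.na(start) || is.na(end) || start > end) {
    stop("gene region requires start <= end", call. = FALSE)
  }
  if (is.na(flank_kb) || flank_kb < 0) {
    stop("flank_kb must be non-negative", call. = FALSE)
  }
  structure(list(gene_name = as.character(gene_name),
                 chrom = as.character(chrom),
                 start = start, end = end, flank_kb = flank_kb),
            class = "gene_region")
}

#' @export
print.gene_region <- function(x, ...) {
  cat(sprintf("gene region %s: chr%s:%s-%s (flank %g kb)\n", x$gene_name,
              x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","), x$flank_kb))
  invisible(x)
}

#' Write MR or mediation results as a tab-delimited table
#'
#' Serialises results in a fixed column layout (`exposure`, `outcome`,
#' `method`, `nsnp`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `pvalue`)
#' mirroring the usual published MR result tables.  Values are written
#' with enough precision that a read-back reproduces them to at least 12
#' significant digits.
#'
#' @param results an `mr_fit`, `mr_mediation`, a list of them, or a data
#'   frame already in the canonical layout.
#' @param path output file path.
#' @return the written data frame, invisibly.
#' @export
write_result_table <- function(results, path) {
  df <- as_result_table(results)
  if (is.null(df) || nrow(df) == 0L) {
    stop("no results to write: refusing to create an empty result table",
         call. = FALSE)
  }
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), "NA", sprintf("%.15g", v))
  })
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write result table to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(df)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# Coerce the various result containers to the canonical table layout.
as_result_table <- function(results) {
  if (is.data.frame(results)) return(results)
  if (inherits(results, "mr_fit")) return(results$results)
  if (inherits(results, "mr_mediation")) return(mediation_table(results))
  if (is.list(results)) {
    parts <- lapply(results, as_result_table)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) return(NULL)
    return(do.call(rbind, parts))
  }
  NULL
}
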