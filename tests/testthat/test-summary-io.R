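test_that("a well-formed table round-trips through read_summary_stats", {
  df <- snp_table(3)
  path <- write_tsv(df)
  ds <- read_summary_stats(path, trait_label = "LDL-C")
  expect_s3_class(ds, "summary_dataset")
  expect_equal(nrow(ds), 3)
  expect_equal(ds$snp_id, df$snp_id)
  expect_equal(ds$beta, df$beta)
  expect_identical(attr(ds, "trait_label"), "LDL-C")
})

test_that("comma-delimited input and column mapping are handled", {
  df <- snp_table(4)
  names(df) <- c("RSID", "CHR", "BP", "EA", "OA", "FREQ", "B", "SE",
                 "P", "N")
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  ds <- read_summary_stats(path, column_map = c(
    snp_id = "RSID", chrom = "CHR", pos = "BP", effect_allele = "EA",
    other_allele = "OA", eaf = "FREQ", beta = "B", se = "SE",
    pvalue = "P", n = "N"))
  expect_equal(nrow(ds), 4)
  expect_equal(ds$pos, df$BP)
  # missing mandatory column in the map is a format error
  expect_error(read_summary_stats(path, column_map = c(snp_id = "RSID")),
               "column_map")
})

test_that("invalid rows are rejected with their line numbers", {
  df <- snp_table(4)
  df$se[2] <- 0            # file line 3
  df$pvalue[4] <- 1.5      # file line 5
  path <- write_tsv(df)
  expect_warning(ds <- read_summary_stats(path), "line 3")
  expect_equal(nrow(ds), 2)
  expect_equal(ds$snp_id, c("rs1", "rs3"))
  rejected <- attr(ds, "rejected")
  expect_length(rejected, 2)
  expect_match(rejected, "line 3|line 5", all = TRUE)
})

test_that("indel alleles and missing optional fields behave as specified", {
  df <- snp_table(3)
  df$effect_allele[2] <- "AT"
  df$eaf <- NULL
  df$n <- NULL
  path <- write_tsv(df)
  expect_warning(ds <- read_summary_stats(
    path, column_map = c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                         effect_allele = "effect_allele",
                         other_allele = "other_allele", beta = "beta",
                         se = "se", pvalue = "pvalue")), "A,C,G,T")
  expect_equal(nrow(ds), 2)
  # absent eaf/n are NA markers, never 0
  expect_true(all(is.na(ds$eaf)))
  expect_true(all(is.na(ds$n)))
})

test_that("duplicated snp_id is a dataset-level error naming the SNP", {
  df <- snp_table(2)
  df$snp_id <- c("rs1", "rs1")
  path <- write_tsv(df)
  expect_error(read_summary_stats(path), "rs1")
  expect_error(summary_dataset(df), "rs1")
})

test_that("alleles are uppercased on ingest", {
  df <- snp_table(2)
  df$effect_allele <- c("a", "c")
  ds <- summary_dataset(df)
  expect_equal(ds$effect_allele, c("A", "C"))
})

test_that("result tables round-trip losslessly to 12 significant digits", {
  bx <- c(0.3, 0.4, 0.5)
  by <- c(-0.00612345678901, 0.2, 0.15) * bx
  fit <- mr_fit(harmonized_fixture(bx, 0.01, by, c(0.0018, 0.05, 1 / 30)),
                n_boot = 50, seed = 1)
  path <- tempfile(fileext = ".tsv")
  written <- write_result_table(fit, path)
  back <- read_result_table(path)
  expect_equal(names(back), c("exposure", "outcome", "method", "nsnp",
                              "beta", "se", "or", "ci_low", "ci_high",
                              "pvalue"))
  for (col in c("beta", "se", "or", "ci_low", "ci_high", "pvalue")) {
    expect_equal(signif(back[[col]], 12), signif(written[[col]], 12))
  }
})

test_that("a small negative beta is written faithfully", {
  fit <- mr_fit(harmonized_fixture(c(0.3, 0.4, 0.5), 0.01,
                                   -0.006 * c(0.3, 0.4, 0.5),
                                   0.0018 * c(0.3, 0.4, 0.5)),
                methods = "ivw")
  path <- tempfile(fileext = ".tsv")
  write_result_table(fit, path)
  expect_match(paste(readLines(path), collapse = "\n"), "-0.006")
})

test_that("writing an empty result collection is an error, not a file", {
  path <- tempfile(fileext = ".tsv")
  expect_error(write_result_table(list(), path), "empty")
  expect_false(file.exists(path))
})

test_that("parsed datasets always satisfy the record invariants", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    df <- snp_table(n)
    # corrupt a random subset of rows in random ways
    k <- sample(0:min(3, n), 1)
    rows <- sample(n, k)
    for (i in rows) {
      df[[sample(c("se", "pvalue", "effect_allele"), 1)]][i] <-
        sample(list(-1, 2, "X"), 1)[[1]]
    }
    path <- write_tsv(df)
    ds <- suppressWarnings(read_summary_stats(path))
    expect_length(targetmr:::validate_summary_records(as.data.frame(ds)), 0)
  }
})

test_that("ld matrices are validated and read back from text", {
  r2 <- matrix(c(1, 0.4, 0.4, 1), 2, 2,
               dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  ld <- ld_matrix(r2)
  expect_s3_class(ld, "ld_matrix")
  expect_error(ld_matrix(matrix(c(1, 0.2, 0.4, 1), 2, 2,
                                dimnames = dimnames(r2))), "symmetric")
  bad <- r2; diag(bad) <- c(1, 0.9)
  expect_error(ld_matrix(bad), "diagonal")
  path <- tempfile(fileext = ".tsv")
  utils::write.table(cbind(snp_id = rownames(r2), as.data.frame(r2)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unclass(read_ld_matrix(path))[1, 2], 0.4)
})

test_that("gene regions validate their invariants", {
  reg <- gene_region("PCSK9", "1", 55505221, 55530525)
  expect_equal(reg$flank_kb, 100)
  expect_error(gene_region("G", "1", 10, 5), "start")
  expect_error(gene_region("G", "1", 1, 5, flank_kb = -1), "flank")
})
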