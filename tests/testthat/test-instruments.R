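test_that("significance filter is strict and order-preserving", {
  ds <- summary_dataset(snp_table(3, pvalue = c(1e-9, 5e-8, 1e-3)))
  kept <- filter_significant(ds, 5e-8)
  expect_equal(kept$snp_id, "rs1")  # 5e-8 itself is excluded
  none <- filter_significant(summary_dataset(snp_table(3, pvalue = rep(0.5, 3))))
  expect_equal(nrow(none), 0)
  expect_s3_class(none, "summary_dataset")
})

test_that("significance filter agrees with a brute-force scan", {
  set.seed(11)
  n <- 1000
  ds <- summary_dataset(snp_table(n, pvalue = 10^stats::runif(n, -12, 0)))
  thr <- 5e-8
  kept <- filter_significant(ds, thr)
  expect_equal(kept$snp_id,
               ds$snp_id[vapply(seq_len(n),
                                function(i) ds$pvalue[i] < thr,
                                logical(1))])
})

test_that("gene-window restriction is inclusive at both flank boundaries", {
  reg <- gene_region("G", "1", 1000000, 1025000, flank_kb = 100)
  ds <- summary_dataset(snp_table(
    5, chrom = c("1", "1", "1", "1", "2"),
    pos = c(900000, 899999, 1125000, 1125001, 1000000)))
  kept <- restrict_to_region(ds, reg)
  # exactly start - 100000 and end + 100000 are kept; one past is not;
  # another chromosome is dropped regardless of position
  expect_equal(kept$snp_id, c("rs1", "rs3"))
})

test_that("window restriction matches an interval-membership oracle", {
  set.seed(12)
  reg <- gene_region("G", "7", 5e6, 5.2e6, flank_kb = 50)
  n <- 400
  ds <- summary_dataset(snp_table(
    n, chrom = sample(c("7", "8"), n, replace = TRUE),
    pos = sample(seq(4.8e6, 5.4e6), n)))
  kept <- restrict_to_region(ds, reg)
  oracle <- ds$snp_id[ds$chrom == "7" &
                        ds$pos >= 5e6 - 50000 & ds$pos <= 5.2e6 + 50000]
  expect_equal(kept$snp_id, oracle)
})

make_ld <- function(ids, r2_pairs = NULL) {
  J <- length(ids)
  r2 <- diag(J); dimnames(r2) <- list(ids, ids)
  for (p in r2_pairs) r2[p[[1]], p[[2]]] <- r2[p[[2]], p[[1]]] <- p[[3]]
  ld_matrix(r2)
}

test_that("clumping keeps the most significant SNP of a conflicting pair", {
  ds <- summary_dataset(snp_table(2, pvalue = c(1e-10, 1e-9)))
  ld <- make_ld(ds$snp_id, list(list("rs1", "rs2", 0.5)))
  iv <- ld_clump(ds, ld, 0.3)
  expect_equal(iv$records$snp_id, "rs1")
  expect_equal(iv$selection_log$status,
               c("kept", "dropped:ld_with:rs1"))
})

test_that("clumping keeps everything when all pairwise r2 is zero", {
  ds <- summary_dataset(snp_table(6))
  iv <- ld_clump(ds, make_ld(ds$snp_id), 0.3)
  expect_equal(nrow(iv$records), 6)
  expect_true(all(iv$selection_log$status == "kept"))
})

test_that("a SNP absent from the LD matrix is a configuration error", {
  ds <- summary_dataset(snp_table(3))
  ld <- make_ld(c("rs1", "rs2"))
  expect_error(ld_clump(ds, ld, 0.3), "rs3")
})

# Independent re-implementation of the greedy rule for the oracle check.
greedy_oracle <- function(ds, r2, thr) {
  remaining <- ds$snp_id[order(ds$pvalue, ds$pos, ds$snp_id)]
  kept <- character(0)
  while (length(remaining)) {
    best <- remaining[1]
    kept <- c(kept, best)
    remaining <- remaining[r2[best, remaining] < thr]
  }
  sort(kept)
}

test_that("clumping equals an independent greedy oracle on random block LD", {
  set.seed(13)
  for (rep in 1:10) {
    J <- 12
    ds <- summary_dataset(snp_table(J, pvalue = 10^stats::runif(J, -12, -8)))
    # random block structure with random within-block r2
    blocks <- split(sample(ds$snp_id), rep(1:4, each = 3))
    pairs <- list()
    for (b in blocks) {
      for (i in 1:2) for (j in (i + 1):3) {
        pairs <- c(pairs, list(list(b[i], b[j], stats::runif(1))))
      }
    }
    ld <- make_ld(ds$snp_id, pairs)
    iv <- ld_clump(ds, ld, 0.3)
    kept <- iv$records$snp_id
    expect_equal(sort(kept), greedy_oracle(ds, ld, 0.3))
    # every kept pair satisfies the invariant
    if (length(kept) > 1) {
      sub <- unclass(ld)[kept, kept]
      expect_true(all(sub[upper.tri(sub)] < 0.3))
    }
  }
})

test_that("clumping is idempotent and invariant to input order", {
  set.seed(14)
  J <- 9
  ds <- summary_dataset(snp_table(J, pvalue = 10^stats::runif(J, -12, -8)))
  pairs <- list(list("rs1", "rs2", 0.8), list("rs2", "rs3", 0.6),
                list("rs4", "rs5", 0.9), list("rs7", "rs8", 0.31))
  ld <- make_ld(ds$snp_id, pairs)
  iv1 <- ld_clump(ds, ld, 0.3)
  # idempotence
  iv2 <- ld_clump(iv1$records, ld, 0.3)
  expect_equal(iv2$records$snp_id, iv1$records$snp_id)
  expect_true(all(iv2$selection_log$status == "kept"))
  # order invariance
  perm <- sample(J)
  iv3 <- ld_clump(targetmr:::ds_subset(ds, perm), ld, 0.3)
  expect_setequal(iv3$records$snp_id, iv1$records$snp_id)
})

test_that("p-value ties during clumping break by position then id", {
  ds <- summary_dataset(snp_table(2, pvalue = c(1e-10, 1e-10),
                                  pos = c(2000000, 1000000)))
  ld <- make_ld(ds$snp_id, list(list("rs1", "rs2", 0.9)))
  iv <- ld_clump(ds, ld, 0.3)
  expect_equal(iv$records$snp_id, "rs2")  # smaller position wins the tie
})

test_that("select_instruments accounts for every SNP exactly once", {
  set.seed(15)
  reg <- gene_region("G", "1", 1000000, 1025000, flank_kb = 10)
  ds <- summary_dataset(snp_table(
    8, pos = c(rep(1001000, 6), 2e6, 3e6),
    pvalue = c(1e-10, 1e-9, 0.5, 1e-9, 1e-11, 1e-9, 1e-12, 1e-12)))
  ld <- make_ld(ds$snp_id, list(list("rs1", "rs2", 0.9)))
  iv <- select_instruments(ds, region = reg, ld = ld)
  log <- iv$selection_log
  expect_equal(sort(log$snp_id), sort(ds$snp_id))
  expect_equal(sum(log$status == "dropped:p_threshold"), 1)  # rs3
  expect_equal(sum(log$status == "dropped:outside_window"), 2)
  expect_equal(log$status[log$snp_id == "rs2"], "dropped:ld_with:rs1")
  expect_equal(nrow(iv$records),
               sum(log$status == "kept"))
})
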