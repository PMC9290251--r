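# helper to build pooled records over one adjacent pair from pattern counts
pair_records <- function(n11, n10, n01, n00) {
  pats <- rep(c("11", "10", "01", "00"), c(n11, n10, n01, n00))
  data.table::data.table(chrom = "chr1", sample_id = "S1",
                         start_index = 0L, pattern = pats, count = 1L)
}

test_that("adjacent-pair r2 matches hand-derived values", {
  # perfect concordance
  ld <- methylation_ld(pair_records(5, 0, 0, 5), min_pair_reads = 10)
  expect_equal(ld$r2, 1)
  # independence: D = 1/4 - 1/2 * 1/2 = 0
  ld <- methylation_ld(pair_records(1, 1, 1, 1), min_pair_reads = 4)
  expect_equal(ld$r2, 0)
  # D = 3/8 - 1/4 = 1/8; r2 = (1/64) / (1/16) = 0.25
  ld <- methylation_ld(pair_records(3, 1, 1, 3), min_pair_reads = 4)
  expect_equal(ld$r2, 0.25)
})

test_that("r2 is undefined under low coverage or a monomorphic marginal", {
  ld <- methylation_ld(pair_records(5, 0, 0, 4), min_pair_reads = 10)
  expect_true(is.na(ld$r2))          # 9 reads < 10
  ld <- methylation_ld(pair_records(6, 0, 6, 0), min_pair_reads = 10)
  expect_true(is.na(ld$r2))          # right-site marginal all methylated
  expect_equal(ld$n, 12L)
  expect_error(methylation_ld(
    data.table::data.table(chrom = "chr1", sample_id = "S1", start_index = 0L,
                           pattern = "11", count = -1L)), "negative")
})

test_that("pair counts pool reads across samples and positions", {
  rec <- data.table::data.table(
    chrom = "chr1", sample_id = c("A", "B", "B"), start_index = c(0L, 0L, 1L),
    pattern = c("110", "11", "10"), count = c(2L, 1L, 1L))
  ld <- methylation_ld(rec, min_pair_reads = 1)
  expect_equal(ld$index_i, c(0L, 1L))
  expect_equal(ld[index_i == 0L, .(n11, n10, n01, n00)],
               data.table::data.table(n11 = 3L, n10 = 0L, n01 = 0L, n00 = 0L))
  expect_equal(ld[index_i == 1L, .(n11, n10)], # "10" from read 1 (x2) + read 3
               data.table::data.table(n11 = 0L, n10 = 3L))
})

make_ld <- function(r2vec, chrom = "chr1") {
  data.table::data.table(chrom = chrom, index_i = seq_along(r2vec) - 1L,
                         n11 = 10L, n10 = 0L, n01 = 0L, n00 = 10L,
                         n = 20L, r2 = r2vec)
}

test_that("block partition matches hand-derived run decompositions", {
  sites4 <- cpg_site_table(rep("chr1", 4), c(100, 120, 140, 160))
  b <- partition_blocks(make_ld(c(0.9, 0.9, 0.9)), sites4,
                        r2_min = 0.5, min_cpgs = 3)
  expect_equal(nrow(b), 1L)
  expect_equal(b$first_index, 0L)
  expect_equal(b$last_index, 3L)
  expect_equal(b$start, 100L)
  expect_equal(b$end, 161L)          # last member position + 1

  # break in the middle leaves two 2-site runs
  b <- partition_blocks(make_ld(c(1.0, 0.3, 1.0)), sites4,
                        r2_min = 0.5, min_cpgs = 3)
  expect_equal(nrow(b), 0L)
  b <- partition_blocks(make_ld(c(1.0, 0.3, 1.0)), sites4,
                        r2_min = 0.5, min_cpgs = 2)
  expect_equal(b$first_index, c(0L, 2L))
  expect_equal(b$last_index, c(1L, 3L))

  expect_error(partition_blocks(make_ld(c(0.9, 0.9))[c(2, 1)], sites4),
               "ordered")
})

test_that("partition agrees with the exhaustive maximal-run oracle", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    r2vec <- runif(n - 1L)
    r2vec[runif(n - 1L) < 0.2] <- NA   # coverage gaps break runs
    min_cpgs <- sample(2:4, 1)
    sites <- cpg_site_table(rep("chr1", n), cumsum(sample(10:40, n, TRUE)))
    got <- partition_blocks(make_ld(r2vec), sites, r2_min = 0.5,
                            min_cpgs = min_cpgs)
    want <- partition_brute(!is.na(r2vec) & r2vec >= 0.5, min_cpgs)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      want_first <- vapply(want, `[`, numeric(1), 1) - 1
      want_last <- vapply(want, `[`, numeric(1), 2) - 1
      expect_equal(got$first_index, as.integer(want_first))
      expect_equal(got$last_index, as.integer(want_last))
    }
  }
})

test_that("raising r2_min never increases block-covered CpG count", {
  set.seed(7)
  r2vec <- runif(40)
  sites <- cpg_site_table(rep("chr1", 41), cumsum(sample(10:40, 41, TRUE)))
  covered <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th) {
    b <- partition_blocks(make_ld(r2vec), sites, r2_min = th, min_cpgs = 3)
    if (nrow(b)) sum(b$last_index - b$first_index + 1L) else 0L
  }, numeric(1))
  expect_true(all(diff(covered) <= 0))
})

test_that("blocks are invariant to sample relabeling", {
  cfg <- small_config()
  co <- generate_cohort(cfg, seed = 3)
  rec1 <- co$haplotypes
  rec2 <- data.table::copy(rec1)
  rec2[, sample_id := paste0("X_", sample_id)]
  ld1 <- methylation_ld(rec1, min_pair_reads = 10)
  ld2 <- methylation_ld(rec2, min_pair_reads = 10)
  expect_equal(ld1, ld2)
  expect_equal(partition_blocks(ld1, co$sites),
               partition_blocks(ld2, co$sites))
})
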