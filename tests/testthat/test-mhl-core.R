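block3 <- data.table::data.table(block_id = "b1", chrom = "chr1",
                                 start = 10L, end = 71L,
                                 first_index = 0L, last_index = 2L)

recs <- function(pats, counts = rep(1L, length(pats)), sample = "S1",
                 start = 0L) {
  data.table::data.table(chrom = "chr1", sample_id = sample,
                         start_index = start, pattern = pats, count = counts)
}

test_that("MHL matches hand-derived window enumerations", {
  # all-methylated reads
  r <- compute_block_mhl(recs(c("111", "111")), block3, min_support = 1)
  expect_equal(r$mhl, 1)
  # 2-CpG block, "10" + "01": m1 = 1/2, m2 = 0, MHL = 1/6
  b2 <- data.table::data.table(block_id = "b", chrom = "chr1", start = 10L,
                               end = 31L, first_index = 0L, last_index = 1L)
  r <- compute_block_mhl(recs(c("10", "01")), b2, min_support = 1)
  expect_equal(r$mhl, 1 / 6)
  # 3-CpG block: m1 = 7/12, m2 = 3/8, m3 = 1/4, MHL = 25/72
  r <- compute_block_mhl(recs(c("111", "110", "000", "101")), block3,
                         min_support = 1)
  expect_equal(r$mhl, 25 / 72)
})

test_that("MHL equals the methylated-read fraction for concordant full-span reads", {
  for (p in c(0, 0.25, 0.5, 1)) {
    n1 <- round(8 * p)
    pats <- rep(c("111", "000"), c(n1, 8 - n1))
    r <- compute_block_mhl(recs(pats), block3, min_support = 1)
    expect_equal(r$mhl, p)
  }
})

test_that("MHL agrees exactly with the brute-force window oracle", {
  set.seed(23)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    nreads <- sample(1:20, 1)
    pats <- vapply(seq_len(nreads), function(.)
      paste(sample(c("0", "1"), k, TRUE), collapse = ""), character(1))
    counts <- sample(1:3, nreads, TRUE)
    blk <- data.table::data.table(block_id = "b", chrom = "chr1", start = 0L,
                                  end = k * 10L, first_index = 0L,
                                  last_index = k - 1L)
    got <- compute_block_mhl(recs(pats, counts), blk, min_support = 1)$mhl
    expect_equal(got, mhl_brute(pats, counts), tolerance = 1e-12)
    # MHL never exceeds the window-level mean methylation m_1
    m1 <- sum(counts * vapply(pats, function(p)
      sum(strsplit(p, "")[[1]] == "1"), numeric(1))) / (k * sum(counts))
    expect_lte(got, m1 + 1e-12)
  }
})

test_that("MHL is invariant to read order and count splitting", {
  pats <- c("110", "011", "111", "000", "101")
  counts <- c(3L, 1L, 2L, 2L, 1L)
  a <- compute_block_mhl(recs(pats, counts), block3, min_support = 1)
  b <- compute_block_mhl(recs(rev(pats), rev(counts)), block3, min_support = 1)
  split1 <- recs(rep(pats, counts), rep(1L, sum(counts)))
  c3 <- compute_block_mhl(split1, block3, min_support = 1)
  expect_equal(a$mhl, b$mhl)
  expect_equal(a$mhl, c3$mhl)
  expect_equal(a$support, c3$support)
})

test_that("partial reads contribute only windows they fully contain", {
  # read covering only sites 1..2 of a 3-site block
  part <- recs("11", start = 1L)
  r <- compute_block_mhl(part, block3, min_support = 1)
  expect_equal(r$mhl, 1)
  expect_equal(r$support, 2)
  # a non-overlapping read is ignored, not an error
  r2 <- compute_block_mhl(recs("11", start = 4L), block3, min_support = 1)
  expect_true(is.na(r2$mhl))
})

test_that("the MHL matrix is cellwise consistent with compute_block_mhl", {
  cfg <- small_config()
  co <- generate_cohort(cfg, seed = 5)
  m <- build_mhl_matrix(co$haplotypes, co$blocks, min_support = 5)
  expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))
  set.seed(1)
  for (i in sample(nrow(m), 5)) for (j in sample(ncol(m), 3)) {
    cell <- compute_block_mhl(
      co$haplotypes[sample_id == colnames(m)[j]], co$blocks[i],
      min_support = 5)
    expect_equal(unname(m[i, j]), cell$mhl)
    expect_equal(unname(attr(m, "support")[i, j]), cell$support)
  }
})

test_that("samples without reads on a block give missing entries", {
  rec <- rbind(recs("111", sample = "A"), recs("000", sample = "B"))
  blk2 <- rbind(block3,
                data.table::data.table(block_id = "b2", chrom = "chr1",
                                       start = 200L, end = 261L,
                                       first_index = 3L, last_index = 5L))
  m <- build_mhl_matrix(rec, blk2, samples = c("A", "B", "C"),
                        min_support = 1)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m["b1", "A"], 1)
  expect_equal(m["b1", "B"], 0)
  expect_true(all(is.na(m[, "C"])))
  expect_true(all(is.na(m["b2", ])))
  expect_error(build_mhl_matrix(rec, rbind(block3, block3)), "duplicate")
})

test_that("missingness filter honours both policies", {
  m <- matrix(c(0.1, NA, NA, 0.2, 0.3, NA, 0.5, 0.6, NA), 3, 3,
              dimnames = list(c("b1", "b2", "b3"), c("S1", "S2", "S3")))
  # b1 complete, b2 missing in 1 of 3 samples, b3 missing everywhere
  expect_equal(rownames(filter_missing_blocks(m, "all")), c("b1", "b2"))
  expect_equal(rownames(filter_missing_blocks(m, "any")), "b1")
  full <- matrix(runif(6), 2, 3, dimnames = list(c("x", "y"), NULL))
  expect_equal(filter_missing_blocks(full, "any"), full)
  expect_equal(filter_missing_blocks(full, "all"), full)
})

test_that("bin methylation counts calls into half-open 10-kb tiles", {
  sites <- cpg_site_table(rep("chr1", 4), c(500, 9999, 10000, 15000))
  rec <- data.table::data.table(chrom = "chr1", sample_id = "S1",
                                start_index = 0L, pattern = "1101",
                                count = 2L)
  bins <- compute_bin_methylation(rec, sites, bin_size = 10000)
  expect_equal(nrow(bins), 2L)
  b1 <- bins[bin_start == 0L]
  expect_equal(b1$MC, 4)             # calls at 500 and 9999, both '1', x2
  expect_equal(b1$MT, 0)
  b2 <- bins[bin_start == 10000L]    # position 10000 falls in the second bin
  expect_equal(b2$MC, 2)             # site 15000 '1' x2
  expect_equal(b2$MT, 2)             # site 10000 '0' x2
  expect_equal(b2$level, 0.5)
  # conservation: totals equal number of calls
  expect_equal(sum(bins$MC + bins$MT), 4 * 2)
  # empty bin is missing
  sites2 <- cpg_site_table(rep("chr1", 2), c(100, 25000))
  rec2 <- data.table::data.table(chrom = "chr1", sample_id = "S1",
                                 start_index = 0L, pattern = "1", count = 1L)
  bins2 <- compute_bin_methylation(rec2, sites2, bin_size = 10000)
  expect_true(is.na(bins2[bin_start == 10000L, level]))
})

test_that("element methylation uses half-open containment, overlaps allowed", {
  tss <- 5000L
  elements <- data.table::data.table(
    chrom = "chr1", start = c(tss - 1000L, tss), end = c(tss + 1000L, tss + 2000L),
    class_label = c("promoter", "genebody"))
  sites <- cpg_site_table(rep("chr1", 3), c(tss - 500L, tss + 500L, tss + 1001L))
  rec <- data.table::data.table(chrom = "chr1", sample_id = "S1",
                                start_index = 0L, pattern = "100", count = 1L)
  em <- element_methylation(rec, sites, elements)
  # promoter contains TSS-500 ('1') and TSS+500 ('0'), not TSS+1001
  expect_equal(em[class_label == "promoter", .(MC, MT, level)],
               data.table::data.table(MC = 1, MT = 1, level = 0.5))
  # the overlapping genebody also receives TSS+500 and TSS+1001
  expect_equal(em[class_label == "genebody", .(MC, MT)],
               data.table::data.table(MC = 0, MT = 2))
  expect_equal(em[class_label == "genebody", level], 0)
})

test_that("profile correlation follows the Pearson definition", {
  expect_equal(profile_correlation(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 1)
  expect_equal(profile_correlation(c(0.1, 0.5, 0.9), 1 - c(0.1, 0.5, 0.9)), -1)
  expect_equal(profile_correlation(c(0, 1, 2), c(0, 2, 1)), 0.5)
  expect_error(profile_correlation(c(0.1, NA, 0.3), c(0.1, 0.2, NA)),
               "fewer than 3")
  expect_error(profile_correlation(c(1, 1, 1), c(0, 1, 2)), "zero variance")
})
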