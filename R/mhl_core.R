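#' Methylation haplotype load of one block in one sample
#'
#' MHL summarises a block's read haplotypes as a weighted mean, over
#' substring lengths l = 1..L, of the fraction of fully methylated
#' contiguous windows of l member CpGs: m_l is the number of all-'1'
#' windows of length l divided by the number of such windows observed
#' (over all reads), and MHL = sum_l w_l m_l / sum_l w_l with linear
#' weights w_l = l. L is the longest within-block stretch observed in any
#' read. Windows are formed within single reads only, from the contiguous
#' run of member CpGs the read actually covers; nothing is imputed. Unlike
#' the plain mean (which m_1 equals), MHL rewards long fully methylated
#' stretches, i.e. haplotype concordance.
#'
#' @param records Haplotype `data.table` for one sample (records not
#'   overlapping the block are ignored).
#' @param block One block row (`chrom`, `first_index`, `last_index`).
#' @param min_support Minimum number of single-CpG observations (length-1
#'   windows) for a defined value; below it the value is `NA`.
#' @return List with `mhl` (value in \[0,1\] or `NA`) and `support`
#'   (length-1 window count).
#' @export
compute_block_mhl <- function(records, block, min_support = 5) {
  stopifnot(nrow(block) == 1L)
  sub <- block_substrings(records, block)
  if (nrow(sub) == 0L) return(list(mhl = NA_real_, support = 0L))
  cells <- sub[, .(count = sum(count)), by = pattern]
  cells[, `:=`(block_id = block$block_id[1L], sample_id = "x")]
  res <- mhl_from_cells(cells, min_support = min_support)
  list(mhl = res$mhl[1L], support = res$support[1L])
}

# contiguous member-CpG substrings of reads overlapping one block
block_substrings <- function(records, block) {
  rec <- records[chrom == block$chrom[1L]]
  if (nrow(rec) == 0L) return(data.table(pattern = character(), count = integer()))
  lo <- pmax(rec$start_index, block$first_index[1L])
  hi <- pmin(rec$start_index + nchar(rec$pattern) - 1L, block$last_index[1L])
  keep <- lo <= hi
  rec <- rec[keep]
  if (nrow(rec) == 0L) return(data.table(pattern = character(), count = integer()))
  data.table(pattern = substr(rec$pattern,
                              lo[keep] - rec$start_index + 1L,
                              hi[keep] - rec$start_index + 1L),
             count = rec$count)
}

# per-pattern window counts: for each substring length l, the number of
# windows (tot) and of fully methylated windows (meth) in one read
pattern_window_stats <- function(patterns) {
  res <- lapply(patterns, function(p) {
    m <- nchar(p)
    bits <- strsplit(p, "", fixed = TRUE)[[1L]] == "1"
    r <- rle(bits)
    ones <- r$lengths[r$values]
    l <- seq_len(m)
    meth <- vapply(l, function(ll) sum(pmax(0L, ones - ll + 1L)), numeric(1))
    list(pattern = p, l = l, tot = m - l + 1L, meth = meth)
  })
  rbindlist(res)
}

# cells: data.table(block_id, sample_id, pattern, count) -> one row per cell
mhl_from_cells <- function(cells, min_support = 5) {
  stats <- pattern_window_stats(unique(cells$pattern))
  ex <- merge(cells, stats, by = "pattern", allow.cartesian = TRUE)
  byl <- ex[, .(tot = sum(as.numeric(count) * tot),
                meth = sum(as.numeric(count) * meth)),
            by = .(block_id, sample_id, l)]
  res <- byl[tot > 0,
             .(mhl = sum(l * meth / tot) / sum(l),
               support = tot[l == 1L]),
             by = .(block_id, sample_id)]
  res[support < min_support, mhl := NA_real_]
  res
}

#' Build the blocks-by-samples MHL matrix
#'
#' Computes [compute_block_mhl()] for every (block, sample) cell. Entries
#' with fewer than `min_support` single-CpG observations are `NA`; the
#' supporting counts are returned as the `"support"` attribute.
#'
#' @param records Haplotype `data.table` (all samples).
#' @param blocks Disjoint block `data.table` with unique `block_id`s.
#' @param samples Sample ids defining the column set and order; defaults to
#'   the samples present in `records`.
#' @param min_support Minimum length-1 window count per entry.
#' @return Numeric matrix (blocks x samples) in \[0,1\] with `NA` for
#'   missing entries, rownames block ids, colnames sample ids.
#' @export
build_mhl_matrix <- function(records, blocks, samples = NULL, min_support = 5) {
  if (anyDuplicated(blocks$block_id)) stop("duplicate block ids")
  if (is.null(samples)) samples <- sort(unique(records$sample_id))
  m <- matrix(NA_real_, nrow(blocks), length(samples),
              dimnames = list(blocks$block_id, samples))
  supp <- matrix(0, nrow(blocks), length(samples),
                 dimnames = dimnames(m))
  rec <- copy(records)[, `:=`(ri_start = start_index,
                              ri_end = start_index + nchar(pattern) - 1L)]
  bl <- copy(blocks)[, `:=`(bi_start = first_index, bi_end = last_index)]
  setkey(bl, chrom, bi_start, bi_end)
  ov <- foverlaps(rec, bl, by.x = c("chrom", "ri_start", "ri_end"),
                  by.y = c("chrom", "bi_start", "bi_end"), nomatch = NULL)
  if (nrow(ov) == 0L) return(structure(m, support = supp))
  lo <- pmax(ov$ri_start, ov$bi_start)
  hi <- pmin(ov$ri_end, ov$bi_end)
  cells <- data.table(block_id = ov$block_id, sample_id = ov$sample_id,
                      pattern = substr(ov$pattern, lo - ov$ri_start + 1L,
                                       hi - ov$ri_start + 1L),
                      count = ov$count)
  cells <- cells[, .(count = sum(count)), by = .(block_id, sample_id, pattern)]
  res <- mhl_from_cells(cells, min_support = min_support)
  res <- res[sample_id %in% samples]
  ij <- cbind(match(res$block_id, rownames(m)), match(res$sample_id, samples))
  m[ij] <- res$mhl
  supp[ij] <- res$support
  structure(m, support = supp)
}

#' Drop blocks with missing MHL entries
#'
#' @param m MHL matrix.
#' @param policy `"any"` drops rows with at least one missing entry (the
#'   default when preparing factorization input, which cannot consume
#'   missing values); `"all"` drops only rows missing in every sample.
#' @return The filtered matrix, row order preserved.
#' @export
filter_missing_blocks <- function(m, policy = c("any", "all")) {
  policy <- match.arg(policy)
  nmiss <- rowSums(is.na(m))
  keep <- if (policy == "any") nmiss == 0L else nmiss < ncol(m)
  sup <- attr(m, "support")
  out <- m[keep, , drop = FALSE]
  if (!is.null(sup)) attr(out, "support") <- sup[keep, , drop = FALSE]
  out
}

# expand haplotype records into per-CpG calls with genomic positions
expand_calls <- function(records, sites) {
  if (nrow(records) == 0L)
    return(data.table(chrom = character(), site_index = integer(),
                      pos = integer(), state = integer(), count = integer()))
  nlen <- nchar(records$pattern)
  row <- rep(seq_len(nrow(records)), times = nlen)
  off <- sequence(nlen)
  calls <- data.table(chrom = records$chrom[row],
                      site_index = records$start_index[row] + off - 1L,
                      state = as.integer(substr(records$pattern[row], off, off)),
                      count = records$count[row])
  calls <- sites[calls, on = .(chrom, site_index)]
  calls[, .(chrom, site_index, pos, state, count)]
}

#' Mean methylation in fixed genomic bins
#'
#' Tiles each chromosome from coordinate 0 in half-open windows of
#' `bin_size` bases and counts methylated (MC) and unmethylated (MT) CpG
#' calls per bin; the level is MC/(MC+MT), missing where a bin has no
#' calls. Bins run to the last CpG site of each chromosome.
#'
#' @param records Haplotype `data.table`.
#' @param sites CpG site table.
#' @param bin_size Bin width in bases (default 10 kb).
#' @return `data.table` with `chrom`, `bin_start`, `bin_end`, `MC`, `MT`,
#'   `level`.
#' @export
compute_bin_methylation <- function(records, sites, bin_size = 10000) {
  calls <- expand_calls(records, sites)
  calls[, bin_start := (pos %/% as.integer(bin_size)) * as.integer(bin_size)]
  agg <- calls[, .(MC = sum(count * (state == 1L)),
                   MT = sum(count * (state == 0L))),
               by = .(chrom, bin_start)]
  grid <- sites[, .(bin_start = seq(0L, max(pos) %/% as.integer(bin_size) *
                                      as.integer(bin_size), by = as.integer(bin_size))),
                by = chrom]
  out <- agg[grid, on = .(chrom, bin_start)]
  out[is.na(MC), `:=`(MC = 0, MT = 0)]
  out[, `:=`(bin_end = bin_start + as.integer(bin_size),
             level = ifelse(MC + MT > 0, MC / (MC + MT), NA_real_))]
  setorder(out, chrom, bin_start)
  out[, .(chrom, bin_start, bin_end, MC, MT, level)]
}

#' Mean methylation over annotated elements
#'
#' Each CpG call contributes to every element whose half-open interval
#' contains its position (elements may overlap, e.g. promoters defined as
#' +/- 1000 bp around a TSS). The level is MC/(MC+MT) per element, missing
#' for elements containing no call.
#'
#' @param records Haplotype `data.table`.
#' @param sites CpG site table.
#' @param elements Annotation `data.table` (`chrom`, `start`, `end`,
#'   `class_label`).
#' @return `elements` with `MC`, `MT` and `level` columns appended.
#' @export
element_methylation <- function(records, sites, elements) {
  calls <- expand_calls(records, sites)
  out <- copy(elements)[, `:=`(MC = 0, MT = 0)]
  if (nrow(calls)) {
    qry <- GRanges(calls$chrom, IRanges(calls$pos + 1L, width = 1L))
    sbj <- GRanges(out$chrom, IRanges(out$start + 1L, out$end))
    hits <- findOverlaps(qry, sbj)
    if (length(hits)) {
      hd <- data.table(el = subjectHits(hits),
                       mc = calls$count[queryHits(hits)] *
                         (calls$state[queryHits(hits)] == 1L),
                       mt = calls$count[queryHits(hits)] *
                         (calls$state[queryHits(hits)] == 0L))
      agg <- hd[, .(mc = sum(mc), mt = sum(mt)), by = el]
      out$MC[agg$el] <- agg$mc
      out$MT[agg$el] <- agg$mt
    }
  }
  out[, level := ifelse(MC + MT > 0, MC / (MC + MT), NA_real_)]
  out[]
}

#' Pearson correlation between two methylation profiles
#'
#' Computed over positions non-missing in both profiles; requires at least
#' 3 shared positions and non-zero variance in each.
#'
#' @param a,b Numeric level vectors of equal length (e.g. `level` columns of
#'   two [compute_bin_methylation()] tables over the same bins).
#' @return Pearson r in \[-1, 1\].
#' @export
profile_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("fewer than 3 shared non-missing positions")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) stop("zero variance in a profile")
  cor(a[ok], b[ok])
}
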