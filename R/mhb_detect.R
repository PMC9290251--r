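#' Methylation linkage between adjacent CpG site pairs
#'
#' Pools read haplotypes across all samples and, for every adjacent pair of
#' CpG sites (ranks i, i+1) covered by at least one read, tabulates the joint
#' methylation haplotype counts n11, n10, n01, n00 and computes the two-locus
#' linkage r-squared: with p11 = n11/n, p1. = (n11+n10)/n, p.1 = (n11+n01)/n,
#' D = p11 - p1.*p.1 and r2 = D^2 / (p1.(1-p1.) p.1(1-p.1)). Only reads
#' covering both sites contribute. r2 is undefined (`NA`) when fewer than
#' `min_pair_reads` reads cover the pair or when either marginal is 0 or 1
#' (a monomorphic site carries no linkage evidence).
#'
#' @param records Haplotype `data.table` (pooled over samples).
#' @param min_pair_reads Minimum reads covering a pair for a defined r2.
#' @return `data.table` with `chrom`, `index_i` (left site rank), counts
#'   `n11`, `n10`, `n01`, `n00`, `n`, and `r2` (`NA` when undefined), ordered
#'   by chromosome and site rank.
#' @export
methylation_ld <- function(records, min_pair_reads = 10) {
  if (any(records$count < 0L)) stop("negative haplotype counts")
  rec <- records[nchar(pattern) >= 2L]
  if (nrow(rec) == 0L)
    return(data.table(chrom = character(), index_i = integer(),
                      n11 = integer(), n10 = integer(), n01 = integer(),
                      n00 = integer(), n = integer(), r2 = numeric()))
  npair <- nchar(rec$pattern) - 1L
  row <- rep(seq_len(nrow(rec)), times = npair)
  off <- sequence(npair)                       # 1-based offset of left site in pattern
  pat <- rec$pattern[row]
  left  <- substr(pat, off, off)
  right <- substr(pat, off + 1L, off + 1L)
  ex <- data.table(chrom = rec$chrom[row],
                   index_i = rec$start_index[row] + off - 1L,
                   cat = paste0(left, right),
                   count = rec$count[row])
  tab <- ex[, .(count = sum(count)), by = .(chrom, index_i, cat)]
  wide <- data.table::dcast(tab, chrom + index_i ~ cat, value.var = "count", fill = 0L)
  for (cc in c("11", "10", "01", "00"))
    if (!cc %in% names(wide)) wide[, (cc) := 0L]
  setnames(wide, c("11", "10", "01", "00"), c("n11", "n10", "n01", "n00"))
  wide[, n := n11 + n10 + n01 + n00]
  wide[, r2 := pair_r2(n11, n10, n01, n00)]
  wide[n < min_pair_reads, r2 := NA_real_]
  setorder(wide, chrom, index_i)
  wide[, .(chrom, index_i, n11, n10, n01, n00, n, r2)]
}

pair_r2 <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p11 <- n11 / n
  p1 <- (n11 + n10) / n
  q1 <- (n11 + n01) / n
  D <- p11 - p1 * q1
  denom <- p1 * (1 - p1) * q1 * (1 - q1)
  r2 <- ifelse(denom > 0, D^2 / denom, NA_real_)
  # guard numerical overshoot
  pmin(pmax(r2, 0), 1)
}

#' Partition CpG sites into methylation haplotype blocks
#'
#' A methylation haplotype block (MHB) is a maximal run of consecutive CpG
#' sites in which every adjacent pair has a defined linkage r2 of at least
#' `r2_min`. An undefined r2 (low coverage or a monomorphic site) breaks a
#' run; runs shorter than `min_cpgs` sites are discarded. Block intervals
#' span the first member CpG position to the last member position + 1
#' (0-based half-open).
#'
#' @param ld Adjacent-pair LD table from [methylation_ld()], ordered by
#'   chromosome and site rank.
#' @param sites CpG site table.
#' @param r2_min Minimum adjacent-pair r2 inside a block.
#' @param min_cpgs Minimum member CpG sites per block.
#' @return Block `data.table` (`block_id`, `chrom`, `start`, `end`,
#'   `first_index`, `last_index`); blocks are disjoint and maximal.
#' @export
partition_blocks <- function(ld, sites, r2_min = 0.5, min_cpgs = 3) {
  if (nrow(ld) && ld[, any(diff(index_i) <= 0L), by = chrom][, any(V1)])
    stop("LD table must be ordered by site rank within chromosome")
  out <- vector("list", 0L)
  for (ch in unique(sites$chrom)) {
    s <- sites[chrom == ch]
    np <- nrow(s) - 1L
    if (np < 1L) next
    ok <- rep(FALSE, np)
    lc <- ld[chrom == ch & !is.na(r2) & r2 >= r2_min]
    ok[lc$index_i[lc$index_i < np] + 1L] <- TRUE
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_cpgs - 1L)) {
      i0 <- starts[k] - 1L          # first member site rank (0-based)
      i1 <- ends[k]                 # last member site rank
      p0 <- s$pos[i0 + 1L]
      p1 <- s$pos[i1 + 1L]
      out[[length(out) + 1L]] <- data.table(
        block_id = sprintf("%s:%d-%d", ch, p0, p1 + 1L),
        chrom = ch, start = p0, end = p1 + 1L,
        first_index = i0, last_index = i1)
    }
  }
  if (!length(out))
    return(data.table(block_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      first_index = integer(), last_index = integer()))
  res <- rbindlist(out)
  setorder(res, chrom, start)
  res[]
}
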