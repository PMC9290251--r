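#' Call differentially methylated blocks between two groups
#'
#' Per block: a two-sided Wilcoxon rank-sum test between the two sample
#' groups on MHL, Benjamini-Hochberg adjustment across tested blocks, and
#' a call of `hyper` (group1 minus group2 mean >= `delta_min` and adjusted
#' p <= `alpha`), `hypo` (delta <= -`delta_min`), or `none`. Blocks with
#' fewer than 2 non-missing values in either group are left untested
#' (`NA` p-values, call `none`).
#'
#' @param m MHL matrix.
#' @param group1,group2 Disjoint character vectors of sample ids (columns
#'   of `m`); each must contain at least 2 samples.
#' @param delta_min Minimum absolute group-mean difference.
#' @param alpha FDR threshold.
#' @return `data.frame` with `block_id`, `mean1`, `mean2`, `delta`, `p`,
#'   `padj`, `call`.
#' @export
differential_blocks <- function(m, group1, group2, delta_min = 0.2,
                                alpha = 0.05) {
  stopifnot(all(c(group1, group2) %in% colnames(m)),
            !any(group1 %in% group2))
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs at least 2 samples")
  x1 <- m[, group1, drop = FALSE]
  x2 <- m[, group2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  testable <- n1 >= 2L & n2 >= 2L
  mean1 <- rowMeans(x1, na.rm = TRUE)
  mean2 <- rowMeans(x2, na.rm = TRUE)
  p <- rep(NA_real_, nrow(m))
  for (i in which(testable)) {
    a <- x1[i, ][!is.na(x1[i, ])]
    b <- x2[i, ][!is.na(x2[i, ])]
    p[i] <- if (sd(c(a, b)) == 0) 1 else
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }
  padj <- rep(NA_real_, nrow(m))
  padj[testable] <- p.adjust(p[testable], method = "BH")
  delta <- mean1 - mean2
  call <- rep("none", nrow(m))
  sig <- testable & !is.na(padj) & padj <= alpha
  call[sig & delta >= delta_min] <- "hyper"
  call[sig & delta <= -delta_min] <- "hypo"
  data.frame(block_id = rownames(m), mean1 = mean1, mean2 = mean2,
             delta = delta, p = p, padj = padj, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotation enrichment of a differential block set
#'
#' For every annotation class, compares the fraction of differential
#' blocks overlapping the class (observed) with the fraction of background
#' blocks overlapping it (expected) and reports log2(obs/exp). A block
#' overlaps a class if any interval of that class intersects it by at
#' least 1 bp (half-open intervals). The background is the set of tested
#' blocks, which controls for block ascertainment.
#'
#' @param diff_ids Block ids of the differential set (subset of
#'   `background_ids`; must be non-empty).
#' @param background_ids Block ids of the background set.
#' @param blocks Block `data.table` covering both sets.
#' @param track Annotation `data.table` (`chrom`, `start`, `end`,
#'   `class_label`).
#' @return `data.frame` per class: `class_label`, `obs`, `exp`,
#'   `log2_ratio` (`NA` with `undefined = TRUE` when `exp` is 0).
#' @export
annotation_enrichment <- function(diff_ids, background_ids, blocks, track) {
  if (length(diff_ids) == 0L) stop("empty differential set")
  if (!all(diff_ids %in% background_ids))
    stop("differential set must be a subset of the background")
  bk <- blocks[match(background_ids, block_id)]
  if (anyNA(bk$block_id)) stop("background ids missing from block table")
  bg <- GRanges(bk$chrom, IRanges(bk$start + 1L, bk$end))
  classes <- unique(track$class_label)
  is_diff <- bk$block_id %in% diff_ids
  res <- lapply(classes, function(cl) {
    iv <- track[class_label == cl]
    tg <- GRanges(iv$chrom, IRanges(iv$start + 1L, iv$end))
    hit <- GenomicRanges::countOverlaps(bg, tg) > 0L
    obs <- mean(hit[is_diff])
    expf <- mean(hit)
    data.frame(class_label = cl, obs = obs, exp = expf,
               log2_ratio = if (expf > 0 && obs > 0) log2(obs / expf)
                            else if (expf > 0) -Inf else NA_real_,
               undefined = expf == 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
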