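#' Map array probes to methylation haplotype blocks
#'
#' A probe maps to the unique disjoint block whose half-open interval
#' \[start, end) contains its position; probes falling in no block are
#' dropped with a message giving the count.
#'
#' @param probes `data.table` with `probe_id`, `chrom`, `pos` (0-based), as
#'   in the `probes` element of a [read_beta_matrix()] result.
#' @param blocks Disjoint block `data.table`.
#' @return `data.table` with `probe_id`, `block_id`.
#' @export
map_probes_to_blocks <- function(probes, blocks) {
  bg <- GRanges(blocks$chrom, IRanges(blocks$start + 1L, blocks$end))
  if (length(bg) > 1L && any(GenomicRanges::countOverlaps(bg, bg) > 1L))
    stop("blocks must be disjoint")
  pg <- GRanges(probes$chrom, IRanges(probes$pos + 1L, width = 1L))
  hits <- findOverlaps(pg, bg)
  dropped <- nrow(probes) - length(unique(queryHits(hits)))
  if (dropped > 0L) message(dropped, " probe(s) outside any block dropped")
  data.table(probe_id = probes$probe_id[queryHits(hits)],
             block_id = blocks$block_id[subjectHits(hits)])
}

#' Average beta values over block-overlapping probes
#'
#' Arrays carry no read-level haplotype information, so blocks are scored
#' on arrays by the plain mean of the overlapping probes' beta values
#' (missing-aware); an entry is missing only when every probe is missing
#' for that sample.
#'
#' @param bm A `beta_matrix` object.
#' @param map Probe-to-block map from [map_probes_to_blocks()].
#' @return Numeric matrix, rows block ids (with >= 1 probe), columns
#'   samples, entries mean beta in \[0,1\] or `NA`.
#' @export
summarize_region_beta <- function(bm, map) {
  if (nrow(map) == 0L) stop("empty probe-to-block map")
  map <- map[probe_id %in% rownames(bm$beta)]
  ids <- unique(map$block_id)
  grp <- match(map$block_id, ids)
  sub <- bm$beta[map$probe_id, , drop = FALSE]
  num <- rowsum(ifelse(is.na(sub), 0, sub), grp)
  den <- rowsum((!is.na(sub)) * 1, grp)
  out <- num / den
  out[den == 0] <- NA_real_
  rownames(out) <- ids
  out
}

#' Classify an external array cohort into epi-clusters
#'
#' Re-runs the epi-cluster discovery independently on the block-level beta
#' matrix of an external cohort: rows with any missing value are dropped,
#' the most variable rows are selected, a rank-2 consensus NMF is fitted,
#' and clusters are labelled Methy-High / Methy-Low by the same
#' hypermethylation rule as on sequencing data.
#'
#' @param regions Region beta matrix from [summarize_region_beta()].
#' @inheritParams classify_epiclusters
#' @return Assignment `data.frame` (see [assign_and_label()]).
#' @export
classify_external <- function(regions, k = 20000, rank = 2, runs = 100,
                              seed = 1, specificity = 0.75) {
  keep <- rowSums(is.na(regions)) == 0L
  regions <- regions[keep, , drop = FALSE]
  if (nrow(regions) < 2L || ncol(regions) < 2L)
    stop("fewer than 2 complete regions or 2 samples after dropping missing rows")
  if (all(apply(regions, 1L, sd) == 0))
    stop("degenerate cohort: zero variance in every region")
  classify_epiclusters(regions, k = k, rank = rank, runs = runs, seed = seed,
                       specificity = specificity)
}
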