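#' Read a CpG site coordinate table (BED3)
#'
#' CpG sites are the strand-collapsed positions of the C of each CpG
#' dinucleotide, 0-based. The file is BED3 (`chrom`, `pos`, `pos + 1`),
#' sorted within chromosome. Sites receive a dense 0-based `site_index`
#' per chromosome; read-level haplotypes address CpGs by this rank so that
#' patterns are unambiguous under any reference assembly.
#'
#' @param path Path to a BED3 file. Lines starting with `#` are ignored.
#' @return A `data.table` with columns `chrom`, `pos`, `site_index`,
#'   positions strictly increasing within each chromosome.
#' @export
read_cpg_sites <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", col.names = c("chrom", "pos", "end3"))
  if (nrow(dt) == 0L) stop("empty CpG site table: ", path)
  if (any(dt$end3 != dt$pos + 1L)) stop("CpG site BED must have end = start + 1")
  dt[, end3 := NULL]
  cpg_site_table(dt$chrom, dt$pos)
}

#' Build a CpG site table from coordinates
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based positions.
#' @return A `data.table` with `chrom`, `pos`, `site_index` (dense, 0-based
#'   per chromosome, in position order).
#' @export
cpg_site_table <- function(chrom, pos) {
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos))
  setorder(dt, chrom, pos)
  if (dt[, any(diff(pos) <= 0L), by = chrom][, any(V1)])
    stop("CpG positions must be strictly increasing within a chromosome")
  dt[, site_index := seq_len(.N) - 1L, by = chrom]
  setkey(dt, chrom, site_index)
  dt[]
}

#' Write a CpG site table as BED3
#' @param sites A site table from [cpg_site_table()].
#' @param path Output path.
#' @export
write_cpg_sites <- function(sites, path) {
  fwrite(sites[, .(chrom, pos, pos + 1L)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read read-level methylation haplotypes
#'
#' The haplotype dialect is a TSV with columns `chrom`, `sample`,
#' `start_site_index`, `pattern`, `count`: one line per collapsed read-level
#' observation, `pattern` a string over `{'1','0'}` ('1' = methylated CpG)
#' covering consecutive CpG sites starting at rank `start_site_index` on
#' `chrom`, repeated `count` times. `#` lines are comments.
#'
#' @param path Path to the haplotype TSV.
#' @param sites CpG site table used to validate chromosome names and extents.
#' @return A `data.table` with columns `chrom`, `sample_id`, `start_index`,
#'   `pattern`, `count`.
#' @export
read_haplotypes <- function(path, sites) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  if (!length(lineno)) return(empty_haplotypes())
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L))
    stop("malformed haplotype line ", lineno[which(nf != 5L)[1L]], ": expected 5 tab-separated fields")
  m <- matrix(unlist(fields), ncol = 5L, byrow = TRUE)
  rec <- data.table(chrom = m[, 1L], sample_id = m[, 2L],
                    start_index = suppressWarnings(as.integer(m[, 3L])),
                    pattern = m[, 4L],
                    count = suppressWarnings(as.integer(m[, 5L])))
  bad <- which(is.na(rec$start_index) | rec$start_index < 0L)
  if (length(bad)) stop("invalid start_site_index at line ", lineno[bad[1L]])
  bad <- which(is.na(rec$count) | rec$count < 1L)
  if (length(bad)) stop("non-positive count at line ", lineno[bad[1L]])
  bad <- which(grepl("[^01]", rec$pattern) | nchar(rec$pattern) < 1L)
  if (length(bad)) stop("pattern with characters outside {0,1} at line ", lineno[bad[1L]])
  validate_haplotypes(rec, sites, lineno)
  rec
}

empty_haplotypes <- function() {
  data.table(chrom = character(), sample_id = character(),
             start_index = integer(), pattern = character(), count = integer())
}

validate_haplotypes <- function(rec, sites, lineno = seq_len(nrow(rec))) {
  nsite <- sites[, .(n_sites = .N), by = chrom]
  bad <- which(!rec$chrom %in% nsite$chrom)
  if (length(bad))
    stop("unknown chromosome '", rec$chrom[bad[1L]], "' at line ", lineno[bad[1L]])
  n <- nsite$n_sites[match(rec$chrom, nsite$chrom)]
  bad <- which(rec$start_index + nchar(rec$pattern) > n)
  if (length(bad))
    stop("haplotype extends past last CpG site at line ", lineno[bad[1L]])
  invisible(rec)
}

#' Write haplotype records in the haplotype TSV dialect
#' @param records Haplotype `data.table` as returned by [read_haplotypes()].
#' @param path Output path.
#' @export
write_haplotypes <- function(records, path) {
  fwrite(records[, .(chrom, sample_id, start_index, pattern, count)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read an array-style beta-value matrix with its probe manifest
#'
#' Values file: TSV, first column the probe id, remaining columns samples,
#' entries beta values in `[0,1]` or `NA`. Manifest: BED4
#' (`chrom`, `start`, `end`, `probe_id`) giving each probe's position.
#' Probes absent from the manifest are dropped with a message giving the count.
#'
#' @param values_path Path to the beta TSV.
#' @param manifest_path Path to the manifest BED4.
#' @return A list of class `beta_matrix`: `beta` (numeric matrix, probes x
#'   samples) and `probes` (`data.table` with `probe_id`, `chrom`, `pos`).
#' @export
read_beta_matrix <- function(values_path, manifest_path) {
  vals <- fread(values_path, header = TRUE, sep = "\t", na.strings = "NA")
  ids <- as.character(vals[[1L]])
  if (anyDuplicated(ids)) stop("duplicate probe id: ", ids[duplicated(ids)][1L])
  beta <- as.matrix(vals[, -1L, with = FALSE])
  rownames(beta) <- ids
  storage.mode(beta) <- "double"
  rng <- range(beta, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("beta value outside [0,1]")
  man <- fread(manifest_path, header = FALSE, sep = "\t",
               col.names = c("chrom", "start", "end", "probe_id"))
  if (anyDuplicated(man$probe_id)) stop("duplicate probe id in manifest")
  keep <- ids %in% man$probe_id
  if (any(!keep))
    message(sum(!keep), " probe(s) without manifest coordinates dropped")
  beta <- beta[keep, , drop = FALSE]
  probes <- man[match(rownames(beta), probe_id),
                .(probe_id, chrom, pos = as.integer(start))]
  structure(list(beta = beta, probes = probes), class = "beta_matrix")
}

#' Write a beta matrix and manifest
#' @param bm A `beta_matrix` object.
#' @param values_path,manifest_path Output paths.
#' @export
write_beta_matrix <- function(bm, values_path, manifest_path) {
  dt <- data.table(probe_id = rownames(bm$beta))
  dt <- cbind(dt, as.data.table(bm$beta))
  fwrite(dt, values_path, sep = "\t", na = "NA", quote = FALSE)
  fwrite(bm$probes[, .(chrom, pos, pos + 1L, probe_id)],
         manifest_path, sep = "\t", col.names = FALSE)
  invisible(values_path)
}

#' Read a clinical / survival table
#'
#' TSV with header `sample`, `os_time`, `os_event`, `pfs_time`, `pfs_event`,
#' followed by free covariate columns. Times are months; event flags are 0/1.
#' Empty covariate cells become `NA`.
#'
#' @param path Path to the clinical TSV.
#' @return A `data.frame` with one row per sample.
#' @export
read_clinical <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t", na.strings = c("", "NA"))
  need <- c("sample", "os_time", "os_event", "pfs_time", "pfs_event")
  if (!all(need %in% names(dt)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(dt$sample)) stop("duplicate sample id in clinical table")
  for (col in c("os_time", "pfs_time")) {
    x <- dt[[col]]
    if (any(!is.na(x) & x < 0)) stop("negative time in column ", col)
  }
  for (col in c("os_event", "pfs_event")) {
    x <- dt[[col]]
    if (any(!is.na(x) & !x %in% c(0, 1))) stop("non-binary event flag in column ", col)
  }
  as.data.frame(dt)
}

#' Write a clinical table
#' @param clinical Clinical `data.frame`.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  fwrite(clinical, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a genomic annotation track (BED4)
#'
#' Four columns: `chrom`, `start`, `end`, class label (e.g. a repeat family
#' or "promoter"). Intervals are 0-based half-open; overlapping intervals of
#' different classes are all retained.
#'
#' @param path Path to the BED4 file.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `class_label`.
#' @export
read_annotation_bed <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("malformed BED line ", lineno[which(nf != 4L)[1L]], ": expected 4 fields")
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  dt <- data.table(chrom = m[, 1L],
                   start = suppressWarnings(as.integer(m[, 2L])),
                   end = suppressWarnings(as.integer(m[, 3L])),
                   class_label = m[, 4L])
  bad <- which(is.na(dt$start) | is.na(dt$end))
  if (length(bad)) stop("malformed BED line ", lineno[bad[1L]])
  bad <- which(dt$start >= dt$end)
  if (length(bad)) stop("empty or inverted interval at line ", lineno[bad[1L]])
  dt
}

#' Read methylation haplotype blocks from BED4
#'
#' Blocks written by [write_blocks_bed()] carry only interval coordinates;
#' member CpG site indices are recovered against a site table: members are
#' all sites with `start <= pos < end`.
#'
#' @param path Path to the block BED4 (`chrom`, `start`, `end`, `block_id`).
#' @param sites CpG site table.
#' @return A block `data.table` (`block_id`, `chrom`, `start`, `end`,
#'   `first_index`, `last_index`).
#' @export
read_blocks_bed <- function(path, sites) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "block_id"))
  if (anyDuplicated(dt$block_id)) stop("duplicate block id")
  memb <- sites[dt, on = .(chrom, pos >= start, pos < end), nomatch = NULL,
                .(block_id = i.block_id, site_index = x.site_index)]
  idx <- memb[, .(first_index = min(site_index), last_index = max(site_index)),
              by = block_id]
  out <- idx[dt, on = "block_id"][, .(block_id, chrom, start, end, first_index, last_index)]
  if (anyNA(out$first_index)) stop("block contains no CpG site: ",
                                   out$block_id[is.na(out$first_index)][1L])
  setorder(out, chrom, start)
  out[]
}

#' Write blocks as BED4
#' @param blocks Block `data.table`.
#' @param path Output path.
#' @export
write_blocks_bed <- function(blocks, path) {
  fwrite(blocks[, .(chrom, start, end, block_id)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

#' Read an MHL (or any block-by-sample) matrix from TSV
#' @param path TSV with first column `block_id`, remaining columns samples;
#'   `NA` marks missing entries.
#' @return Numeric matrix, rows blocks, columns samples.
#' @export
read_mhl_matrix <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t", na.strings = "NA")
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Write an MHL matrix to TSV (missing entries as literal "NA")
#' @param m Numeric matrix with block-id rownames and sample colnames.
#' @param path Output path.
#' @export
write_mhl_matrix <- function(m, path) {
  dt <- data.table(block_id = rownames(m))
  dt <- cbind(dt, as.data.table(m))
  fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
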