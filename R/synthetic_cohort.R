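#' Configuration for the synthetic two-subtype cohort generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' two latent sample subtypes; a set of signature blocks hypermethylated
#' in one subtype by `delta`; read-level haplotypes whose within-read
#' concordance is controlled by a single mixing parameter `rho` (each CpG
#' copies the read's latent methylation state with probability `rho`, and
#' is drawn independently from the block's target level otherwise; `rho`
#' near 1 gives concordant haplotypes, 0 independent CpGs); Poisson read
#' coverage per block; exponential survival with a subtype hazard ratio
#' and independent censoring; and an array arm derived from the same
#' truth.
#'
#' @param n_samples Cohort size.
#' @param proportions Subtype proportions (Low, High); must sum to 1.
#' @param n_blocks Number of blocks.
#' @param n_signature_blocks Number of blocks hypermethylated in the High
#'   subtype.
#' @param cpgs_per_block Integer range (min, max) of member CpGs per block.
#' @param baseline_shape Beta distribution shape parameters for per-block
#'   baseline methylation.
#' @param delta Signature methylation shift in (0,1) added to signature
#'   blocks in the High subtype.
#' @param rho Within-read concordance in \[0,1\].
#' @param coverage Mean reads per block per sample (Poisson).
#' @param read_span `"full"` (reads span the whole block) or `"partial"`
#'   (each read covers a random contiguous stretch of >= 2 member CpGs).
#' @param hazard Baseline event hazard per month (exponential).
#' @param hazard_ratio Hazard ratio of the High subtype.
#' @param censor_frac Per-subject censoring probability.
#' @param probes_per_block Array probes per block.
#' @param beta_noise_sd Gaussian noise SD added to probe betas (clipped to
#'   \[0,1\]).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 50, proportions = c(0.5, 0.5),
                              n_blocks = 500, n_signature_blocks = 60,
                              cpgs_per_block = c(4, 8),
                              baseline_shape = c(2, 2), delta = 0.3,
                              rho = 0.9, coverage = 30,
                              read_span = c("full", "partial"),
                              hazard = 0.02, hazard_ratio = 3,
                              censor_frac = 0.3, probes_per_block = 10,
                              beta_noise_sd = 0.05) {
  read_span <- match.arg(read_span)
  cfg <- list(n_samples = n_samples, proportions = proportions,
              n_blocks = n_blocks, n_signature_blocks = n_signature_blocks,
              cpgs_per_block = cpgs_per_block,
              baseline_shape = baseline_shape, delta = delta, rho = rho,
              coverage = coverage, read_span = read_span, hazard = hazard,
              hazard_ratio = hazard_ratio, censor_frac = censor_frac,
              probes_per_block = probes_per_block,
              beta_noise_sd = beta_noise_sd)
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (length(proportions) != 2L) stop("exactly two subtypes are modelled")
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0,1)")
  if (rho < 0 || rho > 1) stop("rho must lie in [0,1]")
  if (coverage <= 0) stop("coverage must be positive")
  if (n_signature_blocks > n_blocks) stop("more signature blocks than blocks")
  if (censor_frac < 0 || censor_frac >= 1) stop("censor_frac must lie in [0,1)")
  if (probes_per_block < 1) stop("probes_per_block must be positive")
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic read-haplotype cohort with survival
#'
#' Draws a full synthetic study from a [simulation_config()]: CpG site
#' table and disjoint blocks on one synthetic chromosome, per-sample
#' read-level haplotypes, a clinical table, and the generating truth.
#' Subtype counts follow the configured proportions exactly (deterministic
#' allocation). Per block, a baseline methylation level is Beta-distributed;
#' signature-block baselines are rescaled into \[0.05, 0.65\] so the High
#' subtype's `+delta` shift never clips at 1. Per read, a latent state is
#' Bernoulli(target level) and CpGs copy it with probability `rho`.
#' Survival is exponential with the subject's hazard multiplied by
#' `hazard_ratio` for the High subtype; censoring is exponential with rate
#' `hazard * censor_frac / (1 - censor_frac)` scaled to the subject's
#' hazard, giving censoring probability `censor_frac` per subject.
#'
#' @param config A `simulation_config`.
#' @param seed Integer seed; the whole cohort is reproducible from
#'   (config, seed).
#' @return List with `haplotypes`, `sites`, `blocks`, `clinical`, and
#'   `truth` (sample subtypes, per-block targets and signature flags, and
#'   the config).
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  nb <- config$n_blocks
  k <- sample(config$cpgs_per_block[1L]:config$cpgs_per_block[2L], nb,
              replace = TRUE)
  # block geometry on one synthetic chromosome: ~30 bp CpG spacing, 1 kb gaps
  pos_list <- vector("list", nb)
  cur <- 1000L
  for (b in seq_len(nb)) {
    sp <- sample(15:45, k[b], replace = TRUE)
    pos_list[[b]] <- cur + cumsum(sp)
    cur <- pos_list[[b]][k[b]] + 1000L
  }
  sites <- cpg_site_table(rep("chr1", sum(k)), unlist(pos_list))
  first <- cumsum(c(0L, k[-nb]))
  last <- first + k - 1L
  start <- vapply(pos_list, `[`, integer(1), 1L)
  end <- vapply(pos_list, function(p) p[length(p)] + 1L, integer(1))
  blocks <- data.table(block_id = sprintf("chr1:%d-%d", start, end),
                       chrom = "chr1", start = start, end = end,
                       first_index = first, last_index = last)
  # truth: subtypes (exact proportions) and per-block targets
  n <- config$n_samples
  n_low <- round(config$proportions[1L] * n)
  samples <- sprintf("S%03d", seq_len(n))
  subtype <- rep(c("Low", "High"), c(n_low, n - n_low))
  sig <- rep(FALSE, nb)
  if (config$n_signature_blocks > 0)
    sig[sample.int(nb, config$n_signature_blocks)] <- TRUE
  base <- rbeta(nb, config$baseline_shape[1L], config$baseline_shape[2L])
  target_low <- ifelse(sig, 0.05 + 0.6 * base, base)
  target_high <- target_low + ifelse(sig, config$delta, 0)
  haplotypes <- draw_reads(blocks, k, samples, subtype, target_low,
                           target_high, config)
  clinical <- draw_clinical(samples, subtype, config)
  truth <- list(samples = data.table(sample_id = samples, subtype = subtype),
                blocks = data.table(block_id = blocks$block_id,
                                    signature = sig,
                                    target_low = target_low,
                                    target_high = target_high),
                config = config)
  list(haplotypes = haplotypes, sites = sites, blocks = blocks,
       clinical = clinical, truth = truth)
}

draw_reads <- function(blocks, k, samples, subtype, target_low, target_high,
                       config) {
  nb <- nrow(blocks)
  n <- length(samples)
  grid <- data.table(b = rep(seq_len(nb), each = n),
                     s = rep(seq_len(n), times = nb))
  grid[, nread := rpois(.N, config$coverage)]
  grid <- grid[nread > 0L]
  reads <- grid[rep(seq_len(.N), nread)]
  N <- nrow(reads)
  t_read <- ifelse(subtype[reads$s] == "High",
                   target_high[reads$b], target_low[reads$b])
  kb <- k[reads$b]
  lo <- rep(1L, N)
  hi <- kb
  if (config$read_span == "partial") {
    span <- pmin(kb, 2L + floor(runif(N) * (kb - 1L)))
    lo <- 1L + floor(runif(N) * (kb - span + 1L))
    hi <- lo + span - 1L
  }
  len <- hi - lo + 1L
  z <- rbinom(N, 1L, t_read)
  pats <- character(N)
  for (m in sort(unique(len))) {
    ix <- which(len == m)
    nm <- length(ix)
    keep <- matrix(runif(nm * m) < config$rho, nm, m)
    ind <- matrix(rbinom(nm * m, 1L, rep(t_read[ix], m)), nm, m)
    st <- ifelse(keep, z[ix], ind)
    pats[ix] <- do.call(paste0, as.data.frame(st))
  }
  rec <- data.table(chrom = "chr1", sample_id = samples[reads$s],
                    start_index = blocks$first_index[reads$b] + lo - 1L,
                    pattern = pats, count = 1L)
  rec <- rec[, .(count = sum(count)),
             by = .(chrom, sample_id, start_index, pattern)]
  setorder(rec, sample_id, start_index, pattern)
  rec[]
}

draw_clinical <- function(samples, subtype, config) {
  n <- length(samples)
  rate <- config$hazard * ifelse(subtype == "High", config$hazard_ratio, 1)
  f <- config$censor_frac
  draw_endpoint <- function(mult) {
    ev_t <- rexp(n, rate * mult)
    cn_t <- if (f > 0) rexp(n, rate * mult * f / (1 - f)) else rep(Inf, n)
    list(time = round(pmin(ev_t, cn_t), 2), event = as.integer(ev_t <= cn_t))
  }
  os <- draw_endpoint(1)
  pfs <- draw_endpoint(1.5)      # progression precedes death on average
  data.frame(sample = samples, os_time = os$time, os_event = os$event,
             pfs_time = pmin(pfs$time, os$time), pfs_event = pfs$event,
             age = round(stats::rnorm(n, 65, 9)),
             stringsAsFactors = FALSE)
}

#' Generate an array-style cohort from an existing truth
#'
#' Emulates the array validation arm: probes are placed at member CpG
#' positions of each block (sampled with replacement when
#' `probes_per_block` exceeds the block's CpG count), and each probe's
#' beta value is the sample's block target level plus Gaussian noise,
#' clipped to \[0,1\].
#'
#' @param cohort A cohort from [generate_cohort()] (its `truth` and
#'   `blocks`/`sites` are used).
#' @param seed Integer seed.
#' @return A `beta_matrix` object (see [read_beta_matrix()]).
#' @export
generate_array_cohort <- function(cohort, seed = 1) {
  set.seed(seed)
  config <- cohort$truth$config
  blocks <- cohort$blocks
  sites <- cohort$sites
  tr <- cohort$truth
  ppb <- config$probes_per_block
  probe_rows <- lapply(seq_len(nrow(blocks)), function(b) {
    memb <- sites[chrom == blocks$chrom[b] &
                    site_index >= blocks$first_index[b] &
                    site_index <= blocks$last_index[b], pos]
    data.table(chrom = blocks$chrom[b],
               pos = sort(sample(memb, ppb, replace = ppb > length(memb))),
               block = b)
  })
  probes <- rbindlist(probe_rows)
  probes[, probe_id := sprintf("cg%06d", seq_len(.N))]
  n <- nrow(tr$samples)
  target <- ifelse(matrix(tr$samples$subtype, nrow(probes), n,
                          byrow = TRUE) == "High",
                   tr$blocks$target_high[probes$block],
                   tr$blocks$target_low[probes$block])
  noise <- matrix(stats::rnorm(nrow(probes) * n, 0, config$beta_noise_sd),
                  nrow(probes), n)
  beta <- pmin(pmax(target + noise, 0), 1)
  dimnames(beta) <- list(probes$probe_id, tr$samples$sample_id)
  structure(list(beta = beta,
                 probes = probes[, .(probe_id, chrom, pos)]),
            class = "beta_matrix")
}

#' Generate a null cohort (no signature blocks, hazard ratio 1)
#'
#' Both subtypes are statistically identical; used for type-I error and
#' false-labelling checks.
#'
#' @param config A `simulation_config`; its `n_signature_blocks` and
#'   `hazard_ratio` are overridden.
#' @param seed Integer seed.
#' @return As [generate_cohort()].
#' @export
generate_null_cohort <- function(config = simulation_config(), seed = 1) {
  config$n_signature_blocks <- 0L
  config$hazard_ratio <- 1
  generate_cohort(config, seed)
}
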