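#' Select the most variable blocks
#'
#' Ranks rows by the standard deviation of MHL across samples and keeps the
#' `k` largest (default 20,000), the usual feature-selection step before
#' factorization. Requires a complete matrix; run [filter_missing_blocks()]
#' first.
#'
#' @param m Complete MHL matrix.
#' @param k Number of rows to keep.
#' @return The row subset, ordered by decreasing standard deviation.
#' @export
select_top_variable <- function(m, k = 20000) {
  if (anyNA(m))
    stop("matrix has missing entries; apply filter_missing_blocks() first")
  stopifnot(k >= 1)
  sds <- apply(m, 1L, sd)
  if (k > nrow(m)) {
    warning("k = ", k, " exceeds available rows (", nrow(m), "); returning all")
    k <- nrow(m)
  }
  m[order(sds, decreasing = TRUE)[seq_len(k)], , drop = FALSE]
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix V (blocks x samples) as W H with
#' W >= 0 (blocks x rank) and H >= 0 (rank x samples) under the Frobenius
#' objective, using Lee-Seung multiplicative updates. The factorization is
#' restarted `runs` times from seeded random initializations and the run
#' with the lowest reconstruction error is kept; one master seed spawns a
#' per-run seed stream, so results for `runs = r` are a prefix of those for
#' any larger run count.
#'
#' @param m Complete non-negative matrix.
#' @param rank Number of components (default 2).
#' @param runs Number of random restarts (default 100).
#' @param seed Master seed.
#' @param max_iter Maximum update iterations per run.
#' @param tol Convergence threshold on the relative change of the
#'   reconstruction error.
#' @return An object of class `nmf_model`: `W`, `H`, `error` (best
#'   relative Frobenius error), `run_errors`, `best_run`, `runs`, `seed`,
#'   `iterations` of the best run.
#' @export
nmf_factorize <- function(m, rank = 2, runs = 100, seed = 1,
                          max_iter = 500, tol = 1e-6) {
  if (anyNA(m)) stop("matrix has missing entries")
  if (any(m < 0)) stop("matrix must be non-negative")
  if (all(m == 0)) stop("all-zero matrix cannot be factorized")
  if (rank > min(dim(m))) stop("rank exceeds matrix dimensions")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, runs)
  vnorm <- sqrt(sum(m^2))
  best <- NULL
  run_errors <- numeric(runs)
  for (r in seq_len(runs)) {
    fit <- nmf_single_run(m, rank, run_seeds[r], max_iter, tol, vnorm)
    run_errors[r] <- fit$error
    if (is.null(best) || fit$error < best$error) {
      best <- fit
      best$best_run <- r
    }
  }
  structure(list(W = best$W, H = best$H, error = best$error,
                 run_errors = run_errors, best_run = best$best_run,
                 runs = runs, seed = seed, iterations = best$iterations),
            class = "nmf_model")
}

nmf_single_run <- function(m, rank, seed, max_iter, tol, vnorm) {
  set.seed(seed)
  eps <- .Machine$double.eps
  n <- nrow(m); p <- ncol(m)
  scale0 <- sqrt(mean(m) / rank)
  W <- matrix(runif(n * rank), n, rank) * scale0
  H <- matrix(runif(rank * p), rank, p) * scale0
  err_prev <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    H <- H * (crossprod(W, m) / (crossprod(W) %*% H + eps))
    W <- W * (m %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err <- sqrt(sum((m - W %*% H)^2)) / vnorm
    if (it >= max_iter || (is.finite(err_prev) && abs(err_prev - err) <
                           tol * max(err_prev, eps))) break
    err_prev <- err
  }
  list(W = W, H = H, error = err, iterations = it)
}

#' @export
print.nmf_model <- function(x, ...) {
  cat("rank-", ncol(x$W), " NMF model: ", nrow(x$W), " blocks x ",
      ncol(x$H), " samples\n", sep = "")
  cat("best of ", x$runs, " runs (run ", x$best_run,
      "), relative error ", signif(x$error, 4), "\n", sep = "")
  invisible(x)
}

#' Extract per-component signature blocks from an NMF basis
#'
#' Each basis row is normalized to sum 1; a block is a component's
#' signature if its normalized weight on that component is at least
#' `specificity` and its unnormalized row maximum is at least the median
#' row maximum (filtering out low-magnitude rows). Balanced or weak rows
#' are assigned to no component; the signature sets are disjoint.
#'
#' @param model An `nmf_model`.
#' @param specificity Normalized-weight threshold in (0.5, 1\].
#' @return A list of block-id character vectors, one per component.
#' @export
extract_component_features <- function(model, specificity = 0.75) {
  W <- model$W
  rmax <- apply(W, 1L, max)
  rsum <- rowSums(W)
  norm <- W / ifelse(rsum > 0, rsum, 1)
  strong <- rmax >= median(rmax)
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  lapply(seq_len(ncol(W)), function(k)
    ids[strong & rsum > 0 & norm[, k] >= specificity])
}

#' Assign samples to components and label epi-clusters
#'
#' Each sample goes to the component with its maximum coefficient in H
#' (ties to the lower component index). Clusters are then labelled by mean
#' MHL over the union of the signature blocks: the cluster with the higher
#' mean is `Methy-High` (the hypermethylated epi-cluster), the other
#' `Methy-Low`. If a component has an empty signature set, labelling falls
#' back, with a warning, to the mean over all selected blocks.
#'
#' @param model An `nmf_model` fitted on `m`.
#' @param features Signature sets from [extract_component_features()].
#' @param m The matrix the model was fitted on.
#' @return A `data.frame` with columns `sample`, `component`, `label`; the
#'   signature sets are attached as attribute `"signatures"` named by the
#'   component labels.
#' @export
assign_and_label <- function(model, features, m) {
  H <- model$H
  comp <- apply(H, 2L, which.max)            # which.max breaks ties low
  samples <- colnames(m)
  if (is.null(samples)) samples <- as.character(seq_len(ncol(m)))
  sig_union <- unique(unlist(features))
  if (any(lengths(features) == 0L)) {
    warning("component with empty signature set; labelling on all blocks")
    sig_union <- rownames(m)
  }
  cl_mean <- vapply(seq_len(nrow(H)), function(k) {
    in_cl <- comp == k
    if (!any(in_cl)) return(NA_real_)
    mean(m[sig_union, in_cl, drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  hi <- if (all(is.na(cl_mean))) 1L else which.max(cl_mean)
  labels <- ifelse(seq_len(nrow(H)) == hi, "Methy-High", "Methy-Low")
  out <- data.frame(sample = samples, component = as.integer(comp),
                    label = labels[comp], stringsAsFactors = FALSE)
  attr(out, "signatures") <- setNames(features, labels[seq_along(features)])
  out
}

#' Epi-cluster discovery from an MHL matrix
#'
#' Convenience pipeline: drop incomplete rows, select the `k` most variable
#' blocks, fit a rank-2 consensus NMF, extract component signatures and
#' label samples Methy-High / Methy-Low.
#'
#' @inheritParams nmf_factorize
#' @inheritParams select_top_variable
#' @inheritParams extract_component_features
#' @return The assignment `data.frame` from [assign_and_label()], with the
#'   fitted `nmf_model` attached as attribute `"model"`.
#' @export
classify_epiclusters <- function(m, k = 20000, rank = 2, runs = 100, seed = 1,
                                 specificity = 0.75, max_iter = 500,
                                 tol = 1e-6) {
  mm <- filter_missing_blocks(m, "any")
  sel <- suppressWarnings(select_top_variable(mm, k))
  model <- nmf_factorize(sel, rank = rank, runs = runs, seed = seed,
                         max_iter = max_iter, tol = tol)
  feats <- extract_component_features(model, specificity)
  out <- assign_and_label(model, feats, sel)
  attr(out, "model") <- model
  out
}

#' Cluster size proportions
#'
#' Reports each cluster's share of the cohort as a percentage rounded to
#' one decimal, e.g. cluster sizes 19 and 26 of a 45-sample cohort give
#' 42.2 and 57.8.
#'
#' @param sizes Named or unnamed integer vector of cluster sizes.
#' @return Numeric vector of percentages summing to ~100.
#' @export
cluster_proportions <- function(sizes) {
  stopifnot(all(sizes >= 0), sum(sizes) > 0)
  round(100 * sizes / sum(sizes), 1)
}
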