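#' Elementwise exponential transform
#'
#' Maps a signature matrix through e^x so that every entry is strictly
#' positive, the standard preparation of a signed pairwise-signature matrix
#' for non-negative factorization. Monotone, so within-column orderings are
#' preserved; the +/-1 indicator maps to {1/e, e}.
#'
#' @param x Numeric matrix or vector with finite entries.
#' @return exp(x), same shape.
#' @export
exp_transform <- function(x) {
  if (!all(is.finite(x))) stop("input must be finite")
  exp(x)
}

.kl_div <- function(V, WH) {
  # KL(V || WH) = sum(V log(V/WH) - V + WH), 0 log 0 = 0
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

#' Non-negative matrix factorization by multiplicative KL updates
#'
#' The classical KL-divergence NMF ("brunet" flavour): starting from uniform
#' random positive factors, W and H are updated multiplicatively; each step
#' is guaranteed not to increase the KL divergence between V and WH, which
#' the returned objective trace records. Stops when the relative objective
#' change drops below `tol` or after `max_iter` sweeps. Factors are floored
#' at a small epsilon so they remain strictly positive.
#'
#' @param V Nonnegative numeric matrix (features x samples), no all-zero rows.
#' @param k Factorization rank, 2 <= k < min(dim(V)).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum update sweeps (default 2000).
#' @param tol Relative objective-change tolerance (default 1e-6).
#' @return List with `W` (features x k), `H` (k x samples), `trace`
#'   (KL objective per recorded iteration), `iterations`, `seed`.
#' @export
nmf_factorize <- function(V, k, seed = 1L, max_iter = 2000L, tol = 1e-6) {
  stopifnot(is.matrix(V), is.numeric(V))
  if (any(V < 0)) {
    stop("V has negative entries; apply exp_transform() first")
  }
  if (any(rowSums(V) == 0)) stop("V has an all-zero row")
  if (k < 2L || k >= min(dim(V))) stop("rank k must satisfy 2 <= k < min(dim(V))")
  eps <- 1e-12
  set.seed(seed)
  scale <- mean(V)
  W <- matrix(stats::runif(nrow(V) * k), nrow(V), k) * scale
  H <- matrix(stats::runif(k * ncol(V)), k, ncol(V))
  WH <- W %*% H
  obj <- .kl_div(V, WH)
  trace <- obj
  for (it in seq_len(max_iter)) {
    # H update: H <- H * (W' (V/WH)) / colSums(W)
    H <- H * (crossprod(W, V / WH)) / colSums(W)
    H[H < eps] <- eps
    WH <- W %*% H
    # W update: W <- W * ((V/WH) H') / rowSums(H)
    W <- W * ((V / WH) %*% t(H)) / rep(rowSums(H), each = nrow(W))
    W[W < eps] <- eps
    WH <- W %*% H
    new_obj <- .kl_div(V, WH)
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) <= tol * max(abs(obj), eps)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  list(W = W, H = H, trace = trace, iterations = length(trace) - 1L, seed = seed)
}

#' Consensus NMF clustering over random restarts
#'
#' For each candidate rank k, runs `nrun` seeded factorizations; each run
#' assigns every sample to the argmax row of its H column, runs are combined
#' into a consensus matrix (mean co-clustering indicator), and rank-quality
#' metrics are computed: the cophenetic correlation between consensus
#' distances (1 - consensus) and the dendrogram distances of their
#' average-linkage hierarchical clustering, the dispersion
#' mean(4 (c - 1/2)^2), and the mean silhouette width on 1 - consensus.
#' Final sample assignments per k come from cutting that dendrogram into k
#' groups, labelled in decreasing cluster size (cluster 1 is the largest).
#'
#' @param V Nonnegative matrix, features x samples.
#' @param k_range Candidate ranks (default 2:6).
#' @param nrun Restarts per rank (default 10).
#' @param seed Base seed; run r of rank k uses seed + 1000 * k + r.
#' @param max_iter,tol Passed to [nmf_factorize()].
#' @return List with `metrics` (data.frame: k, cophenetic, dispersion,
#'   silhouette) and `results`, a per-k list holding `consensus`,
#'   `assignments` and the per-run seeds.
#' @export
consensus_cluster <- function(V, k_range = 2:6, nrun = 10L, seed = 1L,
                              max_iter = 2000L, tol = 1e-6) {
  stopifnot(nrun >= 2L)
  n <- ncol(V)
  if (any(k_range < 2L) || any(k_range >= min(dim(V)))) {
    stop("k_range outside valid ranks for this matrix")
  }
  results <- list()
  metrics <- data.frame(k = integer(0), cophenetic = numeric(0),
                        dispersion = numeric(0), silhouette = numeric(0))
  for (k in k_range) {
    consensus <- matrix(0, n, n)
    for (r in seq_len(nrun)) {
      fit <- nmf_factorize(V, k, seed = seed + 1000L * k + r,
                           max_iter = max_iter, tol = tol)
      cl <- apply(fit$H, 2L, which.max)
      consensus <- consensus + outer(cl, cl, "==")
    }
    consensus <- consensus / nrun
    dimnames(consensus) <- list(colnames(V), colnames(V))
    d <- stats::as.dist(1 - consensus)
    hc <- stats::hclust(d, method = "average")
    coph <- suppressWarnings(stats::cor(d, stats::cophenetic(hc)))
    if (is.na(coph)) coph <- 1  # zero-variance distances: perfectly stable
    dispersion <- mean(4 * (consensus - 0.5)^2)
    assign_raw <- stats::cutree(hc, k = k)
    # canonical labels: decreasing cluster size
    sizes <- table(assign_raw)
    relabel <- stats::setNames(seq_along(sizes),
                               names(sort(sizes, decreasing = TRUE)))
    assignments <- unname(relabel[as.character(assign_raw)])
    names(assignments) <- colnames(V)
    sil <- if (length(unique(assignments)) > 1L) {
      mean(cluster::silhouette(assignments, d)[, "sil_width"])
    } else NA_real_
    metrics <- rbind(metrics, data.frame(k = k, cophenetic = coph,
                                         dispersion = dispersion,
                                         silhouette = sil))
    results[[as.character(k)]] <- list(consensus = consensus,
                                       assignments = assignments,
                                       seeds = seed + 1000L * k + seq_len(nrun))
  }
  list(metrics = metrics, results = results)
}

#' Choose the factorization rank from consensus metrics
#'
#' Returns the smallest k attaining the maximum cophenetic correlation; ties
#' are broken by higher dispersion, then higher mean silhouette, then the
#' smaller k.
#'
#' @param metrics Data frame from [consensus_cluster()] with columns `k`,
#'   `cophenetic`, `dispersion`, `silhouette`.
#' @return The chosen integer rank.
#' @export
select_rank <- function(metrics) {
  stopifnot(nrow(metrics) >= 2L)
  ord <- order(-metrics$cophenetic, -metrics$dispersion,
               -ifelse(is.na(metrics$silhouette), -Inf, metrics$silhouette),
               metrics$k)
  metrics$k[ord[1L]]
}

#' Subtype case samples from their significant pairwise signatures
#'
#' Convenience wrapper for the subtyping stage: restricts the signature
#' matrix to the flagged pairs and the case samples, exponentiates to make
#' it nonnegative, and runs consensus NMF over a rank range.
#'
#' @param mpp An `mpp_matrix`.
#' @param flagged_pairs Pair ids to keep (e.g. the screen's flagged set).
#' @param case_samples Sample ids to cluster.
#' @param representation "continuous" (delta) or "discrete" (indicator)
#'   values to feed the transform (default continuous).
#' @param k_range,nrun,seed,max_iter,tol Passed to [consensus_cluster()].
#' @return As [consensus_cluster()], plus `k` (the selected rank) and
#'   `assignments` for the selected rank.
#' @export
nmf_subtype <- function(mpp, flagged_pairs, case_samples,
                        representation = c("continuous", "discrete"),
                        k_range = 2:6, nrun = 10L, seed = 1L,
                        max_iter = 2000L, tol = 1e-6) {
  representation <- match.arg(representation)
  mat <- if (representation == "continuous") mpp$delta else mpp$indicator
  keep <- mpp$pair_ids %in% flagged_pairs
  if (!any(keep)) stop("no flagged pairs present in the signature matrix")
  cols <- colnames(mat) %in% case_samples
  if (sum(cols) < 4L) stop("too few case samples to cluster")
  V <- exp_transform(mat[keep, cols, drop = FALSE])
  valid <- k_range[k_range < min(dim(V))]
  if (length(valid) < length(k_range)) {
    warning("k_range truncated to ranks below min(dim) = ", min(dim(V)))
  }
  if (length(valid) < 2L) stop("fewer than 2 valid ranks for this matrix")
  cc <- consensus_cluster(V, k_range = valid, nrun = nrun, seed = seed,
                          max_iter = max_iter, tol = tol)
  k <- select_rank(cc$metrics)
  cc$k <- k
  cc$assignments <- cc$results[[as.character(k)]]$assignments
  cc
}
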