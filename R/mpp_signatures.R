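#' Build the pathway-pairwise (MPP) signature matrix
#'
#' For every unordered pathway pair (i, j) with i < j in catalog order, and
#' every sample k, stores both the continuous contrast
#' `delta = MP_i - MP_j` of the two ssGSEA activities and the discrete
#' ordering indicator `r = +1` if `delta >= 0`, `-1` otherwise (ties count
#' as +1 by convention). With m pathways there are choose(m, 2) pairs; rows
#' are ordered lexicographically in (i, j), and pair ids are "idA-idB" with
#' the lower catalog index first.
#'
#' Because both representations are within-sample contrasts of ranks, they
#' are insensitive to any per-sample monotone rescaling of expression and to
#' the global activity normalisation, which is what makes the signatures
#' portable across cohorts without batch correction.
#'
#' @param activity Pathways-by-samples activity matrix (rows in catalog
#'   order, row names are pathway ids), e.g. from [ssgsea_matrix()].
#' @return An `mpp_matrix`: list with `pair_ids`, `delta` and `indicator`
#'   (both choose(m,2) x n matrices), and `sample_ids`.
#' @export
build_mpp <- function(activity) {
  stopifnot(is.matrix(activity), is.numeric(activity))
  m <- nrow(activity)
  if (m < 2L) stop("need at least 2 pathways to form pairs")
  ids <- rownames(activity)
  if (is.null(ids)) ids <- paste0("P", seq_len(m))
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  delta <- activity[idx[, 1L], , drop = FALSE] - activity[idx[, 2L], , drop = FALSE]
  pair_ids <- paste0(ids[idx[, 1L]], "-", ids[idx[, 2L]])
  dimnames(delta) <- list(pair_ids, colnames(activity))
  indicator <- ifelse(delta >= 0, 1, -1)
  structure(list(pair_ids = pair_ids, delta = delta, indicator = indicator,
                 sample_ids = colnames(activity)),
            class = "mpp_matrix")
}

#' @export
print.mpp_matrix <- function(x, ...) {
  cat("mpp_matrix:", length(x$pair_ids), "pathway pairs x",
      ncol(x$delta), "samples\n")
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' One-degree-of-freedom Pearson test without continuity correction, the form
#' used for the pairwise ordering screen (rows = groups, columns = ordering
#' of the two pathway activities).
#'
#' @param a,b Counts in the first group (e.g. controls) with ordering +1 / -1.
#' @param c,d Counts in the second group (e.g. cases) with ordering +1 / -1.
#' @return List with `chi2` and two-sided `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  tab <- matrix(counts, nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero row or column margin")
  }
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Holm step-down multiple-testing adjustment
#'
#' Familywise-error-controlling step-down procedure: the k-th smallest p is
#' multiplied by (M - k + 1), a running maximum is enforced, and values are
#' capped at 1; results are returned in input order.
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Differential screen of pairwise ordering signatures
#'
#' For each pathway pair, counts per group how many samples order the pair
#' +1 vs -1 (the 2x2 count test), tests association with the group label by
#' the Pearson chi-square (1 df, no continuity correction), and applies the
#' Holm adjustment across all testable pairs. Pairs whose table has a zero
#' margin (e.g. an ordering constant across every sample) carry no test and
#' are excluded from the Holm family rather than assigned p = 1; they are
#' reported with NA statistics and a `skipped` flag.
#'
#' @param mpp An `mpp_matrix`.
#' @param groups Group label per sample (exactly two distinct labels);
#'   character or factor, in sample order.
#' @param alpha_adj Adjusted-p significance threshold (default 0.01).
#' @param reference Optional label to treat as the first (control) row of the
#'   table; defaults to the first level encountered.
#' @return Data frame with one row per pair: `pair_id`, counts `a`, `b`
#'   (reference group, ordering +1 / -1), `c`, `d` (other group), `chi2`,
#'   `p`, `p_adj`, `flagged`, `skipped`.
#' @export
differential_screen <- function(mpp, groups, alpha_adj = 0.01, reference = NULL) {
  stopifnot(inherits(mpp, "mpp_matrix"))
  groups <- as.character(groups)
  if (length(groups) != ncol(mpp$indicator)) {
    stop("one group label per sample required")
  }
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required, got ", length(lev))
  if (!is.null(reference)) {
    if (!reference %in% lev) stop("reference label not present")
    lev <- c(reference, setdiff(lev, reference))
  }
  g1 <- groups == lev[1L]
  ind <- mpp$indicator
  a <- rowSums(ind[, g1, drop = FALSE] == 1)
  b <- rowSums(ind[, g1, drop = FALSE] == -1)
  cc <- rowSums(ind[, !g1, drop = FALSE] == 1)
  d <- rowSums(ind[, !g1, drop = FALSE] == -1)
  # zero column margin <=> ordering constant over all samples (row margins
  # are the group sizes, always positive here)
  skipped <- (a + cc == 0) | (b + d == 0)
  chi2 <- p <- rep(NA_real_, length(a))
  for (i in which(!skipped)) {
    e_row <- c(a[i] + b[i], cc[i] + d[i])
    e_col <- c(a[i] + cc[i], b[i] + d[i])
    n <- sum(a[i], b[i], cc[i], d[i])
    expd <- outer(e_row, e_col) / n
    obs <- matrix(c(a[i], b[i], cc[i], d[i]), 2L, byrow = TRUE)
    chi2[i] <- sum((obs - expd)^2 / expd)
    p[i] <- stats::pchisq(chi2[i], df = 1L, lower.tail = FALSE)
  }
  p_adj <- rep(NA_real_, length(p))
  p_adj[!skipped] <- holm_adjust(p[!skipped])
  data.frame(pair_id = mpp$pair_ids, a = a, b = b, c = cc, d = d,
             chi2 = chi2, p = p, p_adj = p_adj,
             flagged = !is.na(p_adj) & p_adj < alpha_adj,
             skipped = skipped, row.names = NULL)
}
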