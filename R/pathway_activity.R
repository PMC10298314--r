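#' Single-sample gene-set enrichment score for one sample
#'
#' Rank-weighted running-sum statistic: genes are ordered by decreasing
#' expression (ties broken by input order, so the statistic is deterministic),
#' each gene at position p gets rank weight rho = N + 1 - p, and the score is
#' the sum over positions of the gap between the weighted in-set ECDF
#' (weights rho^alpha, normalised over the set) and the unweighted out-of-set
#' ECDF. Depends on the sample's expression only through ranks, so any
#' strictly increasing per-sample transformation leaves it unchanged.
#'
#' @param expression Named numeric vector, one sample's expression (names are
#'   gene ids).
#' @param gene_set Character vector of gene symbols.
#' @param alpha Rank-weight exponent, >= 0. `alpha = 0` gives the plain
#'   Kolmogorov-Smirnov-style running sum.
#' @return A single numeric enrichment score.
#' @export
ssgsea_sample <- function(expression, gene_set, alpha = 0.25) {
  stopifnot(is.numeric(expression), !is.null(names(expression)), alpha >= 0)
  in_set <- names(expression) %in% gene_set
  if (!any(in_set)) stop("gene set shares no genes with the expression vector")
  if (all(in_set)) stop("gene set covers every expression row; complement is empty")
  n <- length(expression)
  # decreasing sort, stable in input order for ties
  ord <- order(-expression)
  in_ord <- in_set[ord]
  rho <- (n:1)^alpha
  p_in <- cumsum(rho * in_ord) / sum(rho[in_ord])
  p_out <- cumsum(!in_ord) / sum(!in_ord)
  sum(p_in - p_out)
}

#' Pathway activity matrix by ssGSEA
#'
#' Scores every catalog pathway in every sample. Genes absent from the
#' expression matrix are dropped from each set (recorded in the `coverage`
#' attribute); a pathway retaining fewer than `min_genes` genes is an error,
#' since its score would be dominated by a single gene. With
#' `normalize = TRUE` all scores are divided by the global score range
#' (max - min over the whole matrix), the conventional ssGSEA
#' normalisation; this is one positive global factor, so every
#' within-sample pairwise ordering is unchanged.
#'
#' @param expr An `expr_dataset` or a numeric genes-by-samples matrix.
#' @param catalog A `gene_set_catalog`.
#' @param alpha Rank-weight exponent (default 0.25, the conventional choice).
#' @param normalize Divide by the global score range (default TRUE).
#' @param min_genes Minimum genes a pathway must retain (default 2).
#' @return Numeric matrix, pathways x samples, rows in catalog order, with
#'   attributes `alpha`, `normalized` and `coverage` (genes retained per
#'   pathway).
#' @export
ssgsea_matrix <- function(expr, catalog, alpha = 0.25, normalize = TRUE,
                          min_genes = 2L) {
  values <- if (inherits(expr, "expr_dataset")) expr$values else expr
  stopifnot(is.matrix(values), is.numeric(values))
  if (n_pathways(catalog) < 1L) stop("empty catalog")
  genes <- rownames(values)
  n <- length(genes)
  kept <- lapply(catalog$genes, function(g) intersect(g, genes))
  coverage <- lengths(kept)
  low <- which(coverage < min_genes)
  if (length(low)) {
    stop("pathway(s) with fewer than ", min_genes, " genes in the matrix: ",
         paste(catalog$ids[low], collapse = ", "))
  }
  if (any(coverage == n)) {
    stop("pathway covers every expression row: ",
         catalog$ids[which(coverage == n)[1L]])
  }
  in_mask <- vapply(kept, function(g) genes %in% g, logical(n))  # n x m
  rho_all <- (n:1)^alpha
  scores <- apply(values, 2L, function(col) {
    ord <- order(-col)
    masks <- in_mask[ord, , drop = FALSE]
    vapply(seq_len(ncol(masks)), function(j) {
      io <- masks[, j]
      sum(cumsum(rho_all * io) / sum(rho_all[io]) - cumsum(!io) / sum(!io))
    }, 0)
  })
  scores <- matrix(scores, nrow = n_pathways(catalog),
                   dimnames = list(catalog$ids, colnames(values)))
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(scores, alpha = alpha, normalized = normalize, coverage = coverage)
}
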