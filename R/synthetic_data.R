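#' Configuration for the synthetic expression generator
#'
#' Describes an additive Gaussian model on the log-expression scale: every
#' gene g has a baseline mean mu_g ~ Normal(mu0, sd0^2) shared by all
#' samples, pathways occupy disjoint gene blocks drawn from the pool, group
#' or subtype membership adds the configured shift to every gene of the
#' named pathway, and i.i.d. Normal(0, sd^2) noise is added on top. Cases
#' ("AD") are split into two planted subtypes S1 and S2; an effect with
#' group "AD" applies to both subtypes, "S1"/"S2" to one.
#'
#' Defaults are the package's stated desk-scale world: 10 pathways of 30
#' genes plus 300 unannotated background genes, 60 controls and 40 + 30
#' cases, baseline mean 6 and gene-level sd 1 (log2 microarray-like), noise
#' sd 0.5.
#'
#' @param n_background_genes Genes outside every pathway.
#' @param m_pathways Number of pathways.
#' @param genes_per_pathway Genes per pathway block.
#' @param n_nonAD,n_S1,n_S2 Samples per group (controls, subtype 1, subtype 2).
#' @param mu0 Baseline log-expression mean.
#' @param sd0 Between-gene baseline sd.
#' @param sd Residual noise sd.
#' @param effects Data frame with columns `pathway` (id), `group` (one of
#'   "AD", "S1", "S2") and `delta` (additive shift, log-expression units);
#'   NULL for a null model.
#' @param batch_effects Optional data frame with columns `batch` and `delta`
#'   giving per-batch intercepts; batches are assigned round-robin. NULL for
#'   a single batch.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_background_genes = 300L, m_pathways = 10L,
                       genes_per_pathway = 30L,
                       n_nonAD = 60L, n_S1 = 40L, n_S2 = 30L,
                       mu0 = 6, sd0 = 1, sd = 0.5,
                       effects = NULL, batch_effects = NULL) {
  stopifnot(n_background_genes >= 0, m_pathways > 0, genes_per_pathway > 1,
            n_nonAD > 0, n_S1 > 0, n_S2 > 0, sd >= 0, sd0 >= 0)
  if (!is.null(effects)) {
    stopifnot(all(c("pathway", "group", "delta") %in% colnames(effects)))
    if (!all(effects$group %in% c("AD", "S1", "S2"))) {
      stop("effect group must be one of AD, S1, S2")
    }
  }
  structure(list(n_background_genes = as.integer(n_background_genes),
                 m_pathways = as.integer(m_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 n_nonAD = as.integer(n_nonAD), n_S1 = as.integer(n_S1),
                 n_S2 = as.integer(n_S2), mu0 = mu0, sd0 = sd0, sd = sd,
                 effects = effects, batch_effects = batch_effects),
            class = "sim_config")
}

#' Generate a synthetic cohort with planted pathway effects
#'
#' Draws an expression dataset, its pathway catalog, and the ground truth
#' needed for recovery tests: per-sample group/subtype labels, per-pathway
#' planted shifts, and the set of pathway pairs whose expected activity
#' ordering differs between cases and controls by construction (computed
#' from the realised gene baselines plus shifts; a pair is a truth pair when
#' both subtypes reverse the control ordering of expected pathway means).
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; identical (config, seed) gives identical output.
#' @return List with `expr` (an `expr_dataset`), `catalog`
#'   (a `gene_set_catalog`) and `truth` (list: `group`, `subtype`,
#'   `truth_pairs`, `shifts`, `expected_means`).
#' @export
generate_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n_pathway_genes <- cf$m_pathways * cf$genes_per_pathway
  n_genes <- cf$n_background_genes + n_pathway_genes
  n <- cf$n_nonAD + cf$n_S1 + cf$n_S2
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n))
  group <- rep(c("non-AD", "AD"), c(cf$n_nonAD, cf$n_S1 + cf$n_S2))
  subtype <- rep(c(NA, "S1", "S2"), c(cf$n_nonAD, cf$n_S1, cf$n_S2))

  path_ids <- sprintf("path%02d", seq_len(cf$m_pathways))
  blocks <- split(gene_ids[seq_len(n_pathway_genes)],
                  rep(seq_len(cf$m_pathways), each = cf$genes_per_pathway))
  catalog <- gene_set_catalog(path_ids, paste("synthetic pathway", seq_len(cf$m_pathways)),
                              unname(blocks))

  # per-pathway shift by sample stratum (non-AD gets none by construction)
  shifts <- matrix(0, cf$m_pathways, 3L,
                   dimnames = list(path_ids, c("non-AD", "S1", "S2")))
  if (!is.null(cf$effects)) {
    for (r in seq_len(nrow(cf$effects))) {
      pw <- as.character(cf$effects$pathway[r])
      if (!pw %in% path_ids) stop("effect names unknown pathway: ", pw)
      tgt <- if (cf$effects$group[r] == "AD") c("S1", "S2") else cf$effects$group[r]
      shifts[pw, tgt] <- shifts[pw, tgt] + cf$effects$delta[r]
    }
  }
  stratum <- ifelse(group == "non-AD", "non-AD", subtype)

  set.seed(seed)
  mu_g <- stats::rnorm(n_genes, cf$mu0, cf$sd0)
  values <- matrix(mu_g, n_genes, n) +
    matrix(stats::rnorm(n_genes * n, 0, cf$sd), n_genes, n)
  for (p in seq_len(cf$m_pathways)) {
    rows <- (p - 1L) * cf$genes_per_pathway + seq_len(cf$genes_per_pathway)
    values[rows, ] <- values[rows, ] + rep(shifts[p, stratum], each = length(rows))
  }
  batch <- NULL
  if (!is.null(cf$batch_effects)) {
    nb <- nrow(cf$batch_effects)
    batch_idx <- rep_len(seq_len(nb), n)
    values <- values + rep(cf$batch_effects$delta[batch_idx], each = n_genes)
    batch <- as.character(cf$batch_effects$batch[batch_idx])
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  meta <- data.frame(sample = sample_ids, group = group, subtype = subtype,
                     stringsAsFactors = FALSE)
  if (!is.null(batch)) meta$batch <- batch

  # expected pathway means per stratum from realised baselines + shifts
  base_mean <- vapply(seq_len(cf$m_pathways), function(p) {
    mean(mu_g[(p - 1L) * cf$genes_per_pathway + seq_len(cf$genes_per_pathway)])
  }, 0)
  expected <- base_mean + shifts  # recycles over columns
  truth_pairs <- character(0)
  for (i in seq_len(cf$m_pathways - 1L)) {
    for (j in (i + 1L):cf$m_pathways) {
      ctrl <- sign(expected[i, "non-AD"] - expected[j, "non-AD"])
      s1 <- sign(expected[i, "S1"] - expected[j, "S1"])
      s2 <- sign(expected[i, "S2"] - expected[j, "S2"])
      if (s1 == s2 && s1 != 0 && ctrl != 0 && s1 != ctrl) {
        truth_pairs <- c(truth_pairs, paste0(path_ids[i], "-", path_ids[j]))
      }
    }
  }
  list(expr = expr_dataset(values, meta), catalog = catalog,
       truth = list(group = stats::setNames(group, sample_ids),
                    subtype = stats::setNames(subtype, sample_ids),
                    truth_pairs = truth_pairs, shifts = shifts,
                    expected_means = expected))
}

#' Type-I error calibration of the pairwise screen on null data
#'
#' Repeatedly simulates a null cohort (no planted effects allowed), runs the
#' full activity -> pairwise-signature -> chi-square screen, and reports the
#' observed false-positive behaviour: the fraction of raw p-values below
#' `alpha` pooled over replicates, and the familywise error rate at the
#' Holm-adjusted threshold `alpha_adj` (fraction of replicates flagging at
#' least one pair).
#'
#' @param config A null `sim_config` (error if any effect is configured).
#' @param n_replicates Monte-Carlo replicates.
#' @param alpha Raw p-value threshold.
#' @param alpha_adj Holm-adjusted threshold for the FWER estimate.
#' @param seed Base seed; replicate r uses seed + r.
#' @param ssgsea_alpha Rank-weight exponent passed through to scoring.
#' @return List: `fp_fraction`, `fwer`, `n_tests`, `n_replicates`.
#' @export
null_screen_calibration <- function(config, n_replicates = 50L, alpha = 0.05,
                                    alpha_adj = 0.01, seed = 1L,
                                    ssgsea_alpha = 0.25) {
  if (!is.null(config$effects) && any(config$effects$delta != 0)) {
    stop("calibration requires a null configuration (all deltas zero)")
  }
  n_below <- 0L
  n_tests <- 0L
  any_flagged <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    ds <- generate_dataset(config, seed = seed + r)
    act <- ssgsea_matrix(ds$expr, ds$catalog, alpha = ssgsea_alpha)
    scr <- differential_screen(build_mpp(act), ds$expr$metadata$group,
                               alpha_adj = alpha_adj)
    ok <- !scr$skipped
    n_below <- n_below + sum(scr$p[ok] < alpha)
    n_tests <- n_tests + sum(ok)
    any_flagged[r] <- any(scr$flagged)
  }
  list(fp_fraction = if (alpha >= 1) 1 else n_below / n_tests,
       fwer = mean(any_flagged), n_tests = n_tests,
       n_replicates = n_replicates)
}
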