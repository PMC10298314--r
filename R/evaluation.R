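#' AUC with a DeLong 95% confidence interval
#'
#' Computes the area under the ROC curve by the rank (Mann-Whitney) formula
#' with half credit for tied scores, and a 95% confidence interval from
#' DeLong's asymptotic variance of the placement values, truncated to
#' [0, 1]. With a single positive or negative the variance is undefined and
#' the CI is reported as [0, 1].
#'
#' @param scores Numeric risk scores (higher = more case-like).
#' @param labels Binary labels: logical, 0/1, or a two-level factor/character
#'   vector whose second sorted level is the positive class unless `positive`
#'   says otherwise.
#' @param positive Optional label naming the positive class.
#' @return List: `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
auc_score <- function(scores, labels, positive = NULL) {
  if (is.character(labels) || is.factor(labels)) {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) != 2L) stop("labels must have exactly two levels")
    pos_lab <- if (is.null(positive)) lev[2L] else positive
    if (!pos_lab %in% lev) stop("positive label not present")
    labels <- as.character(labels) == pos_lab
  }
  y <- as.logical(labels)
  if (!any(y) || all(y)) stop("both classes must be present")
  stopifnot(length(scores) == length(y))
  pos <- scores[y]
  neg <- scores[!y]
  np <- length(pos)
  nn <- length(neg)
  # placement values: V10_i = P(score_i > neg) + .5 P(=); V01_j symmetric
  v10 <- vapply(pos, function(s) (sum(s > neg) + 0.5 * sum(s == neg)) / nn, 0)
  v01 <- vapply(neg, function(s) (sum(pos > s) + 0.5 * sum(pos == s)) / np, 0)
  auc <- mean(v10)
  if (np > 1L && nn > 1L) {
    var_auc <- stats::var(v10) / np + stats::var(v01) / nn
    half <- stats::qnorm(0.975) * sqrt(var_auc)
    ci <- c(max(0, auc - half), min(1, auc + half))
  } else {
    ci <- c(0, 1)
  }
  list(auc = auc, ci_low = ci[1L], ci_high = ci[2L], n_pos = np, n_neg = nn)
}

.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Default L1-logistic classifier for cross-validation
#'
#' Trains cross-validated lasso logistic regression on the training block and
#' returns a function scoring new sample rows by the linear predictor.
#' Constant columns are dropped before fitting.
#'
#' @param x Training matrix (samples x features).
#' @param y Binary 0/1 response.
#' @param cv_folds Internal folds for lambda selection.
#' @return A function(newx) -> numeric scores.
#' @export
lasso_classifier <- function(x, y, cv_folds = 5L) {
  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  if (sum(keep) < 2L) {
    m <- mean(y)
    return(function(newx) rep(m, nrow(newx)))
  }
  fit <- glmnet::cv.glmnet(x[, keep, drop = FALSE], y, family = "binomial",
                           alpha = 1, nfolds = cv_folds,
                           type.measure = "deviance")
  function(newx) {
    as.numeric(stats::predict(fit, newx[, keep, drop = FALSE],
                              s = "lambda.min", type = "link"))
  }
}

#' Stratified k-fold cross-validation of a signature classifier
#'
#' Splits samples into stratified folds, trains the classifier on k-1 folds
#' and scores the held-out fold, pooling held-out scores per repeat. AUC is
#' computed on the pooled scores; recall, precision and F1 use the
#' Youden-optimal threshold determined on the training scores of each fold
#' and are averaged over folds.
#'
#' @param mpp An `mpp_matrix` (or samples-x-features matrix).
#' @param groups Two-level labels per sample (second sorted level positive).
#' @param classifier Factory function(x, y) -> function(newx) -> scores;
#'   default [lasso_classifier()].
#' @param k Folds (default 10); must not exceed the minority class size.
#' @param n_repeats Repeats with reshuffled folds (default 1).
#' @param representation Signature representation when `mpp` is an
#'   `mpp_matrix`.
#' @param seed Integer seed; repeat r uses seed + r.
#' @return A `cv_report`: list with `auc` (mean pooled AUC over repeats),
#'   `per_repeat` data frame (auc, recall, precision, f1), `folds` (fold
#'   assignment of the first repeat), `seed`.
#' @export
cross_validate <- function(mpp, groups, classifier = lasso_classifier, k = 10L,
                           n_repeats = 1L,
                           representation = c("continuous", "discrete"),
                           seed = 1L) {
  representation <- match.arg(representation)
  X <- if (inherits(mpp, "mpp_matrix")) {
    t(if (representation == "continuous") mpp$delta else mpp$indicator)
  } else mpp
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups required")
  y <- as.integer(groups == lev[2L])
  if (k > min(table(y))) stop("k exceeds the minority class size")
  per_repeat <- data.frame()
  folds1 <- NULL
  for (r in seq_len(n_repeats)) {
    folds <- .stratified_folds(y, k, seed + r)
    if (r == 1L) folds1 <- folds
    pooled_scores <- numeric(length(y))
    rec <- prec <- f1 <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      scorer <- classifier(X[tr, , drop = FALSE], y[tr])
      pooled_scores[!tr] <- scorer(X[!tr, , drop = FALSE])
      tr_scores <- scorer(X[tr, , drop = FALSE])
      thr <- youden_threshold(tr_scores, y[tr])
      pred <- as.integer(pooled_scores[!tr] >= thr)
      tp <- sum(pred == 1 & y[!tr] == 1)
      rec[f] <- if (sum(y[!tr] == 1) > 0) tp / sum(y[!tr] == 1) else NA
      prec[f] <- if (sum(pred == 1) > 0) tp / sum(pred == 1) else NA
      f1[f] <- if (!is.na(rec[f]) && !is.na(prec[f]) && rec[f] + prec[f] > 0) {
        2 * rec[f] * prec[f] / (rec[f] + prec[f])
      } else NA
    }
    per_repeat <- rbind(per_repeat, data.frame(
      repeat_id = r, auc = auc_score(pooled_scores, y)$auc,
      recall = mean(rec, na.rm = TRUE), precision = mean(prec, na.rm = TRUE),
      f1 = mean(f1, na.rm = TRUE)))
  }
  structure(list(auc = mean(per_repeat$auc), per_repeat = per_repeat,
                 folds = folds1, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report: mean AUC", round(x$auc, 3), "over",
      nrow(x$per_repeat), "repeat(s)\n")
  invisible(x)
}

#' Youden-optimal classification threshold
#'
#' The score threshold maximizing sensitivity + specificity - 1 on the given
#' scores; midpoints between adjacent distinct scores are scanned.
#'
#' @param scores Numeric scores.
#' @param y Binary 0/1 labels.
#' @return The threshold (numeric scalar).
#' @export
youden_threshold <- function(scores, y) {
  s <- sort(unique(scores))
  if (length(s) == 1L) return(s)
  cand <- (s[-1L] + s[-length(s)]) / 2
  j <- vapply(cand, function(t) {
    mean(scores[y == 1] >= t) + mean(scores[y == 0] < t) - 1
  }, 0)
  cand[which.max(j)]
}

#' Run the full pairwise-signature pipeline on a simulated cohort
#'
#' End-to-end driver: simulate (or accept) a dataset, score pathway
#' activities, build pairwise signatures, run the differential screen, rank
#' hub pathways, subtype the cases by consensus NMF, train the diagnostic
#' score, and evaluate it. All stage outputs are written as TSV/JSON under
#' `out_dir` together with a run log of seeds and parameters.
#'
#' @param config List with components: `sim` (a `sim_config`, or NULL if
#'   `data` given), `data` (optional list with `expr` and `catalog`),
#'   `seed`, `ssgsea_alpha`, `alpha_adj`, `k_range`, `nrun`, `top_n`,
#'   `n_iter`, `freq_threshold`. Missing entries take package defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config, out_dir) {
  defaults <- list(seed = 1L, ssgsea_alpha = 0.25, alpha_adj = 0.01,
                   k_range = 2:4, nrun = 10L, top_n = 10L, n_iter = 50L,
                   freq_threshold = 0.5, nmf_max_iter = 500L)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$sim) && is.null(config$data)) {
    stop("config must provide either a 'sim' block or a 'data' block")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$data)) {
    expr <- config$data$expr
    catalog <- config$data$catalog
    truth <- NULL
  } else {
    ds <- generate_dataset(config$sim, seed = config$seed)
    expr <- ds$expr
    catalog <- ds$catalog
    truth <- ds$truth
  }
  write_expression(expr, file.path(out_dir, "expression.tsv"),
                   file.path(out_dir, "metadata.tsv"))
  write_gmt(catalog, file.path(out_dir, "pathways.gmt"))

  act <- ssgsea_matrix(expr, catalog, alpha = config$ssgsea_alpha)
  utils::write.table(data.frame(pathway = rownames(act), act, check.names = FALSE),
                     file.path(out_dir, "activity.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  mpp <- build_mpp(act)
  screen <- differential_screen(mpp, expr$metadata$group,
                                alpha_adj = config$alpha_adj,
                                reference = "non-AD")
  utils::write.table(screen, file.path(out_dir, "screen.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  flagged <- screen$pair_id[screen$flagged]

  hubs <- NULL
  if (length(flagged)) {
    g <- build_graph(flagged)
    hubs <- mcc_rank(g)
    utils::write.table(hubs, file.path(out_dir, "hubs.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  subtype <- NULL
  cases <- expr$metadata$sample[expr$metadata$group == "AD"]
  if (length(flagged) >= 2L && length(cases) >= 8L) {
    subtype <- nmf_subtype(mpp, flagged, cases, k_range = config$k_range,
                           nrun = config$nrun, seed = config$seed,
                           max_iter = config$nmf_max_iter)
    utils::write.table(data.frame(sample = names(subtype$assignments),
                                  subtype = paste0("S", subtype$assignments)),
                       file.path(out_dir, "subtypes.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(subtype$metrics, file.path(out_dir, "nmf_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report <- train_mppss(mpp, expr$metadata$group, n_iter = config$n_iter,
                        freq_threshold = config$freq_threshold,
                        seed = config$seed, positive = "AD")
  write_model(report$model, file.path(out_dir, "model.json"))
  scores <- risk_score(report$model, mpp)
  utils::write.table(data.frame(sample = names(scores), score = scores,
                                group = expr$metadata$group),
                     file.path(out_dir, "scores.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  test_idx <- expr$metadata$sample %in% report$test_samples
  eval_res <- auc_score(scores[test_idx], expr$metadata$group[test_idx],
                        positive = "AD")
  log <- list(seed = config$seed, ssgsea_alpha = config$ssgsea_alpha,
              alpha_adj = config$alpha_adj, n_flagged = length(flagged),
              n_selected = length(report$selected_pairs),
              selected_k = if (is.null(subtype)) NA else subtype$k,
              test_auc = eval_res$auc, test_ci = c(eval_res$ci_low, eval_res$ci_high))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(expr = expr, catalog = catalog, truth = truth,
                 activity = act, mpp = mpp, screen = screen, hubs = hubs,
                 subtype = subtype, training = report, scores = scores,
                 evaluation = eval_res, log = log))
}
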