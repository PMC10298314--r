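#' Score samples with an MPPSS model
#'
#' Evaluates risk score_k = intercept + sum_i coef_i * value_i^k, where
#' value_i^k is the k-th sample's signature for the i-th model pair, taken
#' from the representation the model names (continuous activity difference
#' or the +/-1 ordering indicator). Model pair ids are orientation-
#' normalized against the signature matrix: a model pair "B-A" whose matrix
#' row is stored as "A-B" contributes the negated row value.
#'
#' @param model An `mppss_model`.
#' @param mpp An `mpp_matrix` (or a numeric matrix of signature values with
#'   pair-id row names, treated as the model's representation).
#' @return Named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(model, mpp) {
  stopifnot(inherits(model, "mppss_model"))
  if (inherits(mpp, "mpp_matrix")) {
    mat <- if (model$representation == "continuous") mpp$delta else mpp$indicator
  } else {
    mat <- mpp
    stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  }
  rows <- rownames(mat)
  scores <- rep(model$intercept, ncol(mat))
  for (i in seq_along(model$pair_ids)) {
    id <- model$pair_ids[i]
    if (id %in% rows) {
      v <- mat[id, ]
    } else {
      parts <- strsplit(id, "-", fixed = TRUE)[[1L]]
      flipped <- paste0(parts[2L], "-", parts[1L])
      if (!flipped %in% rows) {
        stop("model pair id not resolvable in the signature matrix: ", id)
      }
      v <- -mat[flipped, ]
    }
    scores <- scores + model$coefs[i] * v
  }
  stats::setNames(scores, colnames(mat))
}

.stratified_split <- function(groups, train_frac, seed) {
  set.seed(seed)
  train <- logical(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    n_train <- round(train_frac * length(idx))
    train[sample(idx, n_train)] <- TRUE
  }
  train
}

#' Train an MPPSS model by repeated L1-penalized logistic selection
#'
#' The training protocol: a stratified split reserves `train_frac` of the
#' samples for training; then, for `n_iter` iterations, the training split
#' is bootstrap-resampled (redrawn, up to 10 times, if a class vanishes), an
#' L1-penalized logistic regression is fitted with internal cross-validation
#' choosing lambda at minimum CV deviance, and the pairs with nonzero
#' coefficients are recorded. Pairs selected in at least `freq_threshold` of
#' the iterations form the final feature set, and the final model is a
#' single cross-validated L1 fit on the full training split restricted to
#' that set. Deterministic given the seed.
#'
#' @param mpp An `mpp_matrix`.
#' @param groups Two-level group label per sample; `positive` names the
#'   class modelled as 1 (default the second sorted level).
#' @param representation "continuous" or "discrete" signature values.
#' @param train_frac Training fraction (default 0.7).
#' @param n_iter Selection iterations (default 1000; tests scale this down).
#' @param cv_folds Internal CV folds for lambda (default 10).
#' @param freq_threshold Selection-frequency cutoff (default 0.8).
#' @param seed Integer seed.
#' @param positive Label of the positive class.
#' @return A `mppss_training_report`: list with `model` (an `mppss_model`),
#'   `selection_frequency`, `selected_pairs`, `lambda`, `train_samples`,
#'   `test_samples`, `train_auc`, `test_auc`, `seed`.
#' @export
train_mppss <- function(mpp, groups, representation = c("continuous", "discrete"),
                        train_frac = 0.7, n_iter = 1000L, cv_folds = 10L,
                        freq_threshold = 0.8, seed = 1L, positive = NULL) {
  representation <- match.arg(representation)
  stopifnot(inherits(mpp, "mpp_matrix"))
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups required")
  if (is.null(positive)) positive <- lev[2L]
  if (!positive %in% lev) stop("positive label not present")
  if (min(table(groups)) < 10L) stop("need at least 10 samples per group")
  X <- t(if (representation == "continuous") mpp$delta else mpp$indicator)
  y <- as.integer(groups == positive)
  # drop constant columns: no information and they break glmnet standardization
  keep <- apply(X, 2L, function(col) stats::sd(col) > 0)
  Xk <- X[, keep, drop = FALSE]
  if (ncol(Xk) < 2L) stop("fewer than 2 non-constant signatures")

  train <- .stratified_split(groups, train_frac, seed)
  Xtr <- Xk[train, , drop = FALSE]
  ytr <- y[train]
  n_tr <- sum(train)
  sel_count <- stats::setNames(numeric(ncol(Xk)), colnames(Xk))
  for (it in seq_len(n_iter)) {
    set.seed(seed + it)
    for (attempt in seq_len(10L)) {
      boot <- sample(n_tr, n_tr, replace = TRUE)
      if (length(unique(ytr[boot])) == 2L) break
      if (attempt == 10L) stop("a class vanished from 10 consecutive bootstrap draws")
    }
    cvfit <- glmnet::cv.glmnet(Xtr[boot, , drop = FALSE], ytr[boot],
                               family = "binomial", alpha = 1,
                               nfolds = cv_folds, type.measure = "deviance")
    beta <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[-1L, 1L]
    sel_count[beta != 0] <- sel_count[beta != 0] + 1
  }
  freq <- sel_count / n_iter
  selected <- names(freq)[freq >= freq_threshold]

  if (length(selected) >= 2L) {
    set.seed(seed)
    cv_final <- glmnet::cv.glmnet(Xtr[, selected, drop = FALSE], ytr,
                                  family = "binomial", alpha = 1,
                                  nfolds = cv_folds, type.measure = "deviance")
    cf <- as.matrix(stats::coef(cv_final, s = "lambda.min"))[, 1L]
    lambda <- cv_final$lambda.min
    model <- mppss_model(selected, cf[-1L], intercept = cf[1L],
                         representation = representation,
                         provenance = sprintf("trained: n_iter=%d, freq>=%.2f, seed=%d",
                                              n_iter, freq_threshold, seed))
  } else if (length(selected) == 1L) {
    fit <- stats::glm(ytr ~ Xtr[, selected], family = stats::binomial())
    model <- mppss_model(selected, stats::coef(fit)[2L],
                         intercept = stats::coef(fit)[1L],
                         representation = representation,
                         provenance = "trained: single selected signature, unpenalized refit")
    lambda <- NA_real_
  } else {
    model <- mppss_model(character(0), numeric(0), intercept = 0,
                         representation = representation,
                         provenance = "trained: no signature passed the frequency threshold")
    lambda <- NA_real_
  }
  score_all <- risk_score(model, mpp)
  samp <- mpp$sample_ids
  structure(list(model = model, selection_frequency = freq,
                 selected_pairs = selected, lambda = lambda,
                 train_samples = samp[train], test_samples = samp[!train],
                 train_auc = auc_score(score_all[train], y[train])$auc,
                 test_auc = auc_score(score_all[!train], y[!train])$auc,
                 seed = seed),
            class = "mppss_training_report")
}

#' @export
print.mppss_training_report <- function(x, ...) {
  cat("mppss_training_report:", length(x$selected_pairs), "signatures selected;",
      "train AUC", round(x$train_auc, 3), "/ test AUC", round(x$test_auc, 3), "\n")
  invisible(x)
}
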