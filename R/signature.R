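# Diagnostic signature: stratified train/validation split, L1-penalized
# logistic feature selection over a cross-validated lambda path, a
# regression-mode random forest on the selected features (so that both
# %IncMSE and IncNodePurity importances are defined on the 0/1 response),
# rank-based ROC/AUC, and stratified k-fold cross-validation that refits the
# whole selection + forest pipeline inside each fold.

#' Stratified train/validation split
#'
#' Splits the non-excluded samples into a training and a validation set,
#' stratified by group, deterministically for a given seed.
#'
#' @param samples sample table.
#' @param train_fraction proportion of each group assigned to training.
#' @param seed integer seed.
#' @return list with `train` and `validation` sample tables.
#' @export
split_train_validation <- function(samples, train_fraction = 0.8, seed = 1L) {
  train_fraction <- check_fraction(train_fraction, "train_fraction")
  samples <- samples[!samples$excluded, , drop = FALSE]
  for (g in c("control", "case"))
    if (sum(samples$group == g) < 2L) stop_cf("group '%s' has < 2 samples", g)
  idx_train <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(samples)), samples$group), function(ix) {
      k <- round(train_fraction * length(ix))
      sample(ix, k)
    }))
  })
  if (length(idx_train) == nrow(samples) && train_fraction < 1)
    warn_cf("training fraction leaves no validation samples")
  if (train_fraction == 1) warn_cf("validation set is empty")
  train <- samples[sort(idx_train), , drop = FALSE]
  valid <- samples[setdiff(seq_len(nrow(samples)), idx_train), , drop = FALSE]
  rownames(train) <- rownames(valid) <- NULL
  list(train = train, validation = valid)
}

#' LASSO feature selection
#'
#' L1-penalized logistic regression over a lambda path (via glmnet, features
#' standardized internally); lambda is chosen by k-fold cross-validated
#' deviance, either the minimizer (`"min"`, default) or the one-standard-error
#' rule (`"1se"`). Features with non-zero coefficients at the chosen lambda
#' are returned. Passing `lambda` explicitly bypasses cross-validation.
#'
#' @param x expression matrix restricted to candidate features (features x
#'   samples, >= 2 features).
#' @param samples sample table covering the columns of `x`.
#' @param n_folds folds for lambda tuning (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param lambda_rule `"min"` or `"1se"`.
#' @param lambda optional fixed penalty overriding the cross-validated choice.
#' @return data.frame `feature_id`, `coefficient` (non-zero only), with the
#'   chosen `lambda` as an attribute. Empty (with a warning) when everything
#'   is shrunk away.
#' @export
lasso_select <- function(x, samples, n_folds = 10, seed = 1L,
                         lambda_rule = c("min", "1se"), lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  if (nrow(x) < 2L) stop_cf("need >= 2 candidate features")
  samples <- check_sample_table(x, samples)
  y <- as.numeric(samples$group == "case")
  xt <- t(x)
  if (is.null(lambda)) {
    foldid <- stratified_folds(samples$group, n_folds, seed)
    cvfit <- withr::with_seed(seed,
      glmnet::cv.glmnet(xt, y, family = "binomial", foldid = foldid,
                        type.measure = "deviance", standardize = TRUE,
                        thresh = 1e-12))
    lam <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
    fit <- cvfit$glmnet.fit
  } else {
    lam <- check_number(lambda, "lambda", min = 0)
    fit <- glmnet::glmnet(xt, y, family = "binomial", lambda = lam,
                          standardize = TRUE, thresh = 1e-12)
  }
  beta <- as.matrix(predict(fit, type = "coefficients", s = lam))[, 1]
  beta <- beta[setdiff(names(beta), "(Intercept)")]
  sel <- beta[beta != 0]
  if (length(sel) == 0L) warn_cf("LASSO shrank every coefficient to zero")
  out <- data.frame(feature_id = names(sel), coefficient = unname(sel),
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- lam
  out
}

# Fold assignment: per-group cycling (every fold sees every group) when each
# group is at least as large as n_folds; otherwise global cycling over
# group-sorted, shuffled samples (covers leave-one-out).
stratified_folds <- function(group, n_folds, seed) {
  foldid <- integer(length(group))
  withr::with_seed(seed, {
    if (min(table(group)) >= n_folds) {
      for (g in unique(group)) {
        ix <- sample(which(group == g))
        foldid[ix] <- rep_len(seq_len(n_folds), length(ix))
      }
    } else {
      ix <- unlist(lapply(unique(group), function(g) sample(which(group == g))))
      foldid[ix] <- rep_len(seq_len(n_folds), length(ix))
    }
  })
  foldid
}

#' Fit the random-forest signature and its importances
#'
#' A regression-mode random forest on the 0/1 group response (bootstrap per
#' tree, default `sqrt(p)`-style mtry for regression), with permutation
#' importance (%IncMSE) and total impurity decrease (IncNodePurity) per
#' feature. Deterministic given the seed.
#'
#' @param x expression matrix restricted to the selected features.
#' @param samples sample table covering the columns of `x`.
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed.
#' @return object of class `signature_model`: `features`, `forest`,
#'   `importance` (data.frame `feature_id`, `pct_inc_mse`,
#'   `inc_node_purity`), `n_trees`, `seed`.
#' @export
rf_fit_and_importance <- function(x, samples, n_trees = 1000, seed = 1L) {
  if (nrow(x) < 1L) stop_cf("no selected features")
  samples <- check_sample_table(x, samples)
  y <- as.numeric(samples$group == "case")
  if (length(unique(y)) < 2L) stop_cf("training labels contain a single class")
  n_trees <- check_count(n_trees, "n_trees")
  xt <- as.data.frame(t(x))
  # regression mode on the 0/1 response is deliberate (it defines %IncMSE),
  # so randomForest's few-unique-values advisory is muffled
  forest <- withr::with_seed(seed, suppressWarnings(
    randomForest::randomForest(x = xt, y = y, ntree = n_trees, importance = TRUE)))
  imp <- randomForest::importance(forest)
  importance <- data.frame(feature_id = rownames(imp),
                           pct_inc_mse = imp[, "%IncMSE"],
                           inc_node_purity = imp[, "IncNodePurity"],
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(features = rownames(x), forest = forest,
                 importance = importance, n_trees = n_trees, seed = seed),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("Random-forest signature: %d features, %d trees (seed %d)\n",
              length(x$features), x$n_trees, x$seed))
  print(x$importance[order(-x$importance$pct_inc_mse), ], digits = 4,
        row.names = FALSE)
  invisible(x)
}

#' Score samples with a fitted signature
#'
#' @param object a `signature_model`.
#' @param x expression matrix containing at least the signature features;
#'   features missing from `x` raise an error listing them.
#' @param ... unused.
#' @return numeric vector of scores (higher = more case-like), named by sample.
#' @export
predict.signature_model <- function(object, x, ...) {
  missing <- setdiff(object$features, rownames(x))
  if (length(missing))
    stop_cf("features absent from the matrix: %s", paste(missing, collapse = ", "))
  newdata <- as.data.frame(t(x[object$features, , drop = FALSE]))
  scores <- predict(object$forest, newdata = newdata)
  names(scores) <- colnames(x)
  scores
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed through the Mann-Whitney relation
#' `AUC = U / (n1 * n2)`, with ties counted one half.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 (or logical/`control`/`case`) class labels; 1 = case.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- normalize_labels(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop_cf("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  u <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("control", "case")))
      stop_cf("character labels must be control/case")
    return(as.integer(labels == "case"))
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_cf("labels must be 0/1")
  labels
}

#' ROC curve and AUC for a fitted signature
#'
#' @param model a `signature_model`.
#' @param x expression matrix of the evaluation samples.
#' @param samples their sample table (both classes required).
#' @return list of class `roc_result`: `curve` (data.frame `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `scores`.
#' @export
evaluate_roc <- function(model, x, samples) {
  samples <- check_sample_table(x, samples)
  scores <- predict(model, x)
  labels <- normalize_labels(samples$group)
  if (length(unique(labels)) < 2L) stop_cf("both classes required for ROC")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), numeric(1))
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 auc = auc_rank(scores, labels), scores = scores),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f over %d samples\n", x$auc, length(x$scores)))
  invisible(x)
}

#' Cross-validated signature performance
#'
#' Stratified k-fold cross-validation in which the whole pipeline — LASSO
#' selection (its own internal folds) followed by the random forest — is
#' refit on each training split and scored on the held-out fold. When a fold's
#' LASSO selects nothing, all candidates are carried into the forest for that
#' fold (with a warning).
#'
#' @param x candidate-feature expression matrix.
#' @param samples sample table.
#' @param n_folds outer folds (default 5).
#' @param seed integer seed.
#' @param n_trees forest size per fold (default 1000).
#' @param lasso_folds folds for lambda tuning inside each fold (default 10).
#' @return list with `fold_auc` (per-fold; `NA` when a held-out fold has a
#'   single class, as in leave-one-out), `mean_auc` (over defined folds),
#'   `pooled_auc` (AUC of all held-out scores together) and `fold_scores`.
#' @export
cross_validate <- function(x, samples, n_folds = 5, seed = 1L, n_trees = 1000,
                           lasso_folds = 10) {
  samples <- check_sample_table(x, samples)
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  foldid <- stratified_folds(samples$group, n_folds, seed)
  labels <- normalize_labels(samples$group)
  for (f in seq_len(n_folds))
    if (length(unique(labels[foldid != f])) < 2L)
      stop_cf("training split for fold %d lacks both classes; use fewer folds", f)
  fold_auc <- rep(NA_real_, n_folds)
  fold_scores <- vector("list", n_folds)
  pooled <- numeric(length(labels))
  for (f in seq_len(n_folds)) {
    tr <- foldid != f
    xtr <- x[, tr, drop = FALSE]
    str <- samples[tr, , drop = FALSE]
    sel <- tryCatch(
      suppressWarnings(lasso_select(xtr, str, n_folds = lasso_folds, seed = seed + f)),
      error = function(e) data.frame(feature_id = character(0), coefficient = numeric(0)))
    feats <- if (nrow(sel)) sel$feature_id else {
      warn_cf("fold %d: empty LASSO selection; using all candidates", f)
      rownames(x)
    }
    model <- rf_fit_and_importance(xtr[feats, , drop = FALSE], str,
                                   n_trees = n_trees, seed = seed + f)
    scores <- predict(model, x[feats, !tr, drop = FALSE])
    fold_scores[[f]] <- scores
    pooled[!tr] <- scores
    if (length(unique(labels[!tr])) == 2L)
      fold_auc[f] <- auc_rank(scores, labels[!tr])
  }
  list(fold_auc = fold_auc,
       mean_auc = mean(fold_auc, na.rm = TRUE),
       pooled_auc = auc_rank(pooled, labels),
       fold_scores = fold_scores)
}
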