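#' Cross-validation scheme
#'
#' @param folds number of folds k (>= 2).
#' @param repeats number of repeats.
#' @param downsample for classification, subsample the majority class of
#'   every *training* fold down to the minority-class size before fitting
#'   (test folds are never touched).
#' @param seed RNG seed controlling fold assignment, down-sampling and the
#'   learner.
#' @return object of class `cv_scheme`.
#' @export
cv_scheme <- function(folds = 10, repeats = 5, downsample = TRUE, seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  if (repeats < 1) stop("repeats must be >= 1")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 downsample = isTRUE(downsample), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Random-forest learner (fit/predict contract)
#'
#' The default ensemble learner for [repeated_cv()]: 500 trees, features per
#' split at the library defaults (`sqrt(p)` for classification, `p/3` for
#' regression). Any list with the same `fit`/`predict` elements (and
#' optional `importance`) is a valid learner.
#'
#' @param ntree number of trees.
#' @return list with `fit(x, y)`, `predict(model, x)` (class-1 probability
#'   for classification, numeric prediction for regression) and
#'   `importance(model)` (mean decrease in impurity per feature).
#' @export
rf_learner <- function(ntree = 500) {
  list(
    fit = function(x, y) randomForest::randomForest(x = x, y = y, ntree = ntree),
    predict = function(model, x) {
      if (model$type == "classification")
        stats::predict(model, x, type = "prob")[, 2L]
      else stats::predict(model, x)
    },
    importance = function(model) model$importance[, 1L]
  )
}

#' Training-mean baseline learner
#'
#' Predicts the training mean (regression) or the training case rate
#' (classification) for every sample; useful as a null reference.
#'
#' @return a learner list, see [rf_learner()].
#' @export
mean_learner <- function() {
  list(
    fit = function(x, y) if (is.factor(y)) mean(y == levels(y)[2L]) else mean(y),
    predict = function(model, x) rep(model, nrow(x)),
    importance = function(model) NULL
  )
}

#' Repeated, down-sampled, stratified k-fold cross-validation
#'
#' For classification the folds are stratified so every test fold mirrors
#' the full-cohort class proportions (up to rounding), and (optionally) the
#' majority class of each training fold is randomly subsampled to the
#' minority size before fitting -- the down-sampling scheme for unbalanced
#' cohorts. Regression uses plain random folds and no down-sampling. Every
#' sample appears in exactly one test fold per repeat, and out-of-fold
#' predictions cover the cohort each repeat. Deterministic under the scheme
#' seed.
#'
#' @param x [omics_matrix()] or matrix of predictors (samples x features).
#' @param y response: 2-level factor / binary vector for classification,
#'   numeric for regression.
#' @param scheme a [cv_scheme()].
#' @param learner a learner list, see [rf_learner()].
#' @return object of class `cv_result`: list with `task`
#'   (`"classification"` or `"regression"`), `predictions` (samples x
#'   repeats matrix of out-of-fold predictions), `folds` (samples x repeats
#'   matrix of test-fold indices), `per_repeat` (AUC or Spearman accuracy
#'   per repeat), `metric` (their mean), `metric_name`, and `importance`
#'   (mean over all fits; `NULL` if the learner reports none).
#' @export
repeated_cv <- function(x, y, scheme = cv_scheme(), learner = rf_learner()) {
  xm <- if (inherits(x, "omics_matrix")) .values(x) else as.matrix(x)
  n <- nrow(xm)
  if (length(y) != n) stop("x and y must be sample-aligned")
  classif <- is.factor(y) || is.logical(y) ||
    (is.numeric(y) && length(unique(y[!is.na(y)])) == 2L)
  if (classif) {
    y <- factor(y)
    if (nlevels(y) != 2L) stop("classification needs exactly two classes")
    if (min(table(y)) < scheme$folds)
      stop("minority class (", min(table(y)), ") smaller than the fold count (",
           scheme$folds, "); use fewer folds")
  } else {
    y <- as.numeric(y)
  }
  set.seed(scheme$seed)
  k <- scheme$folds
  preds <- matrix(NA_real_, n, scheme$repeats,
                  dimnames = list(rownames(xm), paste0("rep", seq_len(scheme$repeats))))
  folds <- matrix(NA_integer_, n, scheme$repeats, dimnames = dimnames(preds))
  per_repeat <- numeric(scheme$repeats)
  imp_sum <- NULL; imp_n <- 0L

  for (r in seq_len(scheme$repeats)) {
    fold_of <- integer(n)
    if (classif) {
      for (lv in levels(y)) {
        idx <- sample(which(y == lv))
        fold_of[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold_of[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    folds[, r] <- fold_of
    for (f in seq_len(k)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      if (classif && scheme$downsample) {
        tab <- table(y[train])
        n_min <- min(tab)
        train <- unlist(lapply(levels(y), function(lv) {
          cand <- train[y[train] == lv]
          if (length(cand) > n_min) sample(cand, n_min) else cand
        }), use.names = FALSE)
      }
      model <- learner$fit(xm[train, , drop = FALSE], y[train])
      preds[test, r] <- learner$predict(model, xm[test, , drop = FALSE])
      if (!is.null(learner$importance)) {
        im <- learner$importance(model)
        if (!is.null(im)) {
          imp_sum <- if (is.null(imp_sum)) im else imp_sum + im
          imp_n <- imp_n + 1L
        }
      }
    }
    per_repeat[r] <- if (classif) roc_auc(preds[, r], y)
    else spearman_accuracy(preds[, r], y)
  }
  structure(list(task = if (classif) "classification" else "regression",
                 predictions = preds, folds = folds,
                 per_repeat = per_repeat, metric = mean(per_repeat),
                 metric_name = if (classif) "auc" else "spearman",
                 importance = if (imp_n > 0L) sort(imp_sum / imp_n, decreasing = TRUE) else NULL),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean %s = %.4f over %d repeat(s)\n",
              x$task, x$metric_name, x$metric, length(x$per_repeat)))
  invisible(x)
}

#' Spearman prediction accuracy
#'
#' Spearman correlation between predicted and observed values (see
#' [spearman_cor()]); `NA` when the predictions are constant.
#'
#' @param predictions,observed aligned numeric vectors.
#' @return Spearman rho.
#' @export
spearman_accuracy <- function(predictions, observed) {
  spearman_cor(predictions, observed)$rho
}

#' Area under the ROC curve
#'
#' Rank-statistic AUC, `P(score_pos > score_neg) + 0.5 P(tie)`, i.e. the
#' Mann-Whitney U of the positive scores divided by `n1 * n0`.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (0/1, logical, or 2-level factor; the second
#'   factor level is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- .as_binary(labels)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("roc_auc needs both classes present")
  r <- rank(scores)
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' ROC curve points
#'
#' False/true positive rates at every distinct score threshold (plus the
#' degenerate endpoints), suitable for plotting or trapezoidal integration.
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `fpr`, `tpr`, ordered from (0, 0)
#'   to (1, 1).
#' @export
roc_curve <- function(scores, labels) {
  pos <- .as_binary(labels)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("roc_curve needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0)) # tied scores collapse to one point
  tp <- tapply(cumsum(p), grp, max)
  fp <- tapply(cumsum(!p), grp, max)
  thr <- tapply(s, grp, min)
  data.frame(threshold = c(Inf, thr), fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

.as_binary <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    labels == levels(labels)[2L]
  } else if (is.logical(labels)) {
    labels
  } else {
    u <- sort(unique(labels[!is.na(labels)]))
    if (length(u) > 2L) stop("labels must have exactly two levels")
    labels == u[length(u)] # single level: one empty class, caught downstream
  }
}
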