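#' Stratified 6:4 train/test split
#'
#' Randomly splits the samples into a training and a test partition,
#' stratified by group: each group contributes
#' `round(split_train_fraction * n_g)` training samples.  The plan is a
#' deterministic function of the seed.
#'
#' @param samples character vector of sample IDs.
#' @param groups data.frame with `sample_id`, `group`.
#' @param config a [pipeline_config()].
#' @param seed integer seed (defaults to the config's master seed).
#' @return list of class `split_plan`: `train`, `test` (sample IDs),
#'   `counts` (per group and partition), `seed`.
#' @export
split_samples <- function(samples, groups, config = pipeline_config(),
                          seed = config$rng_seed) {
  grp <- groups$group[match(samples, groups$sample_id)]
  if (anyNA(grp)) stop("samples missing from group table", call. = FALSE)
  set.seed(seed)
  train <- character(0L)
  for (g in unique(grp)) {
    ids <- samples[grp == g]
    n_train <- round(config$split_train_fraction * length(ids))
    if (n_train < 2L || length(ids) - n_train < 2L) {
      stop(sprintf("group '%s' too small for a %g:%g split", g,
                   config$split_train_fraction,
                   1 - config$split_train_fraction), call. = FALSE)
    }
    train <- c(train, sample(ids, n_train))
  }
  test <- setdiff(samples, train)
  counts <- table(partition = ifelse(samples %in% train, "train", "test"),
                  group = grp)
  out <- list(train = sort(train), test = sort(test), counts = counts,
              seed = seed)
  class(out) <- "split_plan"
  out
}

# L2-regularized squared-hinge linear classifier ("linear soft-margin
# SVM"), minimized by BFGS on the smooth objective
#   0.5 * ||w||^2 + C * mean( max(0, 1 - y*(x.w + b))^2 ).
# The mean-loss form makes the optimum invariant to duplicating every
# training sample.
fit_linear_svm <- function(X, y, C) {
  n <- nrow(X); p <- ncol(X)
  yy <- ifelse(y == levels(factor(y))[2L], 1, -1)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    margin <- 1 - yy * (X %*% w + b)
    loss <- pmax(margin, 0)
    0.5 * sum(w^2) + C * mean(loss^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    margin <- as.vector(1 - yy * (X %*% w + b))
    act <- pmax(margin, 0)
    gw <- w - (2 * C / n) * as.vector(t(X) %*% (act * yy))
    gb <- -(2 * C / n) * sum(act * yy)
    c(gw, gb)
  }
  opt <- stats::optim(numeric(p + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  list(w = opt$par[seq_len(p)], b = opt$par[p + 1L],
       positive_level = levels(factor(y))[2L], C = C,
       value = opt$value)
}

svm_decision <- function(model, X) {
  as.vector(X %*% model$w + model$b)
}

# Deterministic stratified fold assignment.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (g in unique(y)) {
    idx <- which(y == g)
    if (length(idx) < k) {
      stop("a class has fewer samples than cv_folds; stratification failed",
           call. = FALSE)
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train a linear SVM with cross-validated regularization
#'
#' Fits a linear soft-margin classifier on the ego-gene methylation
#' features.  The regularization strength C is selected from the fixed
#' grid \{0.01, 0.1, 1, 10, 100\} by stratified k-fold cross-validated
#' accuracy on the training set (ties go to the smallest C); the final
#' model is refit on all training data.  Features are standardized with
#' the training-set mean and standard deviation unless
#' `config$svm_standardize` is FALSE (zero-sd features get sd 1).
#'
#' @param X training feature matrix, samples x features.
#' @param y training labels (two classes).
#' @param config a [pipeline_config()].
#' @param seed seed for the fold assignment.
#' @return list of class `linear_svm`: `w`, `b`, `C`, `center`, `scale`,
#'   `positive_level`, `cv_accuracy` (named by C), `fold_accuracy`
#'   (per fold at the chosen C).
#' @export
train_linear_svm <- function(X, y, config = pipeline_config(),
                             seed = config$rng_seed) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) != 2L) stop("need exactly two classes", call. = FALSE)
  if (config$svm_standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | is.na(scl)] <- 1
  } else {
    center <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")

  grid <- c(0.01, 0.1, 1, 10, 100)
  folds <- stratified_folds(y, config$cv_folds, seed)
  cv_acc <- numeric(length(grid))
  fold_acc_best <- NULL
  for (ci in seq_along(grid)) {
    acc <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- folds != f
      m <- fit_linear_svm(Xs[tr, , drop = FALSE], y[tr], grid[ci])
      sc <- svm_decision(m, Xs[!tr, , drop = FALSE])
      pred <- ifelse(sc > 0, m$positive_level,
                     setdiff(unique(y), m$positive_level))
      mean(pred == y[!tr])
    }, numeric(1L))
    cv_acc[ci] <- mean(acc)
    if (ci == 1L || cv_acc[ci] > max(cv_acc[seq_len(ci - 1L)])) {
      fold_acc_best <- acc
    }
  }
  best <- which.max(cv_acc)   # which.max takes the first (smallest C) tie
  model <- fit_linear_svm(Xs, y, grid[best])
  model$center <- center
  model$scale <- scl
  model$cv_accuracy <- stats::setNames(cv_acc, grid)
  model$fold_accuracy <- fold_acc_best
  class(model) <- "linear_svm"
  model
}

#' @rdname train_linear_svm
#' @param object fitted `linear_svm`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L,
              object$scale, "/")
  svm_decision(object, Xs)
}

#' Evaluate a classifier on a test set
#'
#' Computes the confusion matrix at decision threshold 0 and the five
#' summary metrics: rank-based AUC (Mann-Whitney statistic divided by
#' `n_pos * n_neg`, ties counted 1/2), accuracy, Matthews correlation
#' coefficient (0 when its denominator is 0), sensitivity (TPR) and
#' specificity (TNR).  With a single-class test set the AUC is reported
#' as NA with a reason.
#'
#' @param model fitted `linear_svm`.
#' @param X test features, samples x features.
#' @param y test labels.
#' @return list of class `classification_report`: `tp`, `fp`, `tn`,
#'   `fn`, `auc`, `accuracy`, `mcc`, `sensitivity`, `specificity`,
#'   `scores`, `C`, `cv_accuracy`, `fold_accuracy`, and `auc_reason`
#'   when AUC is undefined.
#' @export
evaluate <- function(model, X, y) {
  y <- as.character(y)
  if (!length(y)) stop("empty test set", call. = FALSE)
  scores <- predict(model, X)
  pos <- model$positive_level
  pred_pos <- scores > 0
  is_pos <- y == pos
  tp <- sum(pred_pos & is_pos); fp <- sum(pred_pos & !is_pos)
  tn <- sum(!pred_pos & !is_pos); fn <- sum(!pred_pos & is_pos)
  out <- confusion_metrics(tp, fp, tn, fn)
  if (any(is_pos) && any(!is_pos)) {
    out$auc <- rank_auc(scores, is_pos)
  } else {
    out$auc <- NA_real_
    out$auc_reason <- "single-class test set"
  }
  out$scores <- stats::setNames(scores, rownames(X))
  out$C <- model$C
  out$cv_accuracy <- model$cv_accuracy
  out$fold_accuracy <- model$fold_accuracy
  class(out) <- "classification_report"
  out
}

# Confusion-matrix summary metrics with the documented MCC convention.
confusion_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  den <- sqrt(as.double(tp + fp)) * sqrt(as.double(tp + fn)) *
    sqrt(as.double(tn + fp)) * sqrt(as.double(tn + fn))
  mcc <- if (den == 0) 0 else (as.double(tp) * tn - as.double(fp) * fn) / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / total,
       mcc = mcc,
       sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}

#' Rank-based AUC
#'
#' Mann-Whitney U divided by `n_pos * n_neg`; tied scores count 1/2.
#'
#' @param scores numeric decision scores.
#' @param is_pos logical, TRUE for positive-class samples.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, is_pos) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  stopifnot(n1 > 0, n0 > 0)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report\n")
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  AUC=%s accuracy=%.4f MCC=%.4f sens=%.4f spec=%.4f\n",
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
              x$accuracy, x$mcc, x$sensitivity, x$specificity))
  cat(sprintf("  C=%g, CV accuracy: %s\n", x$C,
              paste(sprintf("%g:%.3f", as.numeric(names(x$cv_accuracy)),
                            x$cv_accuracy), collapse = " ")))
  invisible(x)
}
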