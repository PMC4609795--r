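#' Area under the ROC curve
#'
#' Tie-corrected rank statistic: the probability that a randomly chosen
#' positive sample outscores a randomly chosen negative one (ties count 1/2).
#'
#' @param scores Numeric scores, higher = more case-like.
#' @param labels Binary labels (1 = case).
#' @return AUC in \[0, 1\]; `NA` when a class is absent.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Positive and negative predictive value
#'
#' @param predictions Predicted binary classes (1 = case).
#' @param labels True binary labels.
#' @return Named list `ppv = TP/(TP+FP)`, `npv = TN/(TN+FN)`; `NA` when a
#'   denominator is empty.
#' @export
ppv_npv <- function(predictions, labels) {
  predictions <- as.integer(predictions); labels <- as.integer(labels)
  tp <- sum(predictions == 1L & labels == 1L)
  fp <- sum(predictions == 1L & labels == 0L)
  tn <- sum(predictions == 0L & labels == 0L)
  fn <- sum(predictions == 0L & labels == 1L)
  list(ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' RBF-kernel SVM decision values
#'
#' Soft-margin support vector classifier with a Gaussian kernel
#' (default `gamma = 3`, cost 1) on already-standardized inputs; returns
#' decision values oriented so that larger means more case-like.  A
#' regression-style `epsilon` argument is accepted but ignored with a warning
#' (it has no role in classification mode).
#'
#' @param train_x,test_x Numeric matrices (samples x features).
#' @param train_y Binary labels of the training samples (1 = case).
#' @param gamma RBF kernel width parameter.
#' @param cost Soft-margin cost.
#' @param epsilon Ignored (classification mode).
#' @return List with `scores` (decision values on `test_x`) and `class`
#'   (thresholded at 0).
#' @export
svm_rbf <- function(train_x, train_y, test_x, gamma = 3, cost = 1,
                    epsilon = NULL) {
  if (!is.null(epsilon))
    warning("epsilon belongs to regression-mode SVM and is ignored here")
  y <- factor(as.integer(train_y), levels = c(0, 1))
  if (length(unique(train_y)) < 2)
    stop("training fold contains a single class", call. = FALSE)
  fit <- e1071::svm(as.matrix(train_x), y, kernel = "radial", gamma = gamma,
                    cost = cost, scale = FALSE)
  pr <- predict(fit, as.matrix(test_x), decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # decision values are signed towards the first class in the colname "a/b"
  pos_first <- startsWith(colnames(attr(pr, "decision.values"))[1], "1")
  scores <- if (pos_first) dv else -dv
  list(scores = scores, class = as.integer(as.character(pr)))
}

# Ridge-jittered iteration-capped logistic regression; tolerates more
# features than samples (predictions are still produced, mirroring the
# known degradation of logistic fits in that regime rather than erroring).
logistic_ridge <- function(x, y, ridge = 1e-8, max_iter = 25) {
  x <- cbind(1, as.matrix(x))
  beta <- numeric(ncol(x))
  pen <- diag(c(0, rep(ridge, ncol(x) - 1L)))
  for (i in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(x %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    wt <- pmax(mu * (1 - mu), 1e-10)
    A <- crossprod(x, wt * x) + pen
    b <- crossprod(x, wt * eta + (y - mu))
    new_beta <- tryCatch(solve(A, b), error = function(e)
      solve(A + diag(1e-6, ncol(x)), b))
    if (max(abs(new_beta - beta)) < 1e-8) { beta <- new_beta; break }
    beta <- new_beta
  }
  beta
}

logistic_predict <- function(beta, x) {
  eta <- pmin(pmax(drop(cbind(1, as.matrix(x)) %*% beta), -30), 30)
  1 / (1 + exp(-eta))
}

#' Subset a labelled count matrix by samples
#'
#' @param data A [labeled_count_matrix()].
#' @param idx Sample indices to keep.
#' @return A [labeled_count_matrix()] restricted to those samples.
#' @export
subset_samples <- function(data, idx) {
  labeled_count_matrix(data$counts[, idx, drop = FALSE], data$labels[idx],
                       truth = data$truth,
                       sample_ids = data$sample_ids[idx])
}

#' Feature selection restricted to a training subset
#'
#' Runs [select_features()] on the samples indexed by `train_idx` only; the
#' remaining samples (and in particular their labels) play no part, which is
#' the leakage-freedom contract of the cross-validation harness.
#'
#' @param data A [labeled_count_matrix()].
#' @param train_idx Indices of the training samples.
#' @param fs_method Selector id.
#' @param alpha,bonferroni,params As in [select_features()].
#' @return An [fs_result()] over all features.
#' @export
cv_select <- function(data, train_idx, fs_method, alpha = 0.05,
                      bonferroni = FALSE, params = list()) {
  select_features(fs_method, subset_samples(data, train_idx), alpha = alpha,
                  bonferroni = bonferroni, params = params)
}

#' Repeated stratified cross-validated classification
#'
#' Per repeat: stratified fold assignment; feature selection on the training
#' folds only; the classifier is fitted on the selected features of the
#' training folds (inputs `log2(count + 1)`, standardized with training-fold
#' statistics) and scored on the held-out fold.  AUC comes from the
#' continuous scores; PPV/NPV from classes thresholded at probability 0.5
#' (decision value 0 for the SVM).  Metrics are averaged over folds and
#' repeats, and each feature's selection count across all training folds is
#' tallied.  A fold in which the selector returns no feature falls back to
#' the single best-scoring feature (counted in `n_empty_selections`).
#'
#' @param data A [labeled_count_matrix()].
#' @param fs_method Selector id (see [select_features()]).
#' @param classifier One of `"logistic"`, `"svm"`, `"rf"`.
#' @param n_folds Folds per repeat.
#' @param n_repeats Number of repeats.
#' @param alpha Level passed to p-value selectors.
#' @param gamma RBF width for the SVM.
#' @param n_trees Trees for the random-forest classifier.
#' @param fs_params Extra selector arguments.
#' @param seed Root seed; fixed seed gives an identical report.
#' @param dataset_id Label carried into the report.
#' @return An object of class `classifier_report`.
#' @export
repeated_cv <- function(data, fs_method, classifier = c("logistic", "svm", "rf"),
                        n_folds = 5, n_repeats = 100, alpha = 0.05, gamma = 3,
                        n_trees = 500, fs_params = list(), seed = 1,
                        dataset_id = "dataset") {
  classifier <- match.arg(classifier)
  stopifnot(min(table(data$labels)) >= n_folds)
  p <- nrow(data$counts)
  sel_freq <- stats::setNames(integer(p), data$feature_ids)
  aucs <- ppvs <- npvs <- c()
  n_empty <- 0L
  for (rep_i in seq_len(n_repeats)) {
    folds <- withr::with_seed(child_seed(seed, rep_i),
                              stratified_folds(data$labels, n_folds))
    for (k in seq_len(n_folds)) {
      tr <- which(folds != k); te <- which(folds == k)
      fs <- withr::with_seed(
        child_seed(seed, rep_i, k),
        cv_select(data, tr, fs_method, alpha = alpha, params = fs_params))
      sel <- fs$selected
      if (!any(sel)) {
        n_empty <- n_empty + 1L
        best <- if (fs$score_direction == "lower") which.min(fs$scores)
                else which.max(fs$scores)
        sel[best] <- TRUE
      }
      sel_freq <- sel_freq + sel
      x <- log_design(data$counts)[, sel, drop = FALSE]
      ctr <- colMeans(x[tr, , drop = FALSE])
      scl <- apply(x[tr, , drop = FALSE], 2, sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
      y_tr <- data$labels[tr]; y_te <- data$labels[te]
      out <- withr::with_seed(child_seed(seed, rep_i, k, 7L), switch(classifier,
        logistic = {
          beta <- logistic_ridge(xs[tr, , drop = FALSE], y_tr)
          pr <- logistic_predict(beta, xs[te, , drop = FALSE])
          list(scores = pr, class = as.integer(pr > 0.5))
        },
        svm = svm_rbf(xs[tr, , drop = FALSE], y_tr, xs[te, , drop = FALSE],
                      gamma = gamma),
        rf = {
          fit <- randomForest::randomForest(
            xs[tr, , drop = FALSE], factor(y_tr, levels = c(0, 1)),
            ntree = n_trees)
          pr <- predict(fit, xs[te, , drop = FALSE], type = "prob")[, "1"]
          list(scores = pr, class = as.integer(pr > 0.5))
        }))
      aucs <- c(aucs, auc(out$scores, y_te))
      pn <- ppv_npv(out$class, y_te)
      ppvs <- c(ppvs, pn$ppv); npvs <- c(npvs, pn$npv)
    }
  }
  structure(list(dataset_id = dataset_id, fs_method = fs_method,
                 classifier = classifier,
                 auc = mean(aucs, na.rm = TRUE),
                 ppv = mean(ppvs, na.rm = TRUE),
                 npv = mean(npvs, na.rm = TRUE),
                 n_repeats = n_repeats, n_folds = n_folds,
                 selection_frequency = sel_freq,
                 n_empty_selections = n_empty),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report [%s | %s + %s]: AUC %.3f, PPV %.3f, NPV %.3f (%d x %d-fold CV)\n",
              x$dataset_id, x$fs_method, x$classifier, x$auc, x$ppv, x$npv,
              x$n_repeats, x$n_folds))
  invisible(x)
}
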