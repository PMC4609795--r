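#' Feature-selection result container
#'
#' @param method_tag Selector label.
#' @param scores Per-feature scores (p-value, |coefficient|, swarm score or
#'   importance z-score).
#' @param selected Logical per-feature selection mask.
#' @param rule Human-readable decision rule that produced `selected`.
#' @param score_direction `"lower"` when smaller scores are stronger evidence
#'   (p-values), `"higher"` otherwise.
#' @return An object of class `fs_result`.
#' @export
fs_result <- function(method_tag, scores, selected, rule,
                      score_direction = c("lower", "higher")) {
  score_direction <- match.arg(score_direction)
  stopifnot(length(scores) == length(selected), nzchar(rule))
  structure(list(method_tag = method_tag, scores = scores,
                 selected = as.logical(selected), rule = rule,
                 score_direction = score_direction),
            class = "fs_result")
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("fs_result [%s]: %d / %d features selected (rule: %s)\n",
              x$method_tag, sum(x$selected), length(x$selected), x$rule))
  invisible(x)
}

#' Write a feature-selection result as TSV
#'
#' Columns: feature_id, score, selected, method_tag, rule.
#'
#' @param result An [fs_result()].
#' @param path Output file path.
#' @export
write_fs_result <- function(result, path) {
  df <- data.frame(feature_id = names(result$scores) %||%
                     sprintf("f%04d", seq_along(result$scores)),
                   score = unname(result$scores),
                   selected = unname(result$selected),
                   method_tag = result$method_tag, rule = result$rule)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-sided rank-sum p-value for one feature
#'
#' For group sizes both at most `exact_max` the full permutation distribution
#' of the rank sum is enumerated (ties handled exactly through midranks) and
#' the two-sided p-value is \eqn{P(|W - E W| \ge |w - E W|)}.  Otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.  A feature constant across all samples returns 1.
#'
#' @param x,y Numeric observations of the two groups.
#' @param exact_max Largest group size for which exact enumeration is used.
#' @return Two-sided p-value.
#' @export
rank_sum_p <- function(x, y, exact_max = 8) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  ew <- nx * (n + 1) / 2
  if (max(nx, ny) <= exact_max) {
    sums <- combn(n, nx, FUN = function(i) sum(r[i]))
    return(mean(abs(sums - ew) >= abs(w - ew) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w - ew) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Wilcoxon rank-sum feature selection
#'
#' Applies [rank_sum_p()] to every feature and selects those below the
#' nominal level `alpha`, or below `alpha / n_features` when `bonferroni`.
#'
#' @param data A [labeled_count_matrix()] or a count matrix.
#' @param groups Binary labels when `data` is a bare matrix.
#' @param alpha Nominal level.
#' @param bonferroni Apply the Bonferroni-corrected threshold.
#' @param exact_max Passed to [rank_sum_p()].
#' @return An [fs_result()] whose scores are the p-values.
#' @export
rank_sum_select <- function(data, groups = NULL, alpha = 0.05,
                            bonferroni = FALSE, exact_max = 8) {
  cm <- as_counts_groups(data, groups)
  check_two_groups(cm$groups, min_per_group = 2)
  case <- cm$groups == 1L
  nx <- sum(case); ny <- sum(!case); n <- nx + ny
  p <- if (max(nx, ny) > exact_max) {
    # vectorized normal-approximation path (one pass of ranks + tie term)
    ew <- nx * (n + 1) / 2
    vapply(seq_len(nrow(cm$counts)), function(g) {
      r <- rank(cm$counts[g, ])
      t <- rle(sort.int(r))$lengths
      sigma2 <- nx * ny / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
      if (sigma2 <= 0) return(1)
      z <- (abs(sum(r[case]) - ew) - 0.5) / sqrt(sigma2)
      min(1, 2 * pnorm(-max(z, 0)))
    }, numeric(1))
  } else apply(cm$counts, 1, function(row)
    rank_sum_p(row[case], row[!case], exact_max = exact_max))
  thr <- if (bonferroni) alpha / nrow(cm$counts) else alpha
  fs_result("ranksum", p, p < thr, paste0("p<", format(thr)), "lower")
}

# log2(count + 1) sample-by-feature design matrix used by the ML selectors
# and classifiers.
log_design <- function(counts) t(log2(as.matrix(counts) + 1))

#' L1-penalized logistic feature selection
#'
#' Logistic lasso on `log2(count + 1)`-transformed, standardized features;
#' the penalty is chosen by `n_folds`-fold cross-validation minimizing the
#' binomial deviance (the CV-minimum rule; set `one_se = TRUE` for the
#' one-standard-error rule).  Selected features are those with non-zero
#' coefficients at the chosen penalty.  Fold assignment and the coordinate
#' path use the session RNG.
#'
#' @inheritParams rank_sum_select
#' @param n_folds Cross-validation folds.
#' @param one_se Use the one-standard-error penalty instead of the minimum.
#' @param lambda Optional fixed penalty (skips cross-validation).
#' @return An [fs_result()] whose scores are |coefficients|.
#' @export
lasso_select <- function(data, groups = NULL, n_folds = 10, one_se = FALSE,
                         lambda = NULL) {
  cm <- as_counts_groups(data, groups)
  x <- log_design(cm$counts)
  y <- factor(cm$groups, levels = c(0, 1))
  if (is.null(lambda)) {
    if (min(table(y)) < n_folds)
      stop("each group needs at least n_folds samples", call. = FALSE)
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", nfolds = n_folds,
                               type.measure = "deviance", standardize = TRUE)
    lambda <- if (one_se) cvfit$lambda.1se else cvfit$lambda.min
    co <- as.numeric(stats::coef(cvfit, s = lambda))[-1]
  } else {
    fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda,
                          standardize = TRUE)
    co <- as.numeric(stats::coef(fit, s = lambda))[-1]
  }
  sel <- co != 0
  if (!any(sel)) warning("lasso selected no features (all-null path)")
  scores <- abs(co)
  names(scores) <- rownames(cm$counts)
  fs_result("lasso", scores, sel,
            sprintf("nonzero coefficient at lambda=%.4g", lambda), "higher")
}

#' Binary particle-swarm / decision-tree feature selection (PSODT)
#'
#' A wrapper selector: binary particle-swarm optimization over
#' feature-inclusion masks, each particle's fitness being the decision-tree
#' classification accuracy under internal stratified 3-fold cross-validation
#' on the supplied data.  Velocities follow the standard update with inertia
#' `w` and cognitive/social coefficients, and positions are re-sampled through
#' a sigmoid transfer.  At every iteration, each feature included in the
#' current position of a particle whose personal best fitness equals the
#' swarm's global best fitness gets its score incremented.  A feature is
#' selected when its score is positive in at least half of the `n_restarts`
#' independent swarm restarts.
#'
#' @inheritParams rank_sum_select
#' @param swarm_size Number of particles.
#' @param n_iters Iterations per restart (0 gives all-zero scores and an
#'   empty selection).
#' @param n_restarts Independent swarm restarts.
#' @param w Inertia weight.
#' @param c_cog,c_soc Cognitive and social acceleration coefficients.
#' @return An [fs_result()] whose scores are summed over restarts.
#' @export
psodt_select <- function(data, groups = NULL, swarm_size = 50, n_iters = 100,
                         n_restarts = 1, w = 0.72, c_cog = 1.49, c_soc = 1.49) {
  cm <- as_counts_groups(data, groups)
  check_two_groups(cm$groups, min_per_group = 4)
  x <- log_design(cm$counts)
  y <- factor(cm$groups, levels = c(0, 1))
  p <- ncol(x)
  fitness <- local({
    folds <- stratified_folds(cm$groups, 3)
    function(mask) {
      if (!any(mask)) return(max(table(y)) / length(y))
      acc <- vapply(seq_len(3), function(k) {
        tr <- folds != k
        df_tr <- data.frame(y = y[tr], x[tr, mask, drop = FALSE])
        df_te <- data.frame(x[!tr, mask, drop = FALSE])
        names(df_te) <- names(df_tr)[-1]
        tree <- rpart::rpart(y ~ ., data = df_tr, method = "class")
        mean(predict(tree, df_te, type = "class") == y[!tr])
      }, numeric(1))
      mean(acc)
    }
  })
  total_score <- matrix(0, nrow = n_restarts, ncol = p)
  for (r in seq_len(n_restarts)) {
    pos <- matrix(runif(swarm_size * p) < 0.5, swarm_size, p)
    vel <- matrix(runif(swarm_size * p, -1, 1), swarm_size, p)
    fit <- apply(pos, 1, fitness)
    pbest <- pos; pbest_fit <- fit
    gi <- which.max(pbest_fit)
    gbest <- pbest[gi, ]; gbest_fit <- pbest_fit[gi]
    iter <- 0
    while (iter < n_iters) {
      iter <- iter + 1
      r1 <- matrix(runif(swarm_size * p), swarm_size, p)
      r2 <- matrix(runif(swarm_size * p), swarm_size, p)
      gmat <- matrix(gbest, swarm_size, p, byrow = TRUE)
      vel <- w * vel + c_cog * r1 * (pbest - pos) + c_soc * r2 * (gmat - pos)
      pos <- matrix(runif(swarm_size * p), swarm_size, p) < 1 / (1 + exp(-vel))
      fit <- apply(pos, 1, fitness)
      improved <- fit > pbest_fit
      pbest[improved, ] <- pos[improved, ]
      pbest_fit[improved] <- fit[improved]
      gi <- which.max(pbest_fit)
      if (pbest_fit[gi] > gbest_fit) {
        gbest <- pbest[gi, ]; gbest_fit <- pbest_fit[gi]
      }
      at_best <- abs(pbest_fit - gbest_fit) < 1e-12
      if (any(at_best))
        total_score[r, ] <- total_score[r, ] +
          colSums(pos[at_best, , drop = FALSE])
    }
  }
  scores <- colSums(total_score)
  names(scores) <- rownames(cm$counts)
  need <- ceiling(n_restarts / 2)
  sel <- colSums(total_score > 0) >= need & scores > 0
  fs_result("psodt", scores, sel,
            sprintf("score>0 in >=%d of %d restarts", need, n_restarts),
            "higher")
}

#' Random-forest feature selection by permutation importance
#'
#' Fits a random forest on `log2(count + 1)` features and selects those whose
#' permutation-importance z-score (mean accuracy decrease divided by its
#' standard error) exceeds `z_threshold`.  Uses the session RNG.
#'
#' @inheritParams rank_sum_select
#' @param n_trees Number of trees.
#' @param mtry Variables tried per split; defaults to
#'   `floor(sqrt(n_features))`.
#' @param z_threshold Importance z-score cut-off.
#' @return An [fs_result()] whose scores are importance z-scores.
#' @export
rf_select <- function(data, groups = NULL, n_trees = 500, mtry = NULL,
                      z_threshold = 2) {
  cm <- as_counts_groups(data, groups)
  x <- log_design(cm$counts)
  y <- factor(cm$groups, levels = c(0, 1))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry,
                                    importance = TRUE)
  z <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
  z[!is.finite(z)] <- 0
  names(z) <- rownames(cm$counts)
  fs_result("rf", z, z > z_threshold, sprintf("importance z>%g", z_threshold),
            "higher")
}

#' Uniform feature-selection dispatcher
#'
#' Routes to one of the seven selectors; the NB tests (`"bayseq"`, `"deseq"`,
#' `"edger"`) are thresholded on their p-values at `alpha` (Bonferroni
#' optionally), matching the rank-sum decision rule.
#'
#' @param method One of `"bayseq"`, `"deseq"`, `"edger"`, `"ranksum"`,
#'   `"lasso"`, `"psodt"`, `"rf"`.
#' @param data A [labeled_count_matrix()].
#' @param alpha Nominal level for the p-value methods.
#' @param bonferroni Use `alpha / n_features` for the p-value methods.
#' @param params Named list of extra arguments passed to the selector.
#' @return An [fs_result()].
#' @export
select_features <- function(method, data, alpha = 0.05, bonferroni = FALSE,
                            params = list()) {
  methods_p <- c(bayseq = bayseq_like_posterior, deseq = deseq_like_test,
                 edger = edger_like_test)
  if (method %in% names(methods_p)) {
    res <- do.call(methods_p[[method]], c(list(data), params))
    thr <- if (bonferroni) alpha / length(res$p_values) else alpha
    return(fs_result(method, res$p_values, res$p_values < thr,
                     paste0("p<", format(thr)), "lower"))
  }
  switch(method,
    ranksum = do.call(rank_sum_select,
                      c(list(data, alpha = alpha, bonferroni = bonferroni),
                        params)),
    lasso = do.call(lasso_select, c(list(data), params)),
    psodt = do.call(psodt_select, c(list(data), params)),
    rf = do.call(rf_select, c(list(data), params)),
    stop("unknown selection method: ", method, call. = FALSE))
}

# Stratified fold assignment: within each class, a random permutation of
# balanced fold labels.
stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}
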