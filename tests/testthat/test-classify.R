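test_that("AUC follows the rank statistic, with its extremes", {
  labels <- c(1, 1, 1, 0, 0, 0)
  expect_equal(auc(c(9, 8, 7, 3, 2, 1), labels), 1)
  expect_equal(auc(c(1, 2, 3, 7, 8, 9), labels), 0)
  scores <- withr::with_seed(1, rnorm(40))
  labs <- rep(c(1, 0), 20)
  u <- unname(suppressWarnings(stats::wilcox.test(
    scores[labs == 1], scores[labs == 0]))$statistic)
  expect_equal(auc(scores, labs), u / (20 * 20), tolerance = 1e-12)
  expect_true(is.na(auc(scores, rep(1, 40))))
})

test_that("predictive values follow their definitions", {
  expect_equal(ppv_npv(c(1, 1, 0, 0), c(1, 1, 0, 0)), list(ppv = 1, npv = 1))
  out <- ppv_npv(c(1, 1, 1, 0), c(1, 0, 1, 0))
  expect_equal(out$ppv, 2 / 3)
  expect_equal(out$npv, 1)
  expect_true(is.na(ppv_npv(rep(1, 4), c(1, 0, 1, 0))$npv))
})

test_that("the RBF SVM separates well-separated clouds and ignores duplication", {
  set.seed(111)
  x <- rbind(matrix(rnorm(40, 5), 20, 2), matrix(rnorm(40, -5), 20, 2))
  y <- c(rep(1, 20), rep(0, 20))
  out <- svm_rbf(x, y, x, gamma = 1)
  expect_equal(out$class, y)
  expect_true(all(out$scores[y == 1] > out$scores[y == 0]))
  # duplicating every training point leaves the decision function unchanged
  # (up to the optimizer's convergence tolerance)
  dup <- svm_rbf(rbind(x, x), c(y, y), x, gamma = 1)
  expect_equal(out$scores, dup$scores, tolerance = 1e-3)
  expect_error(svm_rbf(x, rep(1, 40), x), "single class")
  expect_warning(svm_rbf(x, y, x, gamma = 1, epsilon = 0.2), "ignored")
})

test_that("a small RBF width approximates the linear rule on a linear problem", {
  set.seed(112)
  n <- 30
  train_x <- rbind(matrix(rnorm(2 * n, 1.5), n, 2), matrix(rnorm(2 * n, -1.5), n, 2))
  train_y <- c(rep(1, n), rep(0, n))
  test_x <- rbind(matrix(rnorm(400, 1.5), 200, 2), matrix(rnorm(400, -1.5), 200, 2))
  test_y <- c(rep(1, 200), rep(0, 200))
  acc <- vapply(c(0.01, 50), function(g)
    mean(svm_rbf(train_x, train_y, test_x, gamma = g)$class == test_y),
    numeric(1))
  expect_gte(acc[1], acc[2] - 0.02)   # near-linear kernel generalizes at least as well
})

test_that("cross-validated feature selection never sees held-out labels", {
  d <- simulate_dataset(scenario_config(seed = 113, n_features = 60), 1)
  train_idx <- 5:36
  base <- withr::with_seed(9, cv_select(d, train_idx, "ranksum"))
  corrupted <- d
  corrupted$labels[c(1:4, 37:40)] <- 1L - corrupted$labels[c(1:4, 37:40)]
  after <- withr::with_seed(9, cv_select(corrupted, train_idx, "ranksum"))
  expect_identical(base$scores, after$scores)
  expect_identical(base$selected, after$selected)
})

test_that("repeated CV is deterministic and near-perfect on separable data", {
  d <- simulate_dataset(scenario_grid(seed = 114)[["B5"]], 1)
  rep1 <- suppressWarnings(repeated_cv(d, "ranksum", "rf", n_repeats = 3,
                                       n_trees = 100, seed = 7))
  rep2 <- suppressWarnings(repeated_cv(d, "ranksum", "rf", n_repeats = 3,
                                       n_trees = 100, seed = 7))
  expect_equal(rep1$auc, rep2$auc)
  expect_identical(rep1$selection_frequency, rep2$selection_frequency)
  expect_gte(rep1$auc, 0.95)
  expect_lte(max(rep1$selection_frequency), 3 * rep1$n_folds)
})

test_that("permuted labels drive the cross-validated AUC to chance", {
  # A single permutation retains chance structure that in-fold selection can
  # exploit, so the chance level is reached in expectation over permutations.
  d <- simulate_dataset(scenario_config(n_case = 40, n_control = 40,
                                        n_features = 100, seed = 115), 1)
  aucs <- vapply(1:4, function(pm) {
    null_d <- labeled_count_matrix(d$counts,
                                   withr::with_seed(200 + pm, sample(d$labels)))
    suppressWarnings(repeated_cv(null_d, "ranksum", "logistic",
                                 n_repeats = 4, seed = 8))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("logistic regression degrades as features approach the sample count", {
  # moderate signal plus increasing noise padding: held-out AUC slides toward
  # chance as the fitted dimension approaches the training-sample count
  d <- simulate_dataset(scenario_config(seed = 116, n_features = 200,
                                        mu_sig_case = 10), 1)
  x <- t(log2(d$counts + 1))
  p_ranked <- order(rank_sum_select(d)$scores)
  fit_auc <- function(n_noise) {
    sel <- c(p_ranked[1:3], if (n_noise > 0) rev(p_ranked)[seq_len(n_noise)])
    mean(vapply(1:10, function(r) {
      te <- withr::with_seed(300 + r, sort(sample(40, 10)))
      tr <- setdiff(1:40, te)
      beta <- nbfsbench:::logistic_ridge(x[tr, sel, drop = FALSE], d$labels[tr])
      auc(nbfsbench:::logistic_predict(beta, x[te, sel, drop = FALSE]),
          d$labels[te])
    }, numeric(1)))
  }
  curve <- vapply(c(0, 10, 20, 30), fit_auc, numeric(1))
  expect_gt(curve[1], curve[4] + 0.1)
  expect_true(all(diff(curve) < 0.03))   # monotone drop up to sampling noise
})
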