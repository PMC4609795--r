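test_that("rank-sum exact enumeration matches the brute-force oracle", {
  set.seed(81)
  for (i in 1:20) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- rnbinom(nx, mu = 5, size = 1); y <- rnbinom(ny, mu = 8, size = 1)
    expect_equal(rank_sum_p(x, y), oracle_ranksum_p(x, y), tolerance = 1e-10,
                 label = sprintf("case %d (n=%d/%d)", i, nx, ny))
  }
})

test_that("rank-sum worked example: {1,2,3} vs {4,5,6} has exact p = 0.1", {
  expect_equal(rank_sum_p(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)
})

test_that("the large-sample path matches the tie-corrected normal approximation", {
  set.seed(82)
  for (i in 1:10) {
    x <- rnbinom(20, mu = 5, size = 1); y <- rnbinom(20, mu = 8, size = 1)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))$p.value
    expect_equal(rank_sum_p(x, y), ref, tolerance = 1e-10)
  }
  # complete separation at n = 20/20 is overwhelmingly significant
  expect_lt(rank_sum_p(101:120, 1:20), 1e-7)
  # constant features carry no information
  expect_equal(rank_sum_p(rep(3, 20), rep(3, 20)), 1)
})

test_that("rank-sum selection is invariant under monotone transforms", {
  d <- simulate_dataset(scenario_config(seed = 83, n_features = 60), 1)
  base <- rank_sum_select(d)
  logd <- rank_sum_select(log(d$counts + 1), d$labels)
  cubed <- rank_sum_select(d$counts^3, d$labels)
  expect_equal(unname(base$scores), unname(logd$scores), tolerance = 1e-12)
  expect_equal(unname(base$scores), unname(cubed$scores), tolerance = 1e-12)
})

test_that("selection rules are reported with their thresholds", {
  d <- simulate_dataset(scenario_config(seed = 84, n_features = 500), 1)
  nominal <- rank_sum_select(d, alpha = 0.05)
  expect_equal(nominal$rule, "p<0.05")
  expect_identical(nominal$selected, unname(nominal$scores < 0.05))
  bonf <- rank_sum_select(d, alpha = 0.05, bonferroni = TRUE)
  expect_equal(bonf$rule, "p<1e-04")
  expect_identical(bonf$selected, unname(bonf$scores < 1e-4))
})

test_that("lasso selects strong effects and stays sparse on noise", {
  b5 <- simulate_dataset(scenario_grid(seed = 85)[["B5"]], 1)
  res <- withr::with_seed(1, lasso_select(b5))
  cm <- confusion(res$selected, b5$truth)
  expect_gte(cm["tp"], 1)
  expect_gte(cm["tn"] / (cm["tn"] + cm["fp"]), 0.95)

  noise <- simulate_dataset(scenario_config(mu_sig_case = 5, seed = 86), 1)
  res0 <- withr::with_seed(2, suppressWarnings(lasso_select(noise)))
  expect_lte(mean(res0$selected), 0.05)

  forced <- suppressWarnings(lasso_select(b5, lambda = 1e6))
  expect_false(any(forced$selected))
})

test_that("increasing the lasso penalty never grows the selected set", {
  d <- simulate_dataset(scenario_grid(seed = 87)[["B5"]], 2)
  x <- t(log2(d$counts + 1))
  fit <- withr::with_seed(3, glmnet::glmnet(x, factor(d$labels), family = "binomial"))
  sizes <- fit$df                       # nonzero coefficients along decreasing lambda
  expect_true(all(diff(sizes) >= 0))
})

test_that("the particle-swarm selector is deterministic and score-bounded", {
  d <- simulate_dataset(scenario_config(seed = 88, n_features = 20,
                                        mu_sig_case = 5), 1)
  run <- function(seed) withr::with_seed(seed,
    psodt_select(d, swarm_size = 8, n_iters = 5))
  expect_identical(run(1)$scores, run(1)$scores)
  r <- run(2)
  # per iteration at most swarm_size * n_features increments are possible
  expect_lte(sum(r$scores), 5 * 8 * 20)
  zero <- withr::with_seed(1, psodt_select(d, swarm_size = 8, n_iters = 0))
  expect_true(all(zero$scores == 0))
  expect_false(any(zero$selected))
})

test_that("particle-swarm scores are exchangeable across pure-noise features", {
  d <- simulate_dataset(scenario_config(seed = 89, n_features = 20,
                                        mu_sig_case = 5), 1)
  scores <- rowSums(vapply(1:5, function(s) withr::with_seed(400 + s,
    psodt_select(d, swarm_size = 8, n_iters = 6)$scores), numeric(20)))
  # no systematic difference between the first and second half of features
  p <- suppressWarnings(stats::wilcox.test(scores[1:10], scores[11:20]))$p.value
  expect_gt(p, 0.001)
})

test_that("random-forest importance separates signal from noise", {
  d <- simulate_dataset(scenario_config(seed = 90, n_features = 100), 1)
  res <- withr::with_seed(4, rf_select(d, n_trees = 300))
  expect_identical(res$scores,
                   withr::with_seed(4, rf_select(d, n_trees = 300))$scores)
  cm <- confusion(res$selected, d$truth)
  expect_gte(cm["tn"] / (cm["tn"] + cm["fp"]), 0.9)

  noise <- simulate_dataset(scenario_config(mu_sig_case = 5, seed = 91,
                                            n_features = 100), 1)
  res0 <- withr::with_seed(5, rf_select(noise, n_trees = 300))
  expect_lt(abs(mean(res0$scores)), 0.5)
})

test_that("the dispatcher routes methods uniformly and rejects unknown ids", {
  d <- simulate_dataset(scenario_config(seed = 92, n_features = 40), 1)
  res <- withr::with_seed(1, suppressWarnings(select_features("edger", d)))
  expect_equal(res$rule, "p<0.05")
  expect_equal(res$method_tag, "edger")
  rs <- select_features("ranksum", d, bonferroni = TRUE)
  expect_equal(rs$rule, "p<0.00125")
  expect_error(select_features("pca", d), "unknown")
})

test_that("feature-selection results serialize to TSV", {
  res <- fs_result("rf", c(a = 1.5, b = -0.2), c(TRUE, FALSE), "importance z>2",
                   "higher")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fs_result(res, path)
  back <- read.delim(path)
  expect_equal(back$feature_id, c("a", "b"))
  expect_equal(back$selected, c(TRUE, FALSE))
})
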