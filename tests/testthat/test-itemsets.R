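# Six-cohort transaction set in which item B occurs exactly in the three
# transactions containing item A (and a ubiquitous background item C).
worked_transactions <- list(
  t1 = c("A", "B", "C"), t2 = c("A", "B", "C"), t3 = c("A", "B", "C"),
  t4 = c("C", "D"), t5 = c("C", "D"), t6 = c("C", "E"))

test_that("the co-occurring pair yields confidence 1 and lift 2", {
  fs <- apriori(worked_transactions, min_support = 0.5)
  rl <- rules(fs, worked_transactions, min_confidence = 0.5)
  pick <- vapply(seq_len(nrow(rl)), function(i)
    identical(rl$antecedent[[i]], "A") && identical(rl$consequent[[i]], "B"),
    logical(1))
  expect_equal(sum(pick), 1)
  expect_equal(rl$confidence[pick], 1)
  expect_equal(rl$lift[pick], 2)
  expect_equal(rl$support[pick], 0.5)
})

test_that("a ubiquitous consequent has lift 1", {
  fs <- apriori(worked_transactions, min_support = 0.5)
  rl <- rules(fs, worked_transactions, min_confidence = 0.5)
  to_c <- vapply(seq_len(nrow(rl)), function(i)
    identical(rl$consequent[[i]], "C"), logical(1))
  expect_true(any(to_c))
  expect_equal(unique(rl$lift[to_c]), 1)
})

test_that("confidence times antecedent support equals joint support", {
  fs <- apriori(worked_transactions, min_support = 0.3)
  rl <- rules(fs, worked_transactions, min_confidence = 0.3)
  for (i in seq_len(nrow(rl))) {
    sa <- mean(vapply(worked_transactions, function(tr)
      all(rl$antecedent[[i]] %in% tr), logical(1)))
    expect_equal(rl$confidence[i] * sa, rl$support[i], tolerance = 1e-12)
    expect_length(intersect(rl$antecedent[[i]], rl$consequent[[i]]), 0)
  }
})

test_that("apriori equals brute-force enumeration on random small universes", {
  for (s in 1:5) {
    tr <- withr::with_seed(120 + s, {
      items <- letters[1:10]
      lapply(1:8, function(i) sample(items, sample(2:6, 1)))
    })
    for (ms in c(0.25, 0.5)) {
      got <- apriori(tr, min_support = ms)
      want <- oracle_frequent(tr, ms)
      key <- function(x) paste(sort(x), collapse = "|")
      got_keys <- vapply(got$items, key, character(1))
      want_keys <- vapply(want$items, key, character(1))
      expect_setequal(got_keys, want_keys)
      expect_equal(got$support[order(got_keys)],
                   want$support[order(want_keys)], tolerance = 1e-12)
      # downward closure: every subset of a frequent set is frequent
      for (i in seq_along(got$items)) {
        st <- got$items[[i]]
        if (length(st) < 2) next
        for (d in seq_along(st))
          expect_true(key(st[-d]) %in% got_keys)
      }
      # rules agree with directly-computed confidence and lift
      rl <- rules(got, tr, min_confidence = 0.01)
      supp_of <- function(x) mean(vapply(tr, function(t2) all(x %in% t2), logical(1)))
      for (i in seq_len(nrow(rl))) {
        su <- supp_of(c(rl$antecedent[[i]], rl$consequent[[i]]))
        expect_equal(rl$confidence[i], su / supp_of(rl$antecedent[[i]]),
                     tolerance = 1e-12)
        expect_equal(rl$lift[i],
                     rl$confidence[i] / supp_of(rl$consequent[[i]]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("min_support = 1 keeps only universally-present itemsets", {
  fs <- apriori(worked_transactions, min_support = 1)
  expect_equal(vapply(fs$items, paste, character(1), collapse = ","), "C")
  expect_error(apriori(list(character(0)), 0.5), "nonempty")
  expect_error(apriori(worked_transactions, 0), "min_support")
})

test_that("eligibility requires Bonferroni, frequency >= 80 and >= 3 algorithms", {
  freq <- function(x) stats::setNames(x, c("m1", "m2"))
  cohort <- function(f_a, f_b, f_c, p_a) list(
    edger = list(selection_frequency = c(mirA = f_a[1], mirB = f_b[1], mirC = f_c[1]),
                 p_values = c(mirA = p_a, mirB = 1e-9, mirC = 1e-9)),
    ranksum = list(selection_frequency = c(mirA = f_a[2], mirB = f_b[2], mirC = f_c[2]),
                   p_values = c(mirA = p_a, mirB = 1e-9, mirC = 1e-9)),
    rf = list(selection_frequency = c(mirA = f_a[3], mirB = f_b[3], mirC = f_c[3])))
  res <- eligible_items(list(
    # mirA: Bonferroni-significant, 85x in one method, flagged by all 3
    # mirB: frequency 79 everywhere -> fails (b)
    # mirC: only 2 algorithms flag it -> fails (c)
    coh1 = cohort(f_a = c(85, 60, 55), f_b = c(79, 79, 79), f_c = c(90, 85, 0),
                  p_a = 1e-9)))
  expect_equal(res$coh1, "mirA")
  # losing Bonferroni significance removes eligibility even at high frequency
  res2 <- eligible_items(list(
    coh1 = cohort(f_a = c(85, 60, 55), f_b = c(79, 79, 79), f_c = c(90, 85, 0),
                  p_a = 0.3)))
  expect_length(res2$coh1, 0)
})
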