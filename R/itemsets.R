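#' Eligible deregulated features per cohort
#'
#' Builds, for every cohort, the set of features satisfying the three-stage
#' eligibility criteria used before itemset mining: (a) significant after
#' Bonferroni correction in at least one p-value-reporting method; (b)
#' selected at least `freq_threshold` times (of `n_cv` cross-validation
#' repeats) by at least one algorithm; and (c) flagged — selection frequency
#' at least `flag_threshold` — by at least `min_algorithms` algorithms.
#'
#' @param per_dataset_results Named list (cohort) of named lists (method);
#'   each method entry is a list with `selection_frequency` (named counts
#'   over `n_cv` repeats) and optionally `p_values` (named, uncorrected).
#' @param n_cv Number of CV repeats the frequencies were counted over.
#' @param alpha Level before Bonferroni division.
#' @param freq_threshold Criterion (b) frequency cut-off.
#' @param min_algorithms Criterion (c) count.
#' @param flag_threshold Frequency at which an algorithm "flags" a feature;
#'   defaults to half of `n_cv`.
#' @return Named list mapping cohort to a character vector of eligible items.
#' @export
eligible_items <- function(per_dataset_results, n_cv = 100, alpha = 0.05,
                           freq_threshold = 80, min_algorithms = 3,
                           flag_threshold = n_cv / 2) {
  lapply(per_dataset_results, function(methods) {
    if (length(methods) < min_algorithms)
      warning("fewer methods than min_algorithms; evaluating over those available")
    feats <- unique(unlist(lapply(methods, function(m)
      names(m$selection_frequency))))
    keep <- vapply(feats, function(f) {
      freqs <- vapply(methods, function(m)
        m$selection_frequency[f] %||% 0, numeric(1))
      freqs[is.na(freqs)] <- 0
      has_p <- vapply(methods, function(m) !is.null(m$p_values), logical(1))
      bonf <- any(vapply(methods[has_p], function(m) {
        pv <- m$p_values[f]
        !is.na(pv) && pv < alpha / length(m$p_values)
      }, logical(1)))
      bonf && any(freqs >= freq_threshold) &&
        sum(freqs >= flag_threshold) >= min_algorithms
    }, logical(1))
    sort(feats[keep])
  })
}

item_key <- function(items) paste(sort(items), collapse = "\r")

itemset_support <- function(items, transactions) {
  mean(vapply(transactions, function(tr) all(items %in% tr), logical(1)))
}

#' Apriori frequent itemset mining
#'
#' Level-wise generation with the downward-closure prune: every frequent set
#' of size k is the union of two frequent (k-1)-sets sharing a prefix, and
#' candidates with any infrequent subset are discarded before counting.
#' Support is the fraction of transactions containing the whole set.
#'
#' @param transactions List of character vectors (one item set per
#'   transaction, e.g. one per cohort).
#' @param min_support Minimum support in (0, 1].
#' @return Data frame with list-column `items` (sorted), `support` and `size`,
#'   covering all itemsets with support >= `min_support`.
#' @export
apriori <- function(transactions, min_support = 0.5) {
  stopifnot(min_support > 0, min_support <= 1, length(transactions) > 0)
  transactions <- lapply(transactions, function(tr) unique(as.character(tr)))
  if (any(lengths(transactions) == 0))
    stop("transactions must be nonempty", call. = FALSE)
  universe <- sort(unique(unlist(transactions)))
  supp1 <- vapply(universe, function(i) itemset_support(i, transactions),
                  numeric(1))
  level <- lapply(universe[supp1 >= min_support], identity)
  out_items <- level
  out_supp <- supp1[supp1 >= min_support]
  frequent_keys <- vapply(level, item_key, character(1))
  while (length(level) >= 2) {
    cand <- list()
    k <- length(level[[1]])
    for (i in seq_along(level)) {
      for (j in seq_along(level)) {
        if (j <= i) next
        a <- level[[i]]; b <- level[[j]]
        if (k > 1 && !identical(a[seq_len(k - 1)], b[seq_len(k - 1)])) next
        u <- sort(union(a, b))
        if (length(u) != k + 1) next
        subs_ok <- all(vapply(seq_along(u), function(d)
          item_key(u[-d]) %in% frequent_keys, logical(1)))
        if (subs_ok) cand[[item_key(u)]] <- u
      }
    }
    if (length(cand) == 0) break
    supp <- vapply(cand, itemset_support, numeric(1),
                   transactions = transactions)
    keep <- supp >= min_support
    level <- unname(cand[keep])
    if (length(level) == 0) break
    out_items <- c(out_items, level)
    out_supp <- c(out_supp, supp[keep])
    frequent_keys <- c(frequent_keys, vapply(level, item_key, character(1)))
  }
  data.frame(items = I(out_items), support = unname(out_supp),
             size = lengths(out_items))
}

#' Association rules from frequent itemsets
#'
#' Emits every rule A -> B with A, B disjoint non-empty subsets partitioning
#' a frequent set, confidence `support(A u B) / support(A)` at least
#' `min_confidence`, and lift `confidence / support(B)`.
#'
#' @param frequent Output of [apriori()].
#' @param transactions The transactions the sets were mined from.
#' @param min_confidence Minimum confidence in (0, 1].
#' @return Data frame with list-columns `antecedent` and `consequent` plus
#'   `support`, `confidence`, `lift`.
#' @export
rules <- function(frequent, transactions, min_confidence = 0.5) {
  supp_lookup <- stats::setNames(frequent$support,
                                 vapply(frequent$items, item_key, character(1)))
  get_supp <- function(items) {
    key <- item_key(items)
    if (key %in% names(supp_lookup)) unname(supp_lookup[key])
    else itemset_support(items, transactions)
  }
  ante <- cons <- list()
  supp <- conf <- lift <- numeric(0)
  for (r in which(frequent$size >= 2)) {
    s <- frequent$items[[r]]
    s_supp <- frequent$support[r]
    n <- length(s)
    for (mask in seq_len(2^n - 2)) {
      a <- s[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      b <- setdiff(s, a)
      cf <- s_supp / get_supp(a)
      if (cf >= min_confidence) {
        ante[[length(ante) + 1L]] <- a
        cons[[length(cons) + 1L]] <- b
        supp <- c(supp, s_supp)
        conf <- c(conf, cf)
        lift <- c(lift, cf / get_supp(b))
      }
    }
  }
  data.frame(antecedent = I(ante), consequent = I(cons), support = supp,
             confidence = conf, lift = lift)
}

#' Format association rules for printing or TSV export
#'
#' @param rule_df Output of [rules()].
#' @return Data frame with comma-separated item columns.
#' @export
format_rules <- function(rule_df) {
  data.frame(
    antecedent = vapply(rule_df$antecedent, paste, character(1), collapse = ","),
    consequent = vapply(rule_df$consequent, paste, character(1), collapse = ","),
    support = rule_df$support, confidence = rule_df$confidence,
    lift = rule_df$lift)
}
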