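#' Differential-expression result container
#'
#' @param p_values Per-feature p-values in \[0, 1\] (named).
#' @param method_tag Label of the producing method.
#' @param posterior Optional per-feature posterior probability of differential
#'   expression (empirical-Bayes method); then `p_values = 1 - posterior`.
#' @return An object of class `de_result`.
#' @export
de_result <- function(p_values, method_tag, posterior = NULL) {
  stopifnot(all(is.finite(p_values)), all(p_values >= 0 & p_values <= 1))
  if (!is.null(posterior))
    stopifnot(length(posterior) == length(p_values),
              all(posterior >= 0 & posterior <= 1))
  structure(list(p_values = p_values, method_tag = method_tag,
                 posterior = posterior),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result [%s]: %d features, %d with p < 0.05\n",
              x$method_tag, length(x$p_values), sum(x$p_values < 0.05)))
  invisible(x)
}

#' Write a differential-expression result as TSV
#'
#' Columns: feature_id, p_value, posterior (when present), method_tag.
#'
#' @param result A [de_result()].
#' @param path Output file path.
#' @export
write_de_result <- function(result, path) {
  df <- data.frame(feature_id = names(result$p_values) %||%
                     sprintf("f%04d", seq_along(result$p_values)),
                   p_value = unname(result$p_values))
  if (!is.null(result$posterior)) df$posterior <- unname(result$posterior)
  df$method_tag <- result$method_tag
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_exact_tests <- function(norm, groups, phi_by_feature) {
  case <- groups == 1L
  sum_case <- rowSums(norm[, case, drop = FALSE])
  sum_ctrl <- rowSums(norm[, !case, drop = FALSE])
  mu <- rowMeans(norm)
  vapply(seq_len(nrow(norm)), function(g) {
    if (mu[g] <= 0) return(1)
    nb_exact_test(sum_case[g], sum_ctrl[g], sum(case), sum(!case),
                  mu[g], phi_by_feature[g])
  }, numeric(1))
}

#' NB exact test with tagwise weighted-conditional-likelihood dispersion
#'
#' The full pipeline: median-of-ratios size factors, integer-rounded
#' normalized counts, common dispersion by conditional maximum likelihood,
#' tagwise dispersion by weighted conditional likelihood, then the
#' conditional NB exact test per feature with its tagwise dispersion.
#'
#' @param data A [labeled_count_matrix()], or a count matrix (then `groups`
#'   must be given).
#' @param groups Binary group labels when `data` is a bare matrix.
#' @param alpha_weight Weight of the common likelihood component in the
#'   tagwise estimator; see [estimate_tagwise_dispersion()].
#' @return A [de_result()] with `method_tag = "edger"`.
#' @export
edger_like_test <- function(data, groups = NULL, alpha_weight = NULL) {
  cm <- as_counts_groups(data, groups)
  norm <- normalized_counts(cm$counts)
  phi_tag <- estimate_tagwise_dispersion(norm, cm$groups, alpha_weight)
  p <- run_exact_tests(norm, cm$groups, phi_tag)
  names(p) <- rownames(cm$counts)
  de_result(p, "edger")
}

#' NB exact test with pooled mean-variance dispersion
#'
#' Dispersion is derived per feature from a robust local regression of pooled
#' raw variance on pooled mean ([fit_mean_variance()]):
#' \eqn{\phi_g = \max(0, f(\mu_g)) / \mu_g^2}, followed by the conditional NB
#' exact test.  Runs even with a single sample per group (blind variance fit).
#'
#' @inheritParams edger_like_test
#' @return A [de_result()] with `method_tag = "deseq"`.
#' @export
deseq_like_test <- function(data, groups = NULL) {
  cm <- as_counts_groups(data, groups)
  norm <- normalized_counts(cm$counts)
  fn <- fit_mean_variance(norm, cm$groups)
  mu <- rowMeans(norm)
  phi <- ifelse(mu > 0, pmax(0, fn(mu)) / pmax(mu, 1e-8)^2, 0)
  p <- run_exact_tests(norm, cm$groups, phi)
  names(p) <- rownames(cm$counts)
  de_result(p, "deseq")
}

#' Two-model empirical-Bayes posterior of differential expression
#'
#' Compares, per feature, a null model M0 (one NB mean and dispersion shared
#' by all samples) against M1 (group-specific means).  Parameter priors are
#' built empirically by drawing `prior_reps` features at random (with
#' replacement) and recording their moment estimates under each model; the
#' marginal likelihood of a feature under a model is the average of its NB
#' likelihood over those prior draws.  The proportion of features following
#' M1 is estimated by iterating posterior re-weighting
#' (\eqn{\pi \leftarrow \mathrm{mean}_g \, P(M_1 \mid y_g)}) to convergence.
#' The reported p-value is `1 - posterior`.
#'
#' @inheritParams edger_like_test
#' @param prior_reps Number of bootstrap prior draws.
#' @param max_iter,tol Convergence controls of the proportion iteration;
#'   non-convergence warns and returns the last iterate.
#' @param seed Seed for the prior bootstrap (uses the session RNG when NULL).
#' @return A [de_result()] with `method_tag = "bayseq"` and a `posterior`.
#' @export
bayseq_like_posterior <- function(data, groups = NULL, prior_reps = 100,
                                  max_iter = 500, tol = 1e-6, seed = NULL) {
  cm <- as_counts_groups(data, groups)
  check_two_groups(cm$groups, min_per_group = 2)
  norm <- normalized_counts(cm$counts)
  G <- nrow(norm)
  case <- cm$groups == 1L
  draw_priors <- function() {
    idx <- sample.int(G, prior_reps, replace = TRUE)
    mom_phi <- function(y) {
      m <- mean(y)
      if (m <= 0) return(0)
      max(0, (var(y) - m) / m^2)
    }
    list(
      m0 = lapply(idx, function(g) {
        y <- norm[g, ]
        list(mu = max(mean(y), 1e-3), phi = mom_phi(y))
      }),
      m1 = lapply(idx, function(g) {
        y1 <- norm[g, case]; y0 <- norm[g, !case]
        list(mu1 = max(mean(y1), 1e-3), mu0 = max(mean(y0), 1e-3),
             phi = (mom_phi(y1) + mom_phi(y0)) / 2)
      }))
  }
  priors <- if (is.null(seed)) draw_priors() else
    withr::with_seed(child_seed(seed, 211L), draw_priors())

  nb_ll <- function(y, mu, phi) {
    if (phi <= 0) sum(dpois(y, mu, log = TRUE))
    else sum(dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
  }
  log_marg <- function(g) {
    y <- norm[g, ]
    l0 <- vapply(priors$m0, function(p) nb_ll(y, p$mu, p$phi), numeric(1))
    l1 <- vapply(priors$m1, function(p)
      nb_ll(y[case], p$mu1, p$phi) + nb_ll(y[!case], p$mu0, p$phi), numeric(1))
    c(logmeanexp(l0), logmeanexp(l1))
  }
  lm <- vapply(seq_len(G), log_marg, numeric(2))

  pi1 <- 0.1
  post <- rep(pi1, G)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lw1 <- log(pi1) + lm[2, ]
    lw0 <- log1p(-pi1) + lm[1, ]
    post <- 1 / (1 + exp(lw0 - lw1))
    new_pi <- min(max(mean(post), 1e-6), 1 - 1e-6)
    if (abs(new_pi - pi1) < tol) { pi1 <- new_pi; converged <- TRUE; break }
    pi1 <- new_pi
  }
  if (!converged)
    warning("model-proportion iteration did not converge; returning last iterate")
  p <- 1 - post
  names(p) <- names(post) <- rownames(cm$counts)
  res <- de_result(p, "bayseq", posterior = post)
  attr(res, "prop_de") <- pi1
  res
}

logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(mean(exp(x - m)))
}

# Accept either a labeled_count_matrix or counts + groups.
as_counts_groups <- function(data, groups = NULL) {
  if (inherits(data, "labeled_count_matrix"))
    return(list(counts = data$counts, groups = data$labels))
  if (is.null(groups)) stop("groups required when data is a bare matrix", call. = FALSE)
  if (is.factor(groups)) groups <- as.integer(groups == levels(groups)[2L])
  list(counts = as.matrix(data), groups = as.integer(groups))
}
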