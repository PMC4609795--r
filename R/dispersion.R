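# Conditional log-likelihood of the dispersion, per feature, given the
# per-group totals (equal library sizes assumed; counts should already be on
# the common scale).  With r = 1/phi and a group of n samples summing to z,
# the group's contribution is
#   sum_i lgamma(y_i + r) - n*lgamma(r) + lgamma(n*r) - lgamma(z + n*r);
# terms free of phi are dropped.  A group with a single sample contributes 0.
cond_loglik_features <- function(counts, groups, phi) {
  r <- 1 / max(phi, 1e-12)
  ll <- numeric(nrow(counts))
  for (g in unique(groups)) {
    y <- counts[, groups == g, drop = FALSE]
    n <- ncol(y)
    if (n < 2) next
    z <- rowSums(y)
    ll <- ll + rowSums(lgamma(y + r)) - n * lgamma(r) +
      lgamma(n * r) - lgamma(z + n * r)
  }
  ll
}

.phi_lower <- 1e-6
.phi_upper <- 1e2

#' Common dispersion by conditional maximum likelihood
#'
#' Maximizes, over a single dispersion \eqn{\phi} shared by all features, the
#' summed conditional log-likelihood obtained by conditioning each feature's
#' group counts on their group totals (the qCML idea).  The search is a
#' golden-section/Brent optimization on \eqn{\log\phi \in [10^{-6}, 10^2]}
#' with relative tolerance `1e-4`.  Estimates driven to the lower boundary
#' (underdispersed data) are returned as 0 with a warning; the upper cap is
#' likewise warned about.
#'
#' @param counts Count matrix, features x samples (common scale).
#' @param groups Group label per sample (two groups, each with >= 2 samples
#'   for the feature to contribute).
#' @return Scalar dispersion estimate (>= 0).
#' @export
estimate_common_dispersion <- function(counts, groups) {
  counts <- as.matrix(counts)
  check_two_groups(groups, min_per_group = 2)
  f <- function(lp) sum(cond_loglik_features(counts, groups, exp(lp)))
  opt <- optimize(f, interval = log(c(.phi_lower, .phi_upper)),
                  maximum = TRUE, tol = 1e-4)
  phi <- exp(opt$maximum)
  # Brent never lands exactly on the boundary; compare against it explicitly
  # (with a small absolute slack for the flat profile near phi = 0).
  if (phi <= 2 * .phi_lower || f(log(.phi_lower)) >= opt$objective - 1e-3) {
    warning("dispersion estimate at the lower boundary; returning 0 (under/non-overdispersed data)")
    return(0)
  }
  if (f(log(.phi_upper)) > opt$objective) {
    warning("dispersion estimate capped at ", .phi_upper)
    return(.phi_upper)
  }
  phi
}

check_two_groups <- function(groups, min_per_group = 2) {
  tab <- table(groups)
  if (length(tab) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(tab < min_per_group))
    stop("each group needs at least ", min_per_group, " samples", call. = FALSE)
  invisible(tab)
}

# Log-spaced dispersion grid used for tagwise maximization.
phi_grid <- function(n = 161) 10 ^ seq(log10(.phi_lower), log10(.phi_upper), length.out = n)

#' Tagwise dispersion by weighted conditional likelihood
#'
#' Per-feature dispersion maximizing the weighted conditional log-likelihood
#' \deqn{WL_g(\phi) = l_g(\phi) + \alpha \, \bar l(\phi),}
#' where \eqn{l_g} is the feature's conditional log-likelihood and
#' \eqn{\bar l} the average over all features (the common component).
#' `alpha_weight = 0` gives each feature its individual conditional-ML
#' estimate; a large weight shrinks every estimate onto the common maximum.
#' The default weight makes the common component count as 20 prior
#' observations per feature, i.e. `20 / (n_samples - 2)`.
#'
#' Maximization is by argmax over a log-spaced grid of 161 dispersions in
#' \eqn{[10^{-6}, 10^2]} with parabolic refinement between neighbouring grid
#' points.
#'
#' @inheritParams estimate_common_dispersion
#' @param alpha_weight Non-negative weight of the common likelihood component.
#' @return Numeric vector of per-feature dispersions (>= 0).
#' @export
estimate_tagwise_dispersion <- function(counts, groups, alpha_weight = NULL) {
  counts <- as.matrix(counts)
  check_two_groups(groups, min_per_group = 2)
  if (is.null(alpha_weight)) alpha_weight <- 20 / max(1, ncol(counts) - 2)
  stopifnot(alpha_weight >= 0)
  grid <- phi_grid()
  L <- vapply(grid, function(phi) cond_loglik_features(counts, groups, phi),
              numeric(nrow(counts)))
  if (nrow(counts) == 1L) L <- matrix(L, nrow = 1L)
  W <- L + alpha_weight * matrix(colMeans(L), nrow(L), ncol(L), byrow = TRUE)
  lg <- log10(grid)
  vapply(seq_len(nrow(W)), function(g) {
    i <- which.max(W[g, ])
    if (i == 1L) return(0)            # boundary: underdispersed feature
    if (i == length(grid)) return(grid[i])
    # parabolic interpolation on log10(phi) through the argmax and neighbours
    y <- W[g, (i - 1L):(i + 1L)]
    denom <- y[1] - 2 * y[2] + y[3]
    shift <- if (abs(denom) < 1e-12) 0 else 0.5 * (y[1] - y[3]) / denom
    10 ^ (lg[i] + shift * (lg[i + 1L] - lg[i]))
  }, numeric(1))
}

#' Pooled mean-variance local regression
#'
#' The pooled-dispersion strategy: per feature, compute the mean of the
#' (common-scale) counts over all samples and the pooled within-group sample
#' variance; subtract the shot-noise term (the mean) to obtain the raw
#' variance; then fit a robust local regression (loess, degree 1, symmetric
#' family) of raw variance on mean across all features.  The returned
#' function evaluates the fitted curve, clamped below at 0, with constant
#' extrapolation beyond the observed mean range.
#'
#' When some group has fewer than 2 samples (down to one sample per group),
#' the variance is computed blind across all samples, which conservatively
#' absorbs the group difference into the variance.
#'
#' @inheritParams estimate_common_dispersion
#' @param span Loess span.
#' @return A function mapping mean -> fitted raw variance (>= 0).
#' @export
fit_mean_variance <- function(counts, groups, span = 0.3) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 5) stop("need at least 5 features", call. = FALSE)
  mu <- rowMeans(counts)
  tab <- table(groups)
  if (any(tab < 2)) {
    message("a group has fewer than 2 samples; using blind (all-sample) variances")
    v <- apply(counts, 1, var)
  } else {
    ss <- numeric(nrow(counts))
    for (g in names(tab)) {
      y <- counts[, groups == g, drop = FALSE]
      ss <- ss + rowSums((y - rowMeans(y))^2)
    }
    v <- ss / (ncol(counts) - length(tab))
  }
  w <- v - mu                         # raw variance: total minus shot noise
  if (diff(range(mu)) < 1e-8) {
    warning("constant feature means; falling back to a constant raw-variance fit")
    const <- max(0, median(w))
    return(function(m) rep(const, length(m)))
  }
  fit <- loess(w ~ mu, degree = 1, span = span, family = "symmetric",
               control = loess.control(surface = "direct"))
  ord <- order(mu)
  xs <- mu[ord]
  ys <- pmax(0, fitted(fit)[ord])
  keep <- !duplicated(xs)
  xs <- xs[keep]; ys <- ys[keep]
  function(m) approx(xs, ys, xout = m, rule = 2)$y
}

#' @importFrom stats fitted loess.control
NULL
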