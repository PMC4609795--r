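#' Conditional NB exact test on group sums
#'
#' Tests equality of the two group means for one feature, conditional on the
#' total count.  Under the null, the case-group sum A of `n_case` i.i.d.
#' NB(`mu_hat`, `phi`) counts is NB with mean `n_case * mu_hat` and size
#' `n_case / phi` (and analogously for the control sum B), so
#' \eqn{P(A = a \mid A + B = T) \propto P(A = a) P(B = T - a)}.  The
#' two-sided p-value is the total conditional probability of all splits no
#' more likely than the observed one (the "sum of less-likely outcomes" rule).
#' `phi = 0` uses Poisson masses (the conditional law is then binomial).
#'
#' For totals above `enum_cutoff` the enumeration is restricted to a window
#' of +/- 12 conditional standard deviations around the conditional mean;
#' the mass outside is far below 1e-12.
#'
#' @param sum_case,sum_control Observed per-group sums (common-scale counts).
#' @param n_case,n_control Samples per group.
#' @param mu_hat Pooled per-sample mean under the null (positive).
#' @param phi Dispersion (>= 0).
#' @param enum_cutoff Total above which windowed enumeration is used.
#' @return Two-sided p-value in \[0, 1\]; `T = 0` returns 1.
#' @export
nb_exact_test <- function(sum_case, sum_control, n_case, n_control,
                          mu_hat, phi, enum_cutoff = 10000) {
  if (!is.finite(mu_hat) || mu_hat <= 0) stop("mu_hat must be positive", call. = FALSE)
  if (!is.finite(phi) || phi < 0) stop("phi must be non-negative", call. = FALSE)
  total <- sum_case + sum_control
  if (total == 0) return(1)
  a_seq <- if (total > enum_cutoff) {
    m_a <- total * n_case / (n_case + n_control)
    va <- n_case * (mu_hat + phi * mu_hat^2)
    vb <- n_control * (mu_hat + phi * mu_hat^2)
    s <- sqrt(va * vb / (va + vb))
    lo <- max(0, floor(m_a - 12 * s))
    hi <- min(total, ceiling(m_a + 12 * s))
    sort(unique(c(lo:hi, sum_case)))
  } else 0:total
  lp <- cond_split_logmass(a_seq, total, n_case, n_control, mu_hat, phi)
  lp_obs <- cond_split_logmass(sum_case, total, n_case, n_control, mu_hat, phi)
  lmax <- max(lp)
  pr <- exp(lp - lmax)
  keep <- lp <= lp_obs + 1e-7       # numerically "no more likely"
  min(1, sum(pr[keep]) / sum(pr))
}

# log P(A = a) + log P(B = total - a) for group sums of i.i.d. NB counts.
cond_split_logmass <- function(a, total, n_case, n_control, mu_hat, phi) {
  b <- total - a
  if (phi == 0) {
    dpois(a, n_case * mu_hat, log = TRUE) +
      dpois(b, n_control * mu_hat, log = TRUE)
  } else {
    dnbinom(a, mu = n_case * mu_hat, size = n_case / phi, log = TRUE) +
      dnbinom(b, mu = n_control * mu_hat, size = n_control / phi, log = TRUE)
  }
}
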