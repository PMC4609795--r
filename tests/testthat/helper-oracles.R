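# Independent oracles used to pin expected values.  These deliberately avoid
# the code paths they check: the exact-test oracle builds group-sum
# distributions by explicit convolution of per-sample pmfs (not the NB
# closure), and the rank-sum oracle recomputes midranks from scratch and
# enumerates subsets directly.

convolve_trunc <- function(a, b) {
  tmax <- length(a) - 1L
  out <- numeric(tmax + 1L)
  for (t in 0:tmax) out[t + 1L] <- sum(a[1:(t + 1L)] * b[(t + 1L):1])
  out
}

sum_pmf_conv <- function(n, mu, phi, tmax) {
  single <- if (phi == 0) dpois(0:tmax, mu) else dnbinom(0:tmax, mu = mu, size = 1 / phi)
  pmf <- c(1, rep(0, tmax))
  for (i in seq_len(n)) pmf <- convolve_trunc(pmf, single)
  pmf
}

oracle_exact_p <- function(sum_case, sum_control, n_case, n_control, mu, phi) {
  total <- sum_case + sum_control
  pa <- sum_pmf_conv(n_case, mu, phi, total)
  pb <- sum_pmf_conv(n_control, mu, phi, total)
  joint <- vapply(0:total, function(a) pa[a + 1L] * pb[total - a + 1L], numeric(1))
  pobs <- joint[sum_case + 1L]
  sum(joint[joint <= pobs * (1 + 1e-9)]) / sum(joint)
}

oracle_ranksum_p <- function(x, y) {
  v <- c(x, y)
  n <- length(v); nx <- length(x)
  r <- vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  ew <- nx * (n + 1) / 2
  sums <- combn(n, nx, FUN = function(i) sum(r[i]))
  w <- sum(r[seq_len(nx)])
  mean(abs(sums - ew) >= abs(w - ew) - 1e-9)
}

oracle_frequent <- function(transactions, min_support) {
  uni <- sort(unique(unlist(transactions)))
  items <- list(); supp <- numeric(0)
  for (mask in seq_len(2^length(uni) - 1L)) {
    s <- uni[bitwAnd(mask, 2^(seq_along(uni) - 1L)) > 0]
    sp <- mean(vapply(transactions, function(tr) all(s %in% tr), logical(1)))
    if (sp >= min_support) {
      items <- c(items, list(s))
      supp <- c(supp, sp)
    }
  }
  list(items = items, support = supp)
}

# Two-group NB matrix with every feature sharing the same parameters.
make_nb_matrix <- function(p, n1, n0, mu1, mu0, phi1 = 1, phi0 = phi1, seed = 1) {
  withr::with_seed(seed, {
    m <- cbind(matrix(rnbinom(p * n1, mu = mu1, size = 1 / max(phi1, 1e-12)), p, n1),
               matrix(rnbinom(p * n0, mu = mu0, size = 1 / max(phi0, 1e-12)), p, n0))
    if (phi1 == 0) m[, 1:n1] <- rpois(p * n1, mu1)
    if (phi0 == 0) m[, n1 + 1:n0] <- rpois(p * n0, mu0)
    m
  })
}

nb_groups <- function(n1, n0) c(rep(1L, n1), rep(0L, n0))
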