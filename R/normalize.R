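#' Median-of-ratios size factors
#'
#' Per-sample scaling constants correcting library-size differences: each
#' sample's factor is the median, over features, of the ratio of its count to
#' the feature's geometric mean across samples.  Factors are rescaled to have
#' geometric mean 1.  Features containing a zero are excluded from the
#' reference.  When too few features are positive in every sample for the
#' median to be informative (fewer than ~10 on a full-size matrix), a
#' pseudocount-smoothed median-of-ratios over all features (counts + 0.5) is
#' used instead, with a warning; this keeps factors near 1 on sparse
#' discrete data instead of echoing single-feature noise.
#'
#' @param counts Non-negative count matrix, features x samples.
#' @return Positive numeric vector, one factor per sample, geometric mean 1.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) return(stats::setNames(1, colnames(counts)))
  if (all(counts == 0)) stop("all counts are zero; size factors undefined", call. = FALSE)
  lc <- log(counts)
  ref <- rowMeans(lc)              # -Inf whenever the feature has a zero
  ok <- is.finite(ref)
  # The strict path needs enough all-positive reference features to make the
  # median informative; a handful of features would just echo their own
  # sampling noise into every sample's factor.
  min_ref <- max(3, min(10, ceiling(0.02 * nrow(counts))))
  if (sum(ok) >= min_ref) {
    sf <- apply(lc[ok, , drop = FALSE] - ref[ok], 2, median)
  } else {
    warning("too few features with all-positive counts; ",
            "using pseudocount-smoothed median-of-ratios over the positive information")
    lp <- log(counts + 0.5)
    sf <- apply(lp - rowMeans(lp), 2, median)
  }
  sf <- sf - mean(sf)              # geometric mean 1 on the log scale
  exp(sf)
}

# Counts divided by size factors and rounded back to integers; the scale the
# exact tests operate on.  On simulated data factors are ~1 so this is a no-op.
normalized_counts <- function(counts, sf = size_factors(counts)) {
  round(sweep(as.matrix(counts), 2, sf, "/"))
}
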