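#' Define a simulation scenario
#'
#' A scenario fixes the parameters of the case/control negative binomial (NB)
#' generator: group sizes, number of features, the signal-to-noise ratio `s2n`
#' (ratio of truly significant to insignificant features), and the NB mean and
#' dispersion of significant features in each group and of noise features.
#' The defaults are the baseline study conditions: 20 case and 20 control
#' samples, 500 features, control/noise mean 5 with dispersion 1, case mean 20
#' with dispersion 1, and `s2n = 0.1`.
#'
#' The NB parameterization throughout the package is
#' \eqn{Var(X) = \mu + \phi \mu^2}; `phi = 0` degenerates to Poisson.
#'
#' @param scenario_id Label for the scenario (e.g. `"A1"`, `"C5"`, `"baseline"`).
#' @param n_case,n_control Samples per group (each at least 2).
#' @param n_features Number of features (rows) simulated.
#' @param s2n Ratio of significant to insignificant features.
#' @param mu_sig_case,mu_sig_control NB mean of significant features in the
#'   case and control group.
#' @param mu_noise NB mean of insignificant features (both groups).
#' @param phi_sig_case,phi_sig_control,phi_noise NB dispersions.
#' @param n_reps Default replication count for evaluation harnesses.
#' @param seed Root RNG seed for the scenario.
#' @param s2n_rule How `s2n` maps to the number of significant features:
#'   `"ratio"` (default) reads it literally as significant/insignificant, so
#'   `n_sig = round(n_features * s2n / (1 + s2n))`; `"proportion"` uses
#'   `n_sig = round(n_features * s2n)`.
#' @return An object of class `scenario_config`.
#' @seealso [scenario_grid()], [simulate_dataset()]
#' @export
scenario_config <- function(scenario_id = "baseline",
                            n_case = 20, n_control = 20,
                            n_features = 500, s2n = 0.1,
                            mu_sig_case = 20, mu_sig_control = 5, mu_noise = 5,
                            phi_sig_case = 1, phi_sig_control = 1, phi_noise = 1,
                            n_reps = 1000, seed = 1,
                            s2n_rule = c("ratio", "proportion")) {
  s2n_rule <- match.arg(s2n_rule)
  cfg <- list(scenario_id = as.character(scenario_id),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_features = as.integer(n_features), s2n = as.double(s2n),
              mu_sig_case = as.double(mu_sig_case),
              mu_sig_control = as.double(mu_sig_control),
              mu_noise = as.double(mu_noise),
              phi_sig_case = as.double(phi_sig_case),
              phi_sig_control = as.double(phi_sig_control),
              phi_noise = as.double(phi_noise),
              n_reps = as.integer(n_reps), seed = as.integer(seed),
              s2n_rule = s2n_rule)
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  mus <- c(cfg$mu_sig_case, cfg$mu_sig_control, cfg$mu_noise)
  phis <- c(cfg$phi_sig_case, cfg$phi_sig_control, cfg$phi_noise)
  if (any(!is.finite(mus)) || any(mus <= 0))
    stop("all NB means must be positive", call. = FALSE)
  if (any(!is.finite(phis)) || any(phis < 0))
    stop("all NB dispersions must be non-negative", call. = FALSE)
  if (!is.finite(cfg$s2n) || cfg$s2n <= 0)
    stop("s2n must be positive", call. = FALSE)
  if (cfg$n_case < 2 || cfg$n_control < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (cfg$n_features < 2) stop("need at least 2 features", call. = FALSE)
  if (cfg$n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  invisible(cfg)
}

#' Number of significant features implied by a scenario
#'
#' @param config A [scenario_config()].
#' @return Integer count of truly significant features.
#' @export
n_sig_features <- function(config) {
  validate_scenario_config(config)
  n <- switch(config$s2n_rule,
              ratio = round(config$n_features * config$s2n / (1 + config$s2n)),
              proportion = round(config$n_features * config$s2n))
  as.integer(max(1L, n))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario '%s': n=%d/%d, %d features, s2n=%g (%d significant)\n",
              x$scenario_id, x$n_case, x$n_control, x$n_features, x$s2n,
              n_sig_features(x)))
  cat(sprintf("  significant: case NB(mu=%g, phi=%g) vs control NB(mu=%g, phi=%g)\n",
              x$mu_sig_case, x$phi_sig_case, x$mu_sig_control, x$phi_sig_control))
  cat(sprintf("  noise:       NB(mu=%g, phi=%g) in both groups\n",
              x$mu_noise, x$phi_noise))
  invisible(x)
}

#' Draw negative binomial counts
#'
#' Draws `n` i.i.d. counts with mean `mean` and variance
#' `mean + dispersion * mean^2`.  `dispersion = 0` gives Poisson draws.
#' Uses the session RNG.
#'
#' @param mean Positive NB mean.
#' @param dispersion Non-negative dispersion \eqn{\phi}.
#' @param n Number of draws.
#' @return Integer vector of length `n`.
#' @export
nb_sample <- function(mean, dispersion, n) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive", call. = FALSE)
  if (!is.finite(dispersion) || dispersion < 0)
    stop("dispersion must be non-negative", call. = FALSE)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (dispersion == 0) rpois(n, lambda = mean)
  else rnbinom(n, mu = mean, size = 1 / dispersion)
}

#' Construct a labelled count matrix
#'
#' The container used throughout the package: an integer count matrix
#' (features in rows, samples in columns), a binary group label per sample
#' (1 = case, 0 = control) and, for simulated data, a logical truth mask
#' marking the truly significant features.
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @param labels Vector of 0/1 (or a two-level factor), one per sample.
#' @param truth Optional logical vector, one per feature.
#' @param feature_ids,sample_ids Optional identifiers; derived from dimnames
#'   or generated when missing.
#' @return An object of class `labeled_count_matrix`.
#' @export
labeled_count_matrix <- function(counts, labels, truth = NULL,
                                 feature_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (is.factor(labels)) labels <- as.integer(labels == levels(labels)[2L])
  labels <- as.integer(labels)
  if (length(labels) != ncol(counts))
    stop("labels length must equal the number of samples", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  feature_ids <- feature_ids %||% rownames(counts) %||%
    sprintf("f%04d", seq_len(nrow(counts)))
  sample_ids <- sample_ids %||% colnames(counts) %||%
    sprintf("s%03d", seq_len(ncol(counts)))
  rownames(counts) <- feature_ids
  colnames(counts) <- sample_ids
  if (!is.null(truth)) {
    truth <- as.logical(truth)
    if (length(truth) != nrow(counts))
      stop("truth length must equal the number of features", call. = FALSE)
    names(truth) <- feature_ids
  }
  structure(list(counts = counts, labels = labels, truth = truth,
                 feature_ids = feature_ids, sample_ids = sample_ids),
            class = "labeled_count_matrix")
}

#' @export
print.labeled_count_matrix <- function(x, ...) {
  cat(sprintf("labeled_count_matrix: %d features x %d samples (%d case / %d control)%s\n",
              nrow(x$counts), ncol(x$counts), sum(x$labels == 1L),
              sum(x$labels == 0L),
              if (is.null(x$truth)) "" else
                sprintf(", %d significant", sum(x$truth))))
  invisible(x)
}

#' Simulate one case/control NB count matrix
#'
#' The leading `n_sig_features(config)` features are drawn with the
#' significant-feature parameters (case group: `mu_sig_case`, `phi_sig_case`;
#' control group: `mu_sig_control`, `phi_sig_control`); the remaining features
#' are noise, drawn as NB(`mu_noise`, `phi_noise`) in both groups.  No
#' library-size variation is simulated.  The RNG stream is derived from
#' `(config$seed, rep_index)`, so the same pair always reproduces the same
#' matrix and replications are independently reproducible.
#'
#' @param config A [scenario_config()].
#' @param rep_index Replication index (1-based).
#' @return A [labeled_count_matrix()] with a truth mask.
#' @export
simulate_dataset <- function(config, rep_index = 1L) {
  validate_scenario_config(config)
  rep_index <- as.integer(rep_index)
  if (rep_index < 1L || rep_index > config$n_reps)
    stop("rep_index must lie in [1, n_reps]", call. = FALSE)
  n_sig <- n_sig_features(config)
  p <- config$n_features
  n1 <- config$n_case
  n0 <- config$n_control
  counts <- withr::with_seed(child_seed(config$seed, rep_index), {
    m <- matrix(0L, nrow = p, ncol = n1 + n0)
    if (n_sig > 0) {
      m[seq_len(n_sig), seq_len(n1)] <-
        nb_sample(config$mu_sig_case, config$phi_sig_case, n_sig * n1)
      m[seq_len(n_sig), n1 + seq_len(n0)] <-
        nb_sample(config$mu_sig_control, config$phi_sig_control, n_sig * n0)
    }
    if (n_sig < p) {
      m[(n_sig + 1L):p, ] <-
        nb_sample(config$mu_noise, config$phi_noise, (p - n_sig) * (n1 + n0))
    }
    m
  })
  labeled_count_matrix(
    counts,
    labels = c(rep(1L, n1), rep(0L, n0)),
    truth = seq_len(p) <= n_sig,
    sample_ids = c(sprintf("case_%02d", seq_len(n1)),
                   sprintf("ctrl_%02d", seq_len(n0))))
}

#' The full A/B/C scenario grid
#'
#' Fifteen scenarios along three axes, each holding the other parameters at
#' baseline: A1-A5 vary `s2n` over 0.01, 0.05, 0.1, 0.15, 0.20; B1-B5 vary the
#' case-group mean of significant features over 10, 15, 20, 25, 30; C1-C5 vary
#' the case-group dispersion of significant features over 0.125, 0.5, 1, 2, 8.
#' A3, B3 and C3 coincide with the baseline (mean 20, dispersion 1, s2n 0.1).
#'
#' @param n_reps,seed Passed to every [scenario_config()] in the grid.
#' @return Named list of 15 `scenario_config` objects.
#' @export
scenario_grid <- function(n_reps = 1000, seed = 1) {
  s2n_vals <- c(0.01, 0.05, 0.1, 0.15, 0.20)
  mu_vals <- c(10, 15, 20, 25, 30)
  phi_vals <- c(0.125, 0.5, 1, 2, 8)
  grid <- list()
  for (i in 1:5) {
    grid[[paste0("A", i)]] <- scenario_config(paste0("A", i), s2n = s2n_vals[i],
                                              n_reps = n_reps, seed = seed)
    grid[[paste0("B", i)]] <- scenario_config(paste0("B", i),
                                              mu_sig_case = mu_vals[i],
                                              n_reps = n_reps, seed = seed)
    grid[[paste0("C", i)]] <- scenario_config(paste0("C", i),
                                              phi_sig_case = phi_vals[i],
                                              n_reps = n_reps, seed = seed)
  }
  grid[c(paste0("A", 1:5), paste0("B", 1:5), paste0("C", 1:5))]
}

#' Write / read a scenario grid as TSV
#'
#' One scenario per row, columns named as the `scenario_config` fields.
#'
#' @param grid List of `scenario_config` objects.
#' @param path File path.
#' @return `read_scenario_grid` returns a named list of `scenario_config`s.
#' @export
write_scenario_grid <- function(grid, path) {
  df <- do.call(rbind, lapply(grid, function(cfg)
    as.data.frame(unclass(cfg), stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenario_grid
#' @export
read_scenario_grid <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  grid <- lapply(seq_len(nrow(df)), function(i) do.call(scenario_config, as.list(df[i, ])))
  names(grid) <- df$scenario_id
  grid
}
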