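#' Confusion counts of a selection against the truth mask
#'
#' @param selected,truth Equal-length logical masks.
#' @return Named numeric vector `c(tp, fp, tn, fn)`.
#' @export
confusion <- function(selected, truth) {
  if (length(selected) != length(truth))
    stop("selected and truth must have the same length", call. = FALSE)
  selected <- as.logical(selected); truth <- as.logical(truth)
  c(tp = sum(selected & truth), fp = sum(selected & !truth),
    tn = sum(!selected & !truth), fn = sum(!selected & truth))
}

#' Type-I error and power of a p-value vector at two levels
#'
#' Rejection is `p < alpha` (nominal) and `p < alpha / n_tests` (Bonferroni);
#' the type-I error is the rejection rate over truth-negative features and
#' the power the rate over truth-positive features.  An empty truth class
#' yields `NA` for its rates.
#'
#' @param p_values Per-feature p-values.
#' @param truth Logical truth mask.
#' @param alpha Nominal level.
#' @param n_tests Bonferroni denominator (defaults to the number of features).
#' @return Named list with `type1_nominal`, `power_nominal`, `type1_bonf`,
#'   `power_bonf`.
#' @export
type1_power <- function(p_values, truth, alpha = 0.05,
                        n_tests = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  truth <- as.logical(truth)
  rate <- function(rej, mask) if (any(mask)) mean(rej[mask]) else NA_real_
  rn <- p_values < alpha
  rb <- p_values < alpha / n_tests
  list(type1_nominal = rate(rn, !truth), power_nominal = rate(rn, truth),
       type1_bonf = rate(rb, !truth), power_bonf = rate(rb, truth))
}

# One replication of one scenario for a set of methods; returns a list of
# per-method confusion rows at each applicable level.
replicate_once <- function(config, rep_index, methods, alpha, seed, params) {
  data <- simulate_dataset(config, rep_index)
  out <- list()
  for (m in seq_along(methods)) {
    method <- methods[m]
    rows <- tryCatch({
      res <- withr::with_seed(
        child_seed(seed, rep_index, m),
        select_features(method, data, alpha = alpha,
                        params = params[[method]] %||% list()))
      rows <- list(nominal = confusion(res$selected, data$truth))
      if (res$score_direction == "lower") {   # p-value method: add Bonferroni
        thr <- alpha / length(res$scores)
        rows$bonferroni <- confusion(res$scores < thr, data$truth)
      }
      rows
    }, error = function(e) e)
    out[[method]] <- rows
  }
  out
}

#' Run a scenario over replications and average the evaluation indexes
#'
#' Simulates `n_reps` datasets from `config`, applies every method to each,
#' and averages the confusion counts over replications.  Sensitivity,
#' specificity, type-I error and power are formed from the mean counts
#' (equivalently, with fixed class sizes, the mean of per-replication rates).
#' P-value-based methods get both a `nominal` and a `bonferroni` row
#' (denominator = number of features tested).  Method failures in a
#' replication are logged and excluded from that method's average.
#' Results are deterministic for a fixed `seed` regardless of `workers`.
#'
#' @param config A [scenario_config()].
#' @param methods Character vector of selector ids (see [select_features()]).
#' @param n_reps Number of replications (defaults to `config$n_reps`).
#' @param seed Root seed (defaults to `config$seed`).
#' @param alpha Nominal level.
#' @param workers Parallel workers (fork-based; 1 = serial).
#' @param params Named list (by method) of extra selector arguments.
#' @return A data frame of evaluation rows (class `eval_metrics`): method_tag,
#'   scenario_id, level, mean tp/fp/tn/fn, sensitivity, specificity, type1,
#'   power, n_reps_used, n_failures.
#' @export
run_replications <- function(config, methods, n_reps = config$n_reps,
                             seed = config$seed, alpha = 0.05, workers = 1,
                             params = list()) {
  validate_scenario_config(config)
  stopifnot(length(methods) >= 1)
  config$n_reps <- as.integer(n_reps)
  reps <- seq_len(n_reps)
  worker <- function(i) replicate_once(config, i, methods, alpha, seed, params)
  per_rep <- if (workers > 1) {
    parallel::mclapply(reps, worker, mc.cores = workers)
  } else {
    lapply(reps, worker)
  }
  rows <- list()
  for (method in methods) {
    by_level <- list()
    failures <- 0L
    for (i in reps) {
      r <- per_rep[[i]][[method]]
      if (inherits(r, "error")) { failures <- failures + 1L; next }
      for (lv in names(r)) by_level[[lv]] <- rbind(by_level[[lv]], r[[lv]])
    }
    if (failures > 0)
      warning(sprintf("%s failed in %d/%d replications; excluded", method,
                      failures, n_reps))
    for (lv in names(by_level)) {
      m <- colMeans(by_level[[lv]])
      rows[[length(rows) + 1L]] <- data.frame(
        method_tag = method, scenario_id = config$scenario_id, level = lv,
        tp = m["tp"], fp = m["fp"], tn = m["tn"], fn = m["fn"],
        sensitivity = m["tp"] / (m["tp"] + m["fn"]),
        specificity = m["tn"] / (m["tn"] + m["fp"]),
        type1 = m["fp"] / (m["fp"] + m["tn"]),
        power = m["tp"] / (m["tp"] + m["fn"]),
        n_reps_used = nrow(by_level[[lv]]), n_failures = failures,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_metrics", class(out))
  out
}

#' Benchmark a scenario grid
#'
#' Runs [run_replications()] for every scenario and binds the rows.
#'
#' @param grid Named list of [scenario_config()]s (e.g. [scenario_grid()]).
#' @param methods,n_reps,seed,alpha,workers,params As in [run_replications()].
#' @return An `eval_metrics` data frame over all scenarios.
#' @export
benchmark_tables <- function(grid, methods, n_reps = 1000, seed = 1,
                             alpha = 0.05, workers = 1, params = list()) {
  out <- do.call(rbind, lapply(grid, function(cfg) {
    cfg$seed <- as.integer(seed)
    run_replications(cfg, methods, n_reps = n_reps, seed = seed,
                     alpha = alpha, workers = workers, params = params)
  }))
  rownames(out) <- NULL
  class(out) <- c("eval_metrics", class(out))
  out
}

#' Pivot benchmark rows into a sensitivity/specificity report
#'
#' One row per scenario; one column per method x level holding
#' `"sens/spec"` cells rounded to two decimals.
#'
#' @param results An `eval_metrics` data frame from [benchmark_tables()].
#' @return A data frame report.
#' @export
format_benchmark_table <- function(results) {
  results$cell <- sprintf("%.2f/%.2f", results$sensitivity, results$specificity)
  results$col <- ifelse(results$level == "bonferroni",
                        paste0(results$method_tag, "_bonf"), results$method_tag)
  scen <- unique(results$scenario_id)
  cols <- unique(results$col)
  out <- data.frame(scenario = scen)
  for (cl in cols) {
    v <- rep(NA_character_, length(scen))
    sub <- results[results$col == cl, ]
    v[match(sub$scenario_id, scen)] <- sub$cell
    out[[cl]] <- v
  }
  out
}

#' Write benchmark results as TSV
#'
#' Writes the long-format rows and, when `wide = TRUE`, the pivoted
#' sensitivity/specificity report.
#'
#' @param results An `eval_metrics` data frame.
#' @param path Output path.
#' @param wide Write the pivoted report instead of long format.
#' @export
write_benchmark_tsv <- function(results, path, wide = FALSE) {
  df <- if (wide) format_benchmark_table(results) else as.data.frame(results)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
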