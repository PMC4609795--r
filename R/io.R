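#' Read a count matrix with labels
#'
#' Reads a TSV/CSV count table (first column feature ids, header row of
#' sample ids) together with binary case/control labels supplied either as
#' the name of a row inside the table (`label_row`), as a two-column sidecar
#' file `sample_id<TAB>label` (`label_file`), or directly as a vector
#' (`labels`).  The parse is strict: ragged rows, non-numeric or non-integer
#' cells, and duplicate feature ids raise informative errors.
#'
#' @param path Path to the count table.
#' @param label_row Name of the row holding the 0/1 labels.
#' @param label_file Path to a sidecar label file.
#' @param labels Numeric/integer label vector in column order.
#' @param sep Field separator; guessed from the extension when NULL
#'   (`.csv` = comma, otherwise tab).
#' @return A [labeled_count_matrix()] without a truth mask, carrying a
#'   `provenance` attribute (source path and filter log).
#' @export
read_count_matrix <- function(path, label_row = NULL, label_file = NULL,
                              labels = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  if (length(lines) < 2) stop("count table needs a header and at least one feature row", call. = FALSE)
  cells <- strsplit(lines, sep, fixed = TRUE)
  hdr <- cells[[1]]
  n_col <- length(cells[[2]])
  if (length(hdr) == n_col - 1) hdr <- c("feature_id", hdr)  # unnamed id column
  if (length(hdr) != n_col)
    stop("header has ", length(hdr), " fields but data rows have ", n_col, call. = FALSE)
  sample_ids <- hdr[-1]
  body <- cells[-1]
  widths <- lengths(body)
  if (any(widths != n_col))
    stop("ragged row(s) at line(s): ",
         paste(which(widths != n_col) + 1L, collapse = ", "), call. = FALSE)
  feature_ids <- vapply(body, `[`, character(1), 1L)
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  mat <- matrix(NA_real_, length(body), n_col - 1L,
                dimnames = list(feature_ids, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at row %d (feature '%s'), column %d (sample '%s'): '%s'",
                   i + 1L, feature_ids[i], j + 1L, sample_ids[j],
                   body[[i]][j + 1L]), call. = FALSE)
    }
    mat[i, ] <- v
  }
  if (!is.null(label_row)) {
    if (!label_row %in% feature_ids)
      stop("label row '", label_row, "' not found in the table", call. = FALSE)
    labels <- mat[label_row, ]
    mat <- mat[feature_ids != label_row, , drop = FALSE]
  } else if (!is.null(label_file)) {
    lab <- read.delim(label_file, header = FALSE,
                      col.names = c("sample_id", "label"))
    miss <- setdiff(sample_ids, lab$sample_id)
    if (length(miss))
      stop("label file lacks sample(s): ", paste(miss, collapse = ", "), call. = FALSE)
    labels <- lab$label[match(sample_ids, lab$sample_id)]
  } else if (is.null(labels)) {
    stop("labels must be supplied via label_row, label_file or labels", call. = FALSE)
  }
  if (any(mat != round(mat)))
    stop("counts must be integers", call. = FALSE)
  out <- labeled_count_matrix(mat, labels)
  attr(out, "provenance") <- list(source = path, filter_log = list())
  out
}

#' Write a count matrix (and optional truth sidecar) as TSV
#'
#' @param data A [labeled_count_matrix()].
#' @param path Output path for the count table; the labels are written as a
#'   sidecar `<path>.labels.tsv`, and the truth mask (when present) as
#'   `<path>.truth.tsv` (columns feature_id, is_significant).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(data, path) {
  df <- data.frame(feature_id = data$feature_ids, data$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = data$sample_ids, label = data$labels),
              paste0(path, ".labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(data$truth))
    write.table(data.frame(feature_id = data$feature_ids,
                           is_significant = data$truth),
                paste0(path, ".truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Remove low-expression features
#'
#' Drops every feature whose total count over all samples is strictly below
#' `min_total` (the conventional pre-filter for sequencing count tables; the
#' default keeps a feature summing to exactly 10).  The removal is recorded
#' in the object's provenance filter log.  Removing every feature is an
#' error.
#'
#' @param data A [labeled_count_matrix()].
#' @param min_total Minimum row sum to keep a feature.
#' @return The filtered [labeled_count_matrix()].
#' @export
filter_low_expression <- function(data, min_total = 10) {
  totals <- rowSums(data$counts)
  keep <- totals >= min_total
  if (!any(keep)) stop("filter removed every feature", call. = FALSE)
  prov <- attr(data, "provenance") %||% list(source = NA_character_,
                                             filter_log = list())
  out <- labeled_count_matrix(data$counts[keep, , drop = FALSE], data$labels,
                              truth = if (!is.null(data$truth)) data$truth[keep],
                              sample_ids = data$sample_ids)
  prov$filter_log <- c(prov$filter_log, list(list(
    filter = "low_expression", min_total = min_total,
    removed = data$feature_ids[!keep],
    reason = sprintf("total count < %g", min_total))))
  attr(out, "provenance") <- prov
  out
}
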