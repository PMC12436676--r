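#' Construct a dataset for model-based clustering
#'
#' Bundles an n x p numeric score matrix with variable names and (optionally)
#' known group labels used for evaluation. Missing values are rejected: the
#' mixture models in this package assume complete data.
#'
#' @param values Numeric matrix or data frame, observations in rows.
#' @param variable_names Optional character vector of length p; defaults to
#'   the column names of `values`.
#' @param true_labels Optional vector of known group identifiers (length n),
#'   kept alongside the data for adjusted-Rand-index evaluation only; never
#'   used during fitting.
#' @return An object of class `cnmix_dataset` with elements `values`
#'   (numeric matrix), `variable_names`, `true_labels`, `n`, `p`.
#' @export
cnmix_dataset <- function(values, variable_names = NULL, true_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  n <- nrow(values)
  p <- ncol(values)
  if (n < 1L || p < 1L) stop("need n >= 1 and p >= 1", call. = FALSE)
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column %d; complete data required",
                 idx[1L], idx[2L]), call. = FALSE)
  }
  variable_names <- variable_names %||% colnames(values) %||%
    paste0("V", seq_len(p))
  if (length(variable_names) != p) stop("need one name per column", call. = FALSE)
  if (anyDuplicated(variable_names))
    stop("duplicate variable names: ",
         paste(unique(variable_names[duplicated(variable_names)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(true_labels) && length(true_labels) != n)
    stop("`true_labels` must have length n", call. = FALSE)
  colnames(values) <- variable_names
  structure(
    list(values = values, variable_names = variable_names,
         true_labels = true_labels, n = n, p = p),
    class = "cnmix_dataset"
  )
}

#' @export
print.cnmix_dataset <- function(x, ...) {
  cat(sprintf("<cnmix_dataset> %d observations x %d variables\n", x$n, x$p))
  cat("  variables:", paste(x$variable_names, collapse = ", "), "\n")
  if (!is.null(x$true_labels))
    cat("  known labels:",
        paste(sprintf("%s (%d)", names(table(x$true_labels)),
                      table(x$true_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Keep a subset of variables
#'
#' @param data A `cnmix_dataset`.
#' @param vars Character vector of variable names or integer indices.
#' @return A `cnmix_dataset` restricted to the selected columns.
#' @export
subset_variables <- function(data, vars) {
  stopifnot(inherits(data, "cnmix_dataset"))
  if (is.character(vars)) {
    miss <- setdiff(vars, data$variable_names)
    if (length(miss))
      stop("unknown variables: ", paste(miss, collapse = ", "), call. = FALSE)
    vars <- match(vars, data$variable_names)
  }
  cnmix_dataset(data$values[, vars, drop = FALSE],
                variable_names = data$variable_names[vars],
                true_labels = data$true_labels)
}

#' Read a dataset from CSV
#'
#' Expects a header row of variable names; decimal-point dialect. An optional
#' label column (known diagnosis) is split off into `true_labels`. Any
#' non-numeric or missing cell is an error that names the offending row and
#' column.
#'
#' @param path CSV file path.
#' @param label_column Name of the label column to split off, or `NULL`.
#' @return A `cnmix_dataset`.
#' @export
load_dataset <- function(path, label_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df))
      stop("label column '", label_column, "' not present in ", path,
           call. = FALSE)
    labels <- df[[label_column]]
    df <- df[setdiff(names(df), label_column)]
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric or missing value in column '%s', row %d",
                   names(df)[j], bad[1L]), call. = FALSE)
    df[[j]] <- num
  }
  cnmix_dataset(as.matrix(df), variable_names = names(df), true_labels = labels)
}

#' Write a dataset (and its truth record, if any) to CSV
#'
#' @param data A `cnmix_dataset`.
#' @param path Output CSV path for the score matrix (plus label column when
#'   labels are present).
#' @param truth Optional truth record from [simulate_mixture()]; written to a
#'   `*_truth.csv` sidecar with true labels and good/bad indicators.
#' @param label_column Column name used for labels in the main CSV.
#' @return Invisibly, the main path.
#' @export
write_dataset <- function(data, path, truth = NULL, label_column = "group") {
  stopifnot(inherits(data, "cnmix_dataset"))
  df <- as.data.frame(data$values)
  if (!is.null(data$true_labels)) df[[label_column]] <- data$true_labels
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(truth)) {
    sidecar <- sub("\\.csv$", "_truth.csv", path)
    utils::write.csv(
      data.frame(label = truth$labels, bad = as.integer(truth$bad)),
      sidecar, row.names = FALSE)
  }
  invisible(path)
}
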