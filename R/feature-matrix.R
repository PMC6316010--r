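# FeatureMatrix: the common currency between extraction, selection and
# classification stages. A thin S3 wrapper around a numeric matrix with
# aligned sample ids and class labels.

#' Construct a feature matrix
#'
#' @param values numeric matrix, samples in rows, features in columns; no
#'   missing values allowed.
#' @param feature_names unique feature identifiers (defaults to column
#'   names).
#' @param sample_ids sample identifiers (defaults to row names).
#' @param labels per-sample class, each `"case"`, `"control"` or
#'   `"unknown"`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_names = colnames(values),
                           sample_ids = rownames(values), labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(values)))
  if (is.null(sample_ids))
    sample_ids <- paste0("S", seq_len(nrow(values)))
  feature_names <- as.character(feature_names)
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)
  if (anyNA(values) || !all(is.finite(values)))
    stop("feature values must be finite and non-missing")
  if (length(feature_names) != ncol(values))
    stop("feature_names length does not match the number of columns")
  if (anyDuplicated(feature_names))
    stop("feature_names must be unique")
  if (length(sample_ids) != nrow(values) || length(labels) != nrow(values))
    stop("sample_ids and labels must align with the rows")
  if (!all(labels %in% c("case", "control", "unknown")))
    stop("labels must be 'case', 'control' or 'unknown'")
  dimnames(values) <- list(sample_ids, feature_names)
  structure(list(values = values, feature_names = feature_names,
                 sample_ids = sample_ids, labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " features (", sum(x$labels == "case"), " case / ",
      sum(x$labels == "control"), " control)\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset a feature matrix by samples and/or features
#'
#' @param fm a [feature_matrix()].
#' @param samples row indices (or sample ids) to keep; `NULL` keeps all.
#' @param features column indices (or feature names) to keep; `NULL` keeps
#'   all.
#' @return A `feature_matrix` restricted to the requested rows/columns.
#' @export
fm_subset <- function(fm, samples = NULL, features = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(fm$values)) else samples
  if (is.character(si)) si <- match(si, fm$sample_ids)
  fi <- if (is.null(features)) seq_len(ncol(fm$values)) else features
  if (is.character(fi)) {
    miss <- setdiff(fi, fm$feature_names)
    if (length(miss))
      stop("unknown feature names: ", paste(utils::head(miss, 5L), collapse = ", "))
    fi <- match(fi, fm$feature_names)
  }
  feature_matrix(fm$values[si, fi, drop = FALSE],
                 feature_names = fm$feature_names[fi],
                 sample_ids = fm$sample_ids[si],
                 labels = fm$labels[si])
}
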