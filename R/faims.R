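# FAIMS sample data model, file I/O and wavelet feature extraction.
#
# A FAIMS (field-asymmetric ion mobility spectrometry) measurement scans
# the compensation voltage from -6 V to +6 V in 512 steps at each of 51
# dispersion-field settings (0-99%), for both ion polarities. One sample
# is therefore a 512 x 102 ion-current matrix (52,224 values): rows are
# compensation-voltage steps, columns 1-51 the positive-polarity
# dispersion-field sweep and columns 52-102 the negative-polarity sweep.

FAIMS_CV_STEPS <- 512L
FAIMS_DF_STEPS <- 51L
FAIMS_COLS <- 2L * FAIMS_DF_STEPS

#' Construct a FAIMS sample
#'
#' @param matrix numeric 512 x 102 ion-current matrix (compensation-voltage
#'   steps x dispersion-field steps, positive polarity block then negative).
#' @param sample_id sample identifier.
#' @param label class label: `"case"`, `"control"` or `"unknown"`.
#' @param age_days sample storage age at analysis, in days (`NA` if
#'   unknown).
#' @param replicate_index technical replicate number (1-based).
#' @return An object of class `faims_sample`.
#' @export
faims_sample <- function(matrix, sample_id, label = "unknown",
                         age_days = NA_real_, replicate_index = 1L) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("matrix must be a numeric matrix")
  if (nrow(matrix) != FAIMS_CV_STEPS || ncol(matrix) != FAIMS_COLS)
    stop("FAIMS matrix shape error: expected ", FAIMS_CV_STEPS, " x ",
         FAIMS_COLS, ", found ", nrow(matrix), " x ", ncol(matrix))
  if (!all(is.finite(matrix)))
    stop("FAIMS matrix must contain only finite values")
  stopifnot(length(label) == 1L, label %in% c("case", "control", "unknown"))
  if (!is.na(age_days) && age_days < 0) stop("age_days must be non-negative")
  structure(list(sample_id = as.character(sample_id), matrix = unname(matrix),
                 label = label, age_days = as.numeric(age_days),
                 replicate_index = as.integer(replicate_index)),
            class = "faims_sample")
}

#' @export
print.faims_sample <- function(x, ...) {
  cat("<faims_sample> ", x$sample_id, ": ", nrow(x$matrix), " x ",
      ncol(x$matrix), " ion-current matrix, label=", x$label,
      ", age_days=", x$age_days, "\n", sep = "")
  invisible(x)
}

parse_numeric_block <- function(lines, path) {
  rows <- strsplit(lines, ",", fixed = TRUE)
  ncol_found <- length(rows[[1L]])
  if (any(lengths(rows) != ncol_found))
    stop("ragged rows in ", path)
  m <- matrix(NA_real_, length(rows), ncol_found)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric cell at row ", i,
           ", column ", bad[1L])
    m[i, ] <- v
  }
  m
}

#' Read a FAIMS sample from disk
#'
#' Two dialects are supported: `plain_csv` is a headerless 512-row,
#' 102-column comma-separated numeric block; `lonestar_export` is the same
#' block preceded by `#`-prefixed instrument metadata lines, which are
#' skipped.
#'
#' @param path file path.
#' @param dialect input dialect.
#' @param sample_id sample identifier (defaults to the file name).
#' @param label,age_days,replicate_index metadata attached to the sample.
#' @return A [faims_sample()].
#' @export
read_faims_sample <- function(path, dialect = c("plain_csv", "lonestar_export"),
                              sample_id = NULL, label = "unknown",
                              age_days = NA_real_, replicate_index = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "lonestar_export")
    lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  m <- parse_numeric_block(lines, path)
  if (nrow(m) != FAIMS_CV_STEPS || ncol(m) != FAIMS_COLS)
    stop("FAIMS matrix shape error in ", path, ": expected ",
         FAIMS_CV_STEPS, " x ", FAIMS_COLS, ", found ",
         nrow(m), " x ", ncol(m))
  faims_sample(m, sample_id %||% tools::file_path_sans_ext(basename(path)),
               label = label, age_days = age_days,
               replicate_index = replicate_index)
}

#' Write a FAIMS sample to disk
#'
#' Values are serialized with `%.17g`, so a write/read round trip
#' reproduces the matrix exactly.
#'
#' @param sample a [faims_sample()].
#' @param path output file path.
#' @param dialect `plain_csv` or `lonestar_export` (the latter adds a
#'   `#`-prefixed metadata header).
#' @return The path, invisibly.
#' @export
write_faims_sample <- function(sample, path,
                               dialect = c("plain_csv", "lonestar_export")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(sample, "faims_sample"))
  body <- apply(sample$matrix, 1L, function(r) paste(format_full(r), collapse = ","))
  if (dialect == "lonestar_export") {
    hdr <- c(paste0("# sample_id=", sample$sample_id),
             paste0("# label=", sample$label),
             paste0("# age_days=", sample$age_days),
             "# dispersion field 0-99% (51 steps), CV -6..+6 V (512 steps), +/- ions")
    body <- c(hdr, body)
  }
  writeLines(body, path)
  invisible(path)
}

#' Wavelet features of a single FAIMS sample
#'
#' Applies the periodized 2D multilevel Daubechies-4 transform of
#' [dwt2_decompose()] to the sample's ion-current matrix and flattens the
#' retained subbands into a named feature vector with
#' [dwt2_flatten()] ordering.
#'
#' @param sample a [faims_sample()].
#' @param levels decomposition depth (default 4).
#' @param keep subband retention rule, see [dwt2_flatten()].
#' @return Named numeric vector of wavelet coefficients.
#' @export
dwt2_features <- function(sample, levels = 4L,
                          keep = c("all_levels", "coarsest_only")) {
  stopifnot(inherits(sample, "faims_sample"))
  keep <- match.arg(keep)
  dwt2_flatten(dwt2_decompose(sample$matrix, levels = levels), keep = keep)
}

# Average technical replicates into one matrix per biological sample so
# that replicate copies can never straddle a train/test split.
collapse_faims_replicates <- function(cohort) {
  ids <- vapply(cohort, `[[`, character(1L), "sample_id")
  if (!anyDuplicated(ids)) return(cohort)
  lapply(unique(ids), function(id) {
    grp <- cohort[ids == id]
    m <- Reduce(`+`, lapply(grp, `[[`, "matrix")) / length(grp)
    faims_sample(m, id, label = grp[[1L]]$label,
                 age_days = grp[[1L]]$age_days, replicate_index = 1L)
  })
}

#' Extract a wavelet feature matrix from a FAIMS cohort
#'
#' Technical replicates (duplicated `sample_id`s) are averaged into one
#' matrix per biological sample before extraction. Feature ordering is a
#' pure function of the matrix shape, `levels` and `keep`, and identical
#' across samples.
#'
#' @param cohort list of [faims_sample()] objects with homogeneous shapes.
#' @param levels,keep passed to [dwt2_features()].
#' @return A [feature_matrix()], one row per biological sample.
#' @export
extract_faims_features <- function(cohort, levels = 4L,
                                   keep = c("all_levels", "coarsest_only")) {
  keep <- match.arg(keep)
  if (!length(cohort)) stop("empty cohort")
  stopifnot(all(vapply(cohort, inherits, logical(1L), "faims_sample")))
  cohort <- collapse_faims_replicates(cohort)
  feats <- lapply(cohort, dwt2_features, levels = levels, keep = keep)
  nm <- names(feats[[1L]])
  n_feat <- length(nm)
  if (any(lengths(feats) != n_feat)) stop("mixed shapes in cohort")
  # row-bind without per-vector name bookkeeping (names are a pure
  # function of shape/levels/keep, so the first sample's suffice)
  values <- matrix(unlist(feats, use.names = FALSE),
                   nrow = length(feats), ncol = n_feat, byrow = TRUE)
  feature_matrix(values, feature_names = nm,
                 sample_ids = vapply(cohort, `[[`, character(1L), "sample_id"),
                 labels = vapply(cohort, `[[`, character(1L), "label"))
}
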