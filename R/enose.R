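# Electronic-nose (FOX 4000-style) sample data model, I/O and
# response-feature extraction.
#
# One measurement records 18 metal-oxide sensor resistance traces for
# 180 s at 1 Hz. MOS resistance drops on exposure to volatile compounds;
# the dimensionless sensor response is (R0 - RT) / R0 with R0 the baseline
# resistance and RT the resistance at time T.

ENOSE_N_SENSORS <- 18L
ENOSE_N_POINTS <- 180L

#' Default FOX 4000 sensor-array names
#'
#' The 18 metal-oxide sensors of the three-chamber (LY, T, P) array.
#'
#' @return Character vector of length 18.
#' @export
enose_sensor_names <- function() {
  c("LY2/LG", "LY2/G", "LY2/AA", "LY2/GH", "LY2/gCTL", "LY2/gCT",
    "T30/1", "P10/1", "P10/2", "P40/1", "T70/2", "PA/2",
    "P30/1", "P40/2", "P30/2", "T40/2", "T40/1", "TA/2")
}

#' Construct an electronic-nose sample
#'
#' @param traces numeric 18 x 180 matrix of sensor resistances (rows =
#'   sensors, columns = seconds at 1 Hz).
#' @param sample_id sample identifier.
#' @param sensor_names 18 unique sensor labels.
#' @param baselines per-sensor baseline resistance R0 (> 0); defaults to
#'   the first time point of each trace.
#' @param label class label: `"case"`, `"control"` or `"unknown"`.
#' @param age_days sample storage age in days.
#' @return An object of class `enose_sample`.
#' @export
enose_sample <- function(traces, sample_id, sensor_names = enose_sensor_names(),
                         baselines = NULL, label = "unknown",
                         age_days = NA_real_) {
  if (!is.matrix(traces) || !is.numeric(traces))
    stop("traces must be a numeric matrix")
  if (nrow(traces) != ENOSE_N_SENSORS || ncol(traces) != ENOSE_N_POINTS)
    stop("eNose trace shape error: expected ", ENOSE_N_SENSORS, " x ",
         ENOSE_N_POINTS, ", found ", nrow(traces), " x ", ncol(traces))
  if (!all(is.finite(traces))) stop("traces must be finite")
  sensor_names <- as.character(sensor_names)
  if (length(sensor_names) != ENOSE_N_SENSORS || anyDuplicated(sensor_names))
    stop("sensor_names must be 18 unique labels")
  if (is.null(baselines)) baselines <- traces[, 1L]
  baselines <- as.numeric(baselines)
  if (length(baselines) != ENOSE_N_SENSORS || any(!is.finite(baselines)) ||
      any(baselines <= 0))
    stop("baselines must be 18 strictly positive values")
  stopifnot(length(label) == 1L, label %in% c("case", "control", "unknown"))
  if (!is.na(age_days) && age_days < 0) stop("age_days must be non-negative")
  structure(list(sample_id = as.character(sample_id), traces = unname(traces),
                 sensor_names = sensor_names, baselines = baselines,
                 label = label, age_days = as.numeric(age_days)),
            class = "enose_sample")
}

#' @export
print.enose_sample <- function(x, ...) {
  cat("<enose_sample> ", x$sample_id, ": ", nrow(x$traces), " sensors x ",
      ncol(x$traces), " s, label=", x$label, ", age_days=", x$age_days,
      "\n", sep = "")
  invisible(x)
}

#' Read an electronic-nose sample from disk
#'
#' Expects a CSV with a header row of 18 sensor names and 180 numeric rows
#' (one per second). R0 is taken as the first row unless a baseline
#' sidecar CSV (columns `sensor,R0`) is supplied.
#'
#' @param path per-sample CSV path.
#' @param baseline_path optional sidecar CSV with per-sensor baselines.
#' @param sample_id sample identifier (defaults to the file name).
#' @param label,age_days metadata attached to the sample.
#' @return An [enose_sample()].
#' @export
read_enose_sample <- function(path, baseline_path = NULL, sample_id = NULL,
                              label = "unknown", age_days = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) != ENOSE_N_SENSORS)
    stop("eNose trace shape error in ", path, ": expected ",
         ENOSE_N_SENSORS, " columns, found ", ncol(df))
  if (nrow(df) != ENOSE_N_POINTS)
    stop("eNose trace shape error in ", path, ": expected ",
         ENOSE_N_POINTS, " rows, found ", nrow(df))
  m <- t(as.matrix(df))
  if (!is.numeric(m)) stop("parse error in ", path, ": non-numeric cells")
  baselines <- NULL
  if (!is.null(baseline_path)) {
    b <- utils::read.csv(baseline_path)
    baselines <- b$R0[match(colnames(df), b$sensor)]
  }
  enose_sample(m, sample_id %||% tools::file_path_sans_ext(basename(path)),
               sensor_names = colnames(df), baselines = baselines,
               label = label, age_days = age_days)
}

#' Write an electronic-nose sample to disk
#'
#' @param sample an [enose_sample()].
#' @param path output CSV path (180 rows x 18 named columns).
#' @param baseline_path optional path for a `sensor,R0` sidecar CSV.
#' @return The path, invisibly.
#' @export
write_enose_sample <- function(sample, path, baseline_path = NULL) {
  stopifnot(inherits(sample, "enose_sample"))
  lines <- c(paste(sample$sensor_names, collapse = ","),
             apply(t(sample$traces), 1L,
                   function(r) paste(format_full(r), collapse = ",")))
  writeLines(lines, path)
  if (!is.null(baseline_path)) {
    writeLines(c("sensor,R0",
                 paste(sample$sensor_names, format_full(sample$baselines),
                       sep = ",")),
               baseline_path)
  }
  invisible(path)
}

#' Dimensionless sensor response
#'
#' The fractional resistance drop `(r0 - rt) / r0` of a metal-oxide sensor
#' relative to its baseline. Positive when resistance falls on exposure;
#' invariant under rescaling both arguments by the same positive factor.
#'
#' @param r0 baseline resistance (> 0).
#' @param rt resistance at the time of interest.
#' @return `(r0 - rt) / r0`.
#' @export
sensor_response <- function(r0, rt) {
  if (any(!is.finite(r0)) || any(r0 <= 0))
    stop("baseline resistance r0 must be strictly positive")
  (r0 - rt) / r0
}

#' Maximum resistance over baseline
#'
#' `max(trace) / r0`, the peak of the resistance trace normalized to the
#' baseline resistance.
#'
#' @param trace numeric resistance series (non-empty).
#' @param r0 baseline resistance (> 0).
#' @return Dimensionless ratio.
#' @export
max_over_baseline <- function(trace, r0) {
  if (!length(trace)) stop("trace must be non-empty")
  if (length(r0) != 1L || !is.finite(r0) || r0 <= 0)
    stop("baseline resistance r0 must be strictly positive")
  max(trace) / r0
}

#' Maximum windowed variance of a resistance trace
#'
#' The maximum, over all contiguous segments of length `window`, of the
#' segment's population variance (denominator `window`). With `window`
#' equal to the trace length this degenerates to the plain population
#' variance of the whole trace. Translation-invariant and non-negative.
#'
#' @param trace numeric resistance series.
#' @param window segment length, between 1 and `length(trace)`.
#' @return Maximum segment population variance (resistance squared).
#' @export
max_variance_feature <- function(trace, window = length(trace)) {
  n <- length(trace)
  if (!n) stop("trace must be non-empty")
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window > n)
    stop("window must be between 1 and length(trace)")
  # population variance of each window via cumulative sums
  cs <- c(0, cumsum(trace))
  cs2 <- c(0, cumsum(trace^2))
  i <- seq_len(n - window + 1L)
  s <- cs[i + window] - cs[i]
  s2 <- cs2[i + window] - cs2[i]
  max(pmax(s2 / window - (s / window)^2, 0))
}

enose_family_value <- function(sample, family, window) {
  switch(family,
    response = {
      # peak dimensionless response over the exposure
      resp <- sensor_response(sample$baselines, sample$traces)
      apply(resp, 1L, max)
    },
    max_over_baseline = vapply(seq_len(nrow(sample$traces)), function(s)
      max_over_baseline(sample$traces[s, ], sample$baselines[s]), numeric(1L)),
    max_variance = vapply(seq_len(nrow(sample$traces)), function(s)
      max_variance_feature(sample$traces[s, ], window = window), numeric(1L)),
    stop("unknown feature family: ", family))
}

#' Extract response features from an electronic-nose cohort
#'
#' One feature per sensor per requested family, named
#' `{sensor}_{family}` (with `/` in sensor names replaced by `.`).
#' Families: `response` (peak `(R0 - R(t))/R0`), `max_over_baseline`
#' (`max(trace)/R0`), and `max_variance` (maximum windowed population
#' variance of the raw trace; the default window is the full trace, i.e.
#' plain per-sensor variance).
#'
#' @param cohort list of [enose_sample()] objects.
#' @param feature_set character vector of families to extract.
#' @param window window length for the `max_variance` family (default:
#'   full trace).
#' @return A [feature_matrix()] with `18 * length(feature_set)` columns.
#' @export
extract_enose_features <- function(cohort,
                                   feature_set = c("max_variance", "response",
                                                   "max_over_baseline"),
                                   window = ENOSE_N_POINTS) {
  feature_set <- match.arg(feature_set, several.ok = TRUE)
  if (!length(cohort)) stop("empty cohort")
  stopifnot(all(vapply(cohort, inherits, logical(1L), "enose_sample")))
  sensors <- cohort[[1L]]$sensor_names
  for (s in cohort)
    if (!identical(s$sensor_names, sensors)) stop("mixed sensor arrays in cohort")
  rows <- lapply(cohort, function(s)
    unlist(lapply(feature_set, enose_family_value, sample = s, window = window)))
  nm <- as.vector(vapply(feature_set, function(fam)
    paste0(gsub("/", ".", sensors, fixed = TRUE), "_", fam),
    character(ENOSE_N_SENSORS)))
  feature_matrix(do.call(rbind, rows), feature_names = nm,
                 sample_ids = vapply(cohort, `[[`, character(1L), "sample_id"),
                 labels = vapply(cohort, `[[`, character(1L), "label"))
}
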