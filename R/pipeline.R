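# Study orchestration: cohort generation or ingestion, optional
# sample-age stratification, the instrument-specific feature path,
# leakage-safe selection + classification, and full ROC reporting with a
# reproducibility manifest.

age_cutoff_presets <- c("1y" = 365, "18m" = 548)

#' Study configuration
#'
#' Encodes one full analysis run. The default FAIMS study mirrors the
#' wavelet + fold-wise Wilcoxon top-10 path with all four classifier
#' families, a 70/30 stratified split and 10-fold cross-validation; the
#' default eNose study swaps in max-variance sensor features and the
#' Boruta selector.
#'
#' @param instrument `"faims"` or `"enose"`.
#' @param synthetic a [synthetic_config()] to generate the cohort, or
#'   `NULL` when reading from `input_dir`.
#' @param input_dir directory of an on-disk cohort ([write_cohort()]
#'   layout).
#' @param age_cutoff_days optional age stratification: samples older than
#'   this many days are dropped before analysis. The presets `"1y"` (365)
#'   and `"18m"` (548) are accepted.
#' @param selector selector specification; default depends on the
#'   instrument (Wilcoxon top-10 for FAIMS, Boruta for eNose).
#' @param families classifier families to run.
#' @param test_fraction held-out test fraction (default 0.3).
#' @param n_folds cross-validation folds (default 10).
#' @param seed master seed; every stage derives its randomness from it.
#' @param levels,keep FAIMS wavelet settings (see [dwt2_features()]).
#' @param feature_set eNose feature families (see
#'   [extract_enose_features()]).
#' @param n_boot bootstrap resamples for report CIs.
#' @param out_dir optional output directory for report/score/selection
#'   files.
#' @param test_ids optional explicit test-set sample ids, overriding the
#'   seeded split (useful for audits).
#' @return An object of class `study_config`.
#' @export
study_config <- function(instrument = c("faims", "enose"), synthetic = NULL,
                         input_dir = NULL, age_cutoff_days = NULL,
                         selector = NULL,
                         families = c("sparse_logistic", "random_forest",
                                      "gaussian_process", "svm"),
                         test_fraction = 0.3, n_folds = 10L, seed = 1L,
                         levels = 4L, keep = "all_levels",
                         feature_set = "max_variance", n_boot = 2000L,
                         out_dir = NULL, test_ids = NULL) {
  instrument <- match.arg(instrument)
  if (is.null(synthetic) && is.null(input_dir))
    stop("provide either a synthetic config or an input directory")
  if (is.character(age_cutoff_days))
    age_cutoff_days <- unname(age_cutoff_presets[age_cutoff_days])
  if (!is.null(age_cutoff_days) &&
      (!is.finite(age_cutoff_days) || age_cutoff_days <= 0))
    stop("age cutoff must be a positive number of days")
  if (is.null(selector)) {
    selector <- if (instrument == "faims")
      list(method = "wilcoxon_topk", k = 10L)
    else list(method = "boruta", alpha = 0.05, max_iter = 100L,
              forest_size = 500L)
  }
  families <- match.arg(families, c("sparse_logistic", "random_forest",
                                    "gaussian_process", "svm"),
                        several.ok = TRUE)
  structure(list(instrument = instrument, synthetic = synthetic,
                 input_dir = input_dir, age_cutoff_days = age_cutoff_days,
                 selector = selector, families = families,
                 test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), levels = as.integer(levels),
                 keep = keep, feature_set = feature_set,
                 n_boot = as.integer(n_boot), out_dir = out_dir,
                 test_ids = test_ids),
            class = "study_config")
}

#' Retain samples at most `cutoff_days` old
#'
#' @param cohort list of sample objects with `age_days` metadata.
#' @param cutoff_days maximum storage age in days (`Inf` keeps all).
#' @return The retained sub-cohort.
#' @export
filter_by_age <- function(cohort, cutoff_days) {
  ages <- vapply(cohort, `[[`, numeric(1L), "age_days")
  missing <- vapply(cohort, `[[`, character(1L), "sample_id")[is.na(ages)]
  if (length(missing))
    stop("missing age metadata for samples: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  cohort[ages <= cutoff_days]
}

#' Run a full study
#'
#' Executes generate/ingest, optional age filtering, feature extraction,
#' the stratified 70/30 split, cross-validated training of every
#' requested classifier family (fold-wise selections are computed once
#' and shared across families, since selection does not depend on the
#' classifier), held-out test scoring, and ROC reporting for both the
#' out-of-fold and held-out score sets. When `out_dir` is set, report
#' CSVs, score CSVs, per-fold and final selection CSVs and a JSON run
#' manifest are written; reruns with an identical config produce
#' byte-identical outputs.
#'
#' @param config a [study_config()].
#' @return Invisibly, a list with `report_test`, `report_oof`, `models`,
#'   `scores_test`, `scores_oof`, `selections`, sample bookkeeping and the
#'   manifest.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir, instrument = config$instrument)
  } else if (config$instrument == "faims") {
    generate_faims_cohort(config$synthetic)
  } else {
    generate_enose_cohort(config$synthetic)
  }
  n_total <- length(cohort)
  if (!is.null(config$age_cutoff_days))
    cohort <- filter_by_age(cohort, config$age_cutoff_days)
  n_kept <- length(cohort)
  message("cohort: ", n_total, " samples, ", n_kept, " after age filter")

  fm <- if (config$instrument == "faims") {
    extract_faims_features(cohort, levels = config$levels, keep = config$keep)
  } else {
    extract_enose_features(cohort, feature_set = config$feature_set)
  }

  if (!is.null(config$test_ids)) {
    test_idx <- sort(match(config$test_ids, fm$sample_ids))
    if (anyNA(test_idx)) stop("unknown test_ids")
    train_idx <- setdiff(seq_len(nrow(fm$values)), test_idx)
    sp <- list(train = fm_subset(fm, samples = train_idx),
               test = fm_subset(fm, samples = test_idx),
               train_idx = train_idx, test_idx = test_idx)
  } else {
    sp <- split_train_test(fm, test_fraction = config$test_fraction,
                           seed = derive_seed(config$seed, 11L))
  }
  message("split: ", length(sp$train_idx), " train / ",
          length(sp$test_idx), " test")

  folds <- make_stratified_folds(sp$train$labels, config$n_folds,
                                 seed = derive_seed(config$seed, 23L))
  fold_selections <- lapply(seq_along(folds), function(f)
    run_selector(fm_subset(sp$train, samples = -folds[[f]]), config$selector,
                 seed = derive_seed(config$seed, 100L + f)))
  final_selection <- run_selector(sp$train, config$selector,
                                  seed = derive_seed(config$seed, 99L))

  models <- list(); scores_test <- list(); scores_oof <- list()
  selections <- list(final = NULL, folds = fold_selections)
  for (fam in config$families) {
    spec <- classifier_spec(fam)
    fit <- cv_train(sp$train, spec, selector = config$selector,
                    seed = derive_seed(config$seed, 31L),
                    folds = folds, fold_selections = fold_selections,
                    final_selection = final_selection)
    models[[fam]] <- fit$model
    scores_oof[[fam]] <- fit$oof
    scores_test[[fam]] <- predict_scores(fit$model, sp$test)
    selections$final <- fit$model$selection
    message("trained ", fam, ": ", length(fit$model$feature_idx),
            " features [", paste(utils::head(fit$model$feature_names, 5L),
                                 collapse = ", "),
            if (length(fit$model$feature_idx) > 5L) ", ..." else "", "]")
  }

  report_test <- build_report(scores_test, n_boot = config$n_boot,
                              seed = derive_seed(config$seed, 41L))
  report_oof <- build_report(scores_oof, n_boot = config$n_boot,
                             seed = derive_seed(config$seed, 43L))

  manifest <- list(
    package = "vocdx",
    version = as.character(utils::packageVersion("vocdx")),
    instrument = config$instrument, seed = config$seed,
    selector = config$selector, families = config$families,
    test_fraction = config$test_fraction, n_folds = config$n_folds,
    levels = config$levels, keep = config$keep,
    feature_set = config$feature_set,
    age_cutoff_days = config$age_cutoff_days,
    n_boot = config$n_boot,
    synthetic = if (!is.null(config$synthetic))
      unclass(config$synthetic),
    input_dir = config$input_dir,
    n_samples_total = n_total, n_samples_analysed = n_kept,
    test_ids = sp$test$sample_ids)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_csv(report_test, file.path(config$out_dir, "report_test.csv"))
    write_report_csv(report_oof, file.path(config$out_dir, "report_oof.csv"))
    for (f in seq_along(fold_selections))
      write_selection_csv(fold_selections[[f]]$result,
                          file.path(config$out_dir,
                                    sprintf("selection_fold%02d.csv", f)))
    write_selection_csv(selections$final,
                        file.path(config$out_dir, "selection_final.csv"))
    sc_df <- do.call(rbind, lapply(names(scores_test), function(fam) {
      s <- scores_test[[fam]]
      data.frame(method = fam, sample_id = s$sample_ids,
                 score = s$scores, label = s$labels,
                 provenance = s$provenance)
    }))
    utils::write.csv(sc_df, file.path(config$out_dir, "scores_test.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(report_test = report_test, report_oof = report_oof,
                 models = models, scores_test = scores_test,
                 scores_oof = scores_oof, selections = selections,
                 split = list(train_ids = sp$train$sample_ids,
                              test_ids = sp$test$sample_ids),
                 n_samples_total = n_total, n_samples_analysed = n_kept,
                 manifest = manifest))
}
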