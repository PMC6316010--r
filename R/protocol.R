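# Leakage-safe training protocol: stratified 70/30 split, stratified
# k-fold cross-validation with selection re-fitted inside every fold's
# training portion, hyperparameter choice by mean out-of-fold
# misclassification error, and final refit (selection included) on the
# full training set. Test samples are never visible to any selection or
# fit.

#' Construct a score set
#'
#' Continuous classifier scores (higher = more case-like) aligned with
#' sample ids and true labels.
#'
#' @param sample_ids sample identifiers.
#' @param scores finite numeric scores.
#' @param labels true labels.
#' @param provenance `"out_of_fold"` or `"held_out_test"`.
#' @param threshold the score value separating predicted classes for this
#'   model family (used for error rates).
#' @return An object of class `score_set`.
#' @export
score_set <- function(sample_ids, scores, labels,
                      provenance = c("out_of_fold", "held_out_test"),
                      threshold = 0) {
  provenance <- match.arg(provenance)
  stopifnot(length(sample_ids) == length(scores),
            length(labels) == length(scores), all(is.finite(scores)))
  structure(list(sample_ids = as.character(sample_ids),
                 scores = as.numeric(scores), labels = as.character(labels),
                 provenance = provenance, threshold = threshold),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("<score_set> ", length(x$scores), " scores (", x$provenance, ")\n",
      sep = "")
  invisible(x)
}

#' Stratified train/test split
#'
#' Random split preserving class proportions to within one sample per
#' class; deterministic given the seed.
#'
#' @param features a [feature_matrix()].
#' @param labels optional labels (default: from the feature matrix).
#' @param test_fraction fraction held out, strictly between 0 and 1.
#' @param seed RNG seed.
#' @return List with `train` and `test` feature matrices and the row
#'   indices `train_idx`, `test_idx`.
#' @export
split_train_test <- function(features, labels = NULL, test_fraction = 0.3,
                             seed = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labels <- resolve_labels(features, labels)
  if (min(table(labels)) < 2L)
    stop("each class needs at least 2 samples to split")
  test_idx <- with_seed(seed, {
    unlist(lapply(c("case", "control"), function(cl) {
      idx <- which(labels == cl)
      n_test <- round(length(idx) * test_fraction)
      n_test <- max(1L, min(length(idx) - 1L, n_test))
      sort(sample(idx, n_test))
    }))
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(labels), test_idx)
  list(train = fm_subset(features, samples = train_idx),
       test = fm_subset(features, samples = test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Stratified cross-validation folds
#'
#' Class-wise round-robin assignment after a seeded shuffle; every fold
#' contains both classes or an error is raised.
#'
#' @param labels per-sample class labels.
#' @param n_folds number of folds (>= 2).
#' @param seed RNG seed.
#' @return List of integer vectors of held-out indices, one per fold.
#' @export
make_stratified_folds <- function(labels, n_folds = 10L, seed = NULL) {
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 2L)
  labels <- as.character(labels)
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds <- lapply(seq_len(n_folds), function(f) which(assignment == f))
  for (f in folds) {
    if (length(unique(labels[-f])) < 2L || !length(f))
      stop("a fold lacks both classes; reduce n_folds")
  }
  folds
}

# Apply a selector specification to a training feature matrix, returning
# the fitted selection_result and the chosen feature indices. A Boruta run
# that confirms nothing falls back to tentative features, then to all
# features, so downstream fitting always has input; likewise a fold too
# small to test (a class with < 2 samples) keeps every feature.
run_selector <- function(train_fm, selector, seed = NULL) {
  method <- selector$method %||% "wilcoxon_topk"
  p <- ncol(train_fm$values)
  if (min(table(train_fm$labels)) < 2L) {
    res <- selection_result(method, train_fm$feature_names, NULL,
                            rep("selected", p), seq_len(p))
    return(list(result = res, idx = seq_len(p)))
  }
  if (method == "wilcoxon_topk") {
    res <- wilcoxon_rank(train_fm)
    idx <- select_top_k(res, selector$k %||% 10L)
  } else if (method == "boruta") {
    res <- boruta_select(train_fm,
                         alpha = selector$alpha %||% 0.05,
                         max_iter = selector$max_iter %||% 100L,
                         forest_size = selector$forest_size %||% 500L,
                         seed = selector$seed %||% seed,
                         importance = selector$importance %||% "permutation")
    idx <- which(res$decisions == "confirmed")
    if (!length(idx)) idx <- which(res$decisions == "tentative")
    if (!length(idx)) idx <- seq_along(res$feature_names)
  } else {
    stop("unknown selector method: ", method)
  }
  list(result = res, idx = sort(idx))
}

#' Cross-validated training with in-fold feature selection
#'
#' For each stratified fold, the selector is fitted on the fold's training
#' portion only, each hyperparameter-grid candidate is fitted on the
#' selected features, and the fold's held-out portion is scored. The
#' candidate minimizing mean out-of-fold misclassification error (at the
#' family's score threshold) is chosen; ties go to the earlier grid
#' entry. The final model refits selection and classifier on the full
#' training set with the winning hyperparameters.
#'
#' @param train a [feature_matrix()] of training samples.
#' @param spec a [classifier_spec()].
#' @param selector selector specification:
#'   `list(method = "wilcoxon_topk", k = 10)` (default) or
#'   `list(method = "boruta", alpha =, max_iter =, forest_size =)`.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed controlling folds, in-fold selection and
#'   stochastic fits.
#' @param folds optional precomputed folds (held-out index vectors).
#' @param fold_selections optional precomputed per-fold selections (as
#'   returned by the internal selector runner), allowing several families
#'   to share one set of fold-wise selections.
#' @param final_selection optional precomputed selection on the full
#'   training set, shared across families for the final refit.
#' @return List with the trained model (`model`, of class
#'   `vocdx_trained`), the out-of-fold `score_set` (`oof`), per-candidate
#'   CV error (`grid_errors`), per-fold selections (`fold_selections`) and
#'   the folds.
#' @export
cv_train <- function(train, spec, selector = list(method = "wilcoxon_topk",
                                                  k = 10L),
                     n_folds = 10L, seed = NULL, folds = NULL,
                     fold_selections = NULL, final_selection = NULL) {
  stopifnot(inherits(train, "feature_matrix"),
            inherits(spec, "classifier_spec"))
  labels <- train$labels
  y <- as.integer(labels == "case")
  if (is.null(folds))
    folds <- make_stratified_folds(labels, n_folds, seed = seed)
  if (is.null(fold_selections)) {
    fold_selections <- lapply(seq_along(folds), function(f)
      run_selector(fm_subset(train, samples = -folds[[f]]), selector,
                   seed = derive_seed(seed, f)))
  }
  n_grid <- length(spec$grid)
  errors <- matrix(NA_real_, length(folds), n_grid)
  fold_scores <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    ho <- folds[[f]]
    tr <- setdiff(seq_along(labels), ho)
    sel <- fold_selections[[f]]$idx
    xtr <- train$values[tr, sel, drop = FALSE]
    xho <- train$values[ho, sel, drop = FALSE]
    fold_scores[[f]] <- vector("list", n_grid)
    for (g in seq_len(n_grid)) {
      m <- fit_family(spec, xtr, y[tr], spec$grid[[g]],
                      seed = derive_seed(seed, 1000L + f * n_grid + g))
      sc <- predict_family(m, xho)
      errors[f, g] <- mean((sc > m$threshold) != (y[ho] == 1L))
      fold_scores[[f]][[g]] <- sc
    }
  }
  mean_err <- colMeans(errors)
  best <- which.min(mean_err) # ties -> first candidate
  oof_scores <- numeric(length(labels))
  for (f in seq_along(folds))
    oof_scores[folds[[f]]] <- fold_scores[[f]][[best]]
  final_sel <- final_selection %||%
    run_selector(train, selector, seed = derive_seed(seed, 0L))
  final_fit <- fit_family(spec, train$values[, final_sel$idx, drop = FALSE],
                          y, spec$grid[[best]],
                          seed = derive_seed(seed, 999983L))
  model <- structure(
    list(family = spec$family, spec = spec, fit = final_fit,
         hyper = spec$grid[[best]],
         feature_idx = final_sel$idx,
         feature_names = train$feature_names[final_sel$idx],
         selection = final_sel$result,
         n_folds = length(folds), seed = seed),
    class = "vocdx_trained")
  oof <- score_set(train$sample_ids, oof_scores, labels,
                   provenance = "out_of_fold", threshold = final_fit$threshold)
  list(model = model, oof = oof, grid_errors = mean_err,
       fold_selections = fold_selections, folds = folds)
}

#' @export
print.vocdx_trained <- function(x, ...) {
  cat("<vocdx_trained> ", x$family, " on ", length(x$feature_idx),
      " selected features\n", sep = "")
  invisible(x)
}

#' Score new samples with a trained model
#'
#' Predicts only on the feature subset stored at training time, resolved
#' by feature name; unknown or missing feature names are an error.
#'
#' @param model a `vocdx_trained` object from [cv_train()].
#' @param features a [feature_matrix()] containing at least the model's
#'   features.
#' @return A `score_set` with provenance `"held_out_test"`.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "vocdx_trained"),
            inherits(features, "feature_matrix"))
  miss <- setdiff(model$feature_names, features$feature_names)
  if (length(miss))
    stop("features missing from input: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  x <- features$values[, model$feature_names, drop = FALSE]
  score_set(features$sample_ids, predict_family(model$fit, x),
            features$labels, provenance = "held_out_test",
            threshold = model$fit$threshold)
}
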