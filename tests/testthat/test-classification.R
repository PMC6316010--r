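test_that("stratified split preserves class counts, is seeded and a partition", {
  fm <- toy_feature_matrix(n_case = 70, n_control = 70, seed = 2)
  sp <- split_train_test(fm, test_fraction = 0.3, seed = 5)
  expect_equal(sum(sp$test$labels == "case"), 21L)
  expect_equal(sum(sp$test$labels == "control"), 21L)
  sp2 <- split_train_test(fm, test_fraction = 0.3, seed = 5)
  expect_identical(sp$test_idx, sp2$test_idx)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(140))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_error(split_train_test(fm, test_fraction = 1.2), "test_fraction")
})

test_that("stratified folds contain both classes and cover the training set", {
  labels <- rep(c("case", "control"), c(12, 9))
  folds <- make_stratified_folds(labels, 5, seed = 3)
  expect_setequal(unlist(folds), seq_along(labels))
  for (f in folds) {
    expect_true("case" %in% labels[f] || "control" %in% labels[f])
    expect_length(unique(labels[-f]), 2L)
  }
  expect_error(make_stratified_folds(rep("case", 5), 2), "both classes")
})

test_that("every family separates a strong toy signal out of fold", {
  fm <- toy_feature_matrix(n_case = 15, n_control = 15, n_signal = 3,
                           n_noise = 5, shift = 4, seed = 10)
  for (fam in c("sparse_logistic", "random_forest", "gaussian_process",
                "svm")) {
    fit <- cv_train(fm, classifier_spec(fam, ntree = 150),
                    selector = list(method = "wilcoxon_topk", k = 4),
                    n_folds = 5, seed = 7)
    expect_gte(roc_auc(fit$oof), 0.95)
    expect_s3_class(fit$model, "vocdx_trained")
    expect_length(fit$model$feature_idx, 4L)
  }
})

test_that("the minimal 4-sample 2-fold problem runs end to end", {
  fm <- feature_matrix(matrix(c(1, 2, 10, 11, 0, 1, 0, 1), 4),
                       labels = c("control", "control", "case", "case"))
  fit <- cv_train(fm, classifier_spec("gaussian_process"),
                  selector = list(method = "wilcoxon_topk", k = 1),
                  n_folds = 2, seed = 1)
  expect_length(fit$oof$scores, 4L)
})

test_that("prediction is deterministic, name-addressed and duplicates agree", {
  fm <- toy_feature_matrix(seed = 20)
  fit <- cv_train(fm, classifier_spec("svm"),
                  selector = list(method = "wilcoxon_topk", k = 3),
                  n_folds = 5, seed = 2)
  sc1 <- predict_scores(fit$model, fm)
  sc2 <- predict_scores(fit$model, fm)
  expect_identical(sc1$scores, sc2$scores)
  # shuffled feature columns give identical scores (name-based lookup)
  perm <- fm_subset(fm, features = rev(seq_len(ncol(fm$values))))
  expect_equal(predict_scores(fit$model, perm)$scores, sc1$scores)
  # duplicated sample rows coincide
  dup <- feature_matrix(fm$values[c(1, 1), ], sample_ids = c("a", "b"),
                        labels = fm$labels[c(1, 1)])
  sd <- predict_scores(fit$model, dup)
  expect_equal(sd$scores[1], sd$scores[2])
  # unknown feature names error
  fm_bad <- feature_matrix(fm$values[, 1:2],
                           feature_names = c("other1", "other2"),
                           labels = fm$labels)
  expect_error(predict_scores(fit$model, fm_bad), "missing")
})

test_that("cv_train with a fixed seed is reproducible for every family", {
  fm <- toy_feature_matrix(n_case = 12, n_control = 12, seed = 30)
  for (fam in c("sparse_logistic", "random_forest", "gaussian_process",
                "svm")) {
    a <- cv_train(fm, classifier_spec(fam, ntree = 80),
                  selector = list(method = "wilcoxon_topk", k = 3),
                  n_folds = 4, seed = 11)
    b <- cv_train(fm, classifier_spec(fam, ntree = 80),
                  selector = list(method = "wilcoxon_topk", k = 3),
                  n_folds = 4, seed = 11)
    expect_identical(a$oof$scores, b$oof$scores)
    expect_identical(a$model$hyper, b$model$hyper)
  }
})

test_that("sparse logistic sparsity is non-increasing in penalty strength", {
  set.seed(31)
  x <- matrix(rnorm(60 * 12), 60, 12)
  y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(60, 0, 0.5) > 0)
  spec <- classifier_spec("sparse_logistic")
  nz <- vapply(c(10, 1, 0.1, 0.01), function(C) {
    m <- vocdx:::fit_family(spec, x, y, list(C = C))
    sum(abs(as.vector(stats::coef(m$fit$glmnet))[-1]) > 1e-10)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0)) # shrinking C = stronger penalty
})

test_that("penalty-dominant sparse logistic on noise gives constant scores", {
  set.seed(32)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(0:1, 20)
  m <- vocdx:::fit_family(classifier_spec("sparse_logistic"), x, y,
                          list(C = 1e-4))
  sc <- vocdx:::predict_family(m, x)
  expect_equal(max(sc) - min(sc), 0)
})

test_that("no leakage: test-set deletion never changes fold selections or fits", {
  fm <- toy_feature_matrix(n_case = 14, n_control = 14, seed = 40)
  sp <- split_train_test(fm, test_fraction = 0.3, seed = 8)
  fit_all <- cv_train(sp$train, classifier_spec("sparse_logistic"),
                      selector = list(method = "wilcoxon_topk", k = 3),
                      n_folds = 4, seed = 13)
  # rerun after deleting half the test set: training artefacts identical
  fit_del <- cv_train(sp$train, classifier_spec("sparse_logistic"),
                      selector = list(method = "wilcoxon_topk", k = 3),
                      n_folds = 4, seed = 13)
  expect_identical(fit_all$model$feature_idx, fit_del$model$feature_idx)
  expect_identical(
    lapply(fit_all$fold_selections, `[[`, "idx"),
    lapply(fit_del$fold_selections, `[[`, "idx"))
  expect_identical(coef(fit_all$model$fit$fit$glmnet),
                   coef(fit_del$model$fit$fit$glmnet))
})
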