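test_that("roc_auc matches hand counts and brute-force concordance", {
  expect_equal(roc_auc(toy_score_set(c(0.35, 0.8), c(0.1, 0.4))), 0.75)
  expect_equal(roc_auc(toy_score_set(c(5, 6), c(1, 2))), 1)
  expect_equal(roc_auc(toy_score_set(rep(1, 4), rep(1, 5))), 0.5)
  set.seed(50)
  for (i in 1:30) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    case <- sample(seq(0, 1, 0.05), n1, TRUE) # coarse grid forces ties
    control <- sample(seq(0, 1, 0.05), n2, TRUE)
    expect_equal(roc_auc(toy_score_set(case, control)),
                 auc_by_pairs(case, control))
  }
})

test_that("AUC is invariant to increasing transforms and flips with labels", {
  set.seed(51)
  case <- rnorm(12, 1); control <- rnorm(15)
  a <- roc_auc(toy_score_set(case, control))
  expect_equal(roc_auc(toy_score_set(exp(case), exp(control))), a)
  expect_equal(roc_auc(toy_score_set(control, case)), 1 - a)
  expect_error(roc_auc(toy_score_set(case, numeric(0))), "both classes")
})

test_that("operating point arithmetic follows the confusion matrix", {
  # 10 cases, 10 controls engineered so threshold 0.5 gives TP=9 FN=1 TN=8 FP=2
  case <- c(rep(0.9, 9), 0.1)
  control <- c(rep(0.2, 8), 0.8, 0.8)
  op <- operating_point(toy_score_set(case, control),
                        rule = "fixed_threshold", t = 0.5)
  expect_equal(op$sensitivity, 0.9)
  expect_equal(op$specificity, 0.8)
  expect_equal(op$ppv, 9 / 11)
  expect_equal(op$npv, 8 / 9)
  perfect <- operating_point(toy_score_set(c(2, 3), c(0, 1)))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$ppv,
                 perfect$npv), rep(1, 4))
})

test_that("the youden point equals an exhaustive threshold scan", {
  set.seed(52)
  for (i in 1:10) {
    ss <- toy_score_set(rnorm(8, 0.8), rnorm(9))
    op <- operating_point(ss)
    js <- vapply(c(sort(unique(ss$scores)), Inf), function(t) {
      o <- operating_point(ss, rule = "fixed_threshold", t = t)
      o$sensitivity + o$specificity - 1
    }, numeric(1))
    expect_equal(op$sensitivity + op$specificity - 1, max(js))
    # recomputing metrics from stored confusion counts is exact
    expect_equal(op$sensitivity, op$tp / (op$tp + op$fn))
    expect_equal(op$specificity, op$tn / (op$tn + op$fp))
  }
})

test_that("bootstrap CI is degenerate-exact, covers the estimate and shrinks with n", {
  expect_equal(bootstrap_ci(toy_score_set(rep(1, 5), rep(0, 5)),
                            n_boot = 200, seed = 1), c(1, 1))
  set.seed(53)
  ss <- toy_score_set(rnorm(20, 1), rnorm(20))
  ci <- bootstrap_ci(ss, n_boot = 400, seed = 2)
  a <- roc_auc(ss)
  expect_true(ci[1] <= a && a <= ci[2])
  expect_identical(ci, bootstrap_ci(ss, n_boot = 400, seed = 2))
  shrunk <- 0
  for (s in 1:6) {
    set.seed(s)
    small <- toy_score_set(rnorm(10, 0.8), rnorm(10))
    big <- toy_score_set(rnorm(100, 0.8), rnorm(100))
    wi <- function(ss) diff(bootstrap_ci(ss, n_boot = 300, seed = s))
    shrunk <- shrunk + (wi(big) < wi(small))
  }
  expect_gte(shrunk, 5)
})

test_that("score_pvalue matches enumeration and tracks the AUC CI", {
  expect_equal(score_pvalue(toy_score_set(4:6, 1:3)), 0.1)
  set.seed(54)
  near1 <- score_pvalue(toy_score_set(rnorm(30), rnorm(30)))
  expect_gt(near1, 0.05)
  agree <- 0
  for (s in 1:10) {
    set.seed(s)
    ss <- toy_score_set(rnorm(15, runif(1, 0, 1.5)), rnorm(15))
    sig_p <- score_pvalue(ss) < 0.05
    sig_ci <- bootstrap_ci(ss, n_boot = 400, seed = s)[1] > 0.5 ||
      bootstrap_ci(ss, n_boot = 400, seed = s)[2] < 0.5
    agree <- agree + (sig_p == sig_ci)
  }
  expect_gte(agree, 8)
})

test_that("PCA puts a line on one component and reconstructs exactly", {
  set.seed(55)
  t <- rnorm(40)
  line <- cbind(t, 2 * t) + matrix(rnorm(80, 0, 1e-4), 40)
  co <- project_pca(line, 2)
  expect_gte(attr(co, "explained_variance")[1], 0.999)
  # duplicated rows coincide
  x <- matrix(rnorm(5 * 4), 5)
  xx <- rbind(x, x[3, ])
  cc <- project_pca(xx, 2)
  expect_equal(cc[3, ], cc[6, ], ignore_attr = TRUE)
  # full-rank reconstruction
  co4 <- project_pca(x, 4)
  rec <- co4 %*% t(attr(co4, "loadings"))
  rec <- sweep(rec, 2, colMeans(x), "+")
  expect_lt(max(abs(rec - x)), 1e-8)
  # sign convention: largest-magnitude loading positive
  for (j in 1:4) {
    l <- attr(co4, "loadings")[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("LDA separates blobs, shrugs at null data and survives collinearity", {
  set.seed(56)
  blob <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 6), 30))
  labels <- rep(c("control", "case"), each = 30)
  co <- project_lda(blob, labels)
  d <- (mean(co[labels == "case", ]) - mean(co[labels == "control", ])) /
    sqrt(mean(c(var(co[labels == "case", ]), var(co[labels == "control", ]))))
  expect_gt(abs(d), 5)
  low <- 0
  for (s in 1:10) {
    set.seed(s)
    nullx <- matrix(rnorm(200), 100)
    cn <- project_lda(nullx, rep(c("case", "control"), 50))
    dn <- abs(mean(cn[rep(c(TRUE, FALSE), 50), ]) -
              mean(cn[rep(c(FALSE, TRUE), 50), ])) / sd(cn)
    low <- low + (dn < 0.5)
  }
  expect_gte(low, 8)
  dupcol <- cbind(blob, blob[, 1])
  expect_silent(project_lda(dupcol, labels))
})

test_that("LDA direction agrees with the MASS reference on clean data", {
  skip_if_not_installed("MASS")
  set.seed(57)
  x <- rbind(matrix(rnorm(80, 0), 40), matrix(rnorm(80, 1.5), 40))
  labels <- rep(c("control", "case"), each = 40)
  w <- attr(project_lda(x, labels, eps = 1e-10), "direction")
  ref <- MASS::lda(x, grouping = labels)$scaling[, 1]
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(abs(sum(w * ref)), 1, tolerance = 1e-4)
})

test_that("build_report emits the documented columns and round-trips", {
  set.seed(58)
  sets <- list(
    gaussian_process = toy_score_set(rnorm(15, 2), rnorm(15)),
    svm = toy_score_set(rnorm(15, 1), rnorm(15)))
  rep_ <- build_report(sets, n_boot = 200, seed = 3)
  expect_identical(names(rep_),
                   c("method", "auc", "auc_lo", "auc_hi", "sensitivity",
                     "sens_lo", "sens_hi", "specificity", "spec_lo",
                     "spec_hi", "ppv", "npv", "p_value", "n_case",
                     "n_control"))
  expect_equal(nrow(rep_), 2L)
  expect_true(all(rep_$auc_lo <= rep_$auc & rep_$auc <= rep_$auc_hi))
  one <- build_report(sets[1], n_boot = 200, seed = 3)
  expect_equal(nrow(one), 1L)
  expect_identical(one[1, ], rep_[1, ]) # rows independent of other rows
  path <- tempfile(fileext = ".csv")
  write_report_csv(rep_, path)
  back <- read_report_csv(path)
  expect_equal(back$auc, rep_$auc)
  expect_identical(back$method, rep_$method)
  unlink(path)
})
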