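test_that("wilcoxon_rank reproduces the exact enumeration p-value", {
  fm <- feature_matrix(matrix(c(1, 2, 3, 4, 5, 6), ncol = 1),
                       labels = c(rep("case", 3), rep("control", 3)))
  res <- wilcoxon_rank(fm)
  expect_equal(res$p_values, 0.1) # 4 of 20 assignments as extreme
  expect_equal(res$p_values, pvalue_by_enumeration(1:3, 4:6))
})

test_that("a constant feature gets p = 1 and single-class input errors", {
  fm <- feature_matrix(cbind(v1 = rep(2, 8), v2 = rnorm(8)),
                       labels = rep(c("case", "control"), each = 4))
  expect_equal(wilcoxon_rank(fm)$p_values[1], 1)
  bad <- feature_matrix(matrix(rnorm(4), ncol = 1), labels = rep("case", 4))
  expect_error(wilcoxon_rank(bad), "both classes")
})

test_that("approximate p-values track full permutation enumeration", {
  set.seed(11)
  worst <- 0
  for (i in 1:25) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    vals <- if (i %% 3 == 0) sample(1:4, n1 + n2, TRUE) else rnorm(n1 + n2)
    case <- vals[seq_len(n1)]; control <- vals[-seq_len(n1)]
    fm <- feature_matrix(matrix(vals, ncol = 1),
                         labels = c(rep("case", n1), rep("control", n2)))
    worst <- max(worst, abs(wilcoxon_rank(fm)$p_values -
                            pvalue_by_enumeration(case, control)))
  }
  expect_lt(worst, 0.02)
})

test_that("p-values are invariant under strictly monotone transforms", {
  set.seed(12)
  x <- matrix(rnorm(30 * 5), 30)
  labels <- rep(c("case", "control"), each = 15)
  p0 <- wilcoxon_rank(feature_matrix(x, labels = labels))$p_values
  for (f in list(function(v) exp(v), function(v) v^3,
                 function(v) rank(v, ties.method = "first"))) {
    xt <- apply(x, 2, f)
    expect_equal(wilcoxon_rank(feature_matrix(xt, labels = labels))$p_values,
                 p0)
  }
})

test_that("select_top_k keeps the k smallest p-values with stable ties", {
  fm <- toy_feature_matrix(n_signal = 3, n_noise = 7, seed = 4)
  res <- wilcoxon_rank(fm)
  top <- select_top_k(res, 10)
  expect_equal(sort(res$p_values[top]), sort(res$p_values)[1:10])
  expect_equal(select_top_k(res, 50), res$ranking) # k > p: everything
  # exact ties broken by ascending index, reproducibly
  tie <- vocdx:::selection_result("wilcoxon_topk", paste0("f", 1:4),
                          c(0.5, 0.2, 0.5, 0.2),
                          rep("selected", 4), order(c(0.5, 0.2, 0.5, 0.2), 1:4))
  expect_equal(select_top_k(tie, 3), c(2L, 4L, 1L))
  expect_identical(select_top_k(tie, 3), select_top_k(tie, 3))
})

test_that("selection results serialize to the documented CSV shape", {
  fm <- toy_feature_matrix(seed = 6)
  res <- wilcoxon_rank(fm)
  path <- tempfile(fileext = ".csv")
  write_selection_csv(res, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("feature_name", "p_value", "decision", "rank"))
  expect_equal(nrow(df), length(res$feature_names))
  expect_equal(df$rank[res$ranking[1]], 1L)
  unlink(path)
})

test_that("selection ranking is a permutation covering all features", {
  fm <- toy_feature_matrix(seed = 8)
  res <- wilcoxon_rank(fm)
  expect_setequal(res$ranking, seq_along(res$feature_names))
  expect_true(all(res$p_values >= 0 & res$p_values <= 1))
})
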