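make_enose <- function(seed = 1, label = "case") {
  set.seed(seed)
  base <- runif(18, 80, 250)
  traces <- base - outer(runif(18, 0, 30), 1 - exp(-(0:179) / 20)) +
    matrix(rnorm(18 * 180, 0, 0.5), 18, 180)
  enose_sample(traces, sprintf("E%02d", seed), baselines = base, label = label)
}

test_that("enose sample validation enforces the 18 x 180 contract", {
  expect_error(enose_sample(matrix(1, 17, 180), "x"), "expected 18 x 180")
  expect_error(enose_sample(matrix(1, 18, 179), "x"), "18 x 180")
  expect_error(enose_sample(matrix(1, 18, 180), "x", baselines = rep(0, 18)),
               "strictly positive")
  expect_error(enose_sample(matrix(1, 18, 180), "x",
                            sensor_names = rep("a", 18)), "unique")
})

test_that("write/read round-trips traces and baselines", {
  s <- make_enose(2)
  path <- tempfile(fileext = ".csv")
  bpath <- tempfile(fileext = ".csv")
  write_enose_sample(s, path, baseline_path = bpath)
  r <- read_enose_sample(path, baseline_path = bpath, sample_id = s$sample_id)
  expect_identical(r$traces, s$traces)
  expect_identical(r$baselines, s$baselines)
  expect_identical(r$sensor_names, s$sensor_names)
  # 17-column file is rejected
  df <- utils::read.csv(path, check.names = FALSE)
  utils::write.csv(df[, -1], path, row.names = FALSE)
  expect_error(read_enose_sample(path), "expected 18 columns, found 17")
  unlink(c(path, bpath))
})

test_that("sensor_response follows (R0 - RT)/R0 and is scale-invariant", {
  expect_equal(sensor_response(100, 100), 0)
  expect_equal(sensor_response(100, 60), 0.4)
  expect_equal(sensor_response(50, 75), -0.5)
  expect_error(sensor_response(0, 10), "positive")
  set.seed(3)
  for (i in 1:20) {
    r0 <- runif(1, 1, 100); rt <- runif(1, 1, 100); k <- runif(1, 0.1, 50)
    expect_equal(sensor_response(k * r0, k * rt), sensor_response(r0, rt))
  }
})

test_that("max_over_baseline agrees with an exhaustive scan", {
  expect_equal(max_over_baseline(rep(100, 180), 100), 1)
  expect_equal(max_over_baseline(c(rep(90, 179), 120), 100), 1.2)
  set.seed(4)
  for (i in 1:10) {
    tr <- runif(180, 10, 200); r0 <- runif(1, 10, 100)
    best <- -Inf
    for (v in tr) best <- max(best, v / r0)
    expect_equal(max_over_baseline(tr, r0), best)
  }
})

test_that("max_variance_feature matches the brute-force sliding window", {
  expect_equal(max_variance_feature(rep(5, 30), 10), 0)
  tr <- rnorm(180)
  expect_equal(max_variance_feature(tr, 180),
               mean((tr - mean(tr))^2))
  set.seed(5)
  for (i in 1:5) {
    tr <- rnorm(180)
    brute <- max(vapply(1:151, function(s) {
      w <- tr[s:(s + 29)]
      mean((w - mean(w))^2)
    }, numeric(1)))
    expect_equal(max_variance_feature(tr, 30), brute, tolerance = 1e-12)
    # translation invariance and non-negativity
    expect_equal(max_variance_feature(tr + 1e3, 30),
                 max_variance_feature(tr, 30), tolerance = 1e-6)
    expect_gte(max_variance_feature(tr, 30), 0)
  }
  expect_error(max_variance_feature(tr, 0), "window")
  expect_error(max_variance_feature(tr, 181), "window")
})

test_that("feature extraction names and aligns sensor features", {
  s1 <- make_enose(1); s2 <- make_enose(2, label = "control")
  fm <- extract_enose_features(list(s1, s2), feature_set = "max_variance")
  expect_equal(dim(fm$values), c(2L, 18L))
  expect_true(all(grepl("_max_variance$", fm$feature_names)))
  expect_false(any(grepl("/", fm$feature_names)))
  fm3 <- extract_enose_features(list(s1), feature_set = c("response",
                                                          "max_over_baseline"))
  expect_equal(ncol(fm3$values), 36L)
  # identical samples give identical rows
  dup <- enose_sample(s1$traces, "dup", baselines = s1$baselines,
                      label = "case")
  fmd <- extract_enose_features(list(s1, dup))
  expect_equal(unname(fmd$values[1, ]), unname(fmd$values[2, ]))
})

test_that("flat traces at baseline give zero response features", {
  cfg <- synthetic_config(n_case = 1, n_control = 1, seed = 3, noise_sd = 0,
                          enose_amplitude = 0)
  co <- generate_enose_cohort(cfg)
  for (s in co) {
    expect_true(all(s$traces == s$traces[, 1]))
    expect_equal(max(abs(sensor_response(s$baselines, s$traces))), 0)
    expect_equal(max(vapply(seq_len(18), function(i)
      max_variance_feature(s$traces[i, ]), numeric(1))), 0)
  }
})
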