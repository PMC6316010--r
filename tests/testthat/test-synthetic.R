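test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_case = -1), "non-negative")
  expect_error(synthetic_config(effect_size = 0), "effect_size")
  expect_error(synthetic_config(noise_sd = -0.1), "noise_sd")
  expect_error(synthetic_config(age_decay_rate = -1), "age_decay_rate")
})

test_that("cohorts are deterministic given config + seed and balanced", {
  cfg <- synthetic_config(n_case = 3, n_control = 2, seed = 42)
  a <- generate_faims_cohort(cfg)
  b <- generate_faims_cohort(cfg)
  expect_identical(lapply(a, `[[`, "matrix"), lapply(b, `[[`, "matrix"))
  expect_identical(vapply(a, `[[`, character(1), "label"),
                   c("case", "case", "case", "control", "control"))
  e1 <- generate_enose_cohort(cfg)
  e2 <- generate_enose_cohort(cfg)
  expect_identical(lapply(e1, `[[`, "traces"), lapply(e2, `[[`, "traces"))
  expect_equal(length(e1), 5L)
})

test_that("a FAIMS sample holds exactly 52,224 values in a 512 x 102 grid", {
  co <- generate_faims_cohort(synthetic_config(n_case = 1, n_control = 0,
                                               seed = 99))
  expect_equal(length(co), 1L)
  expect_equal(dim(co[[1]]$matrix), c(512L, 102L))
  expect_equal(length(co[[1]]$matrix), 52224L)
})

test_that("an eNose sample holds exactly 18 traces of 180 points", {
  co <- generate_enose_cohort(synthetic_config(n_case = 0, n_control = 1,
                                               seed = 7))
  expect_equal(dim(co[[1]]$traces), c(18L, 180L))
})

test_that("zero effect with matched draws gives byte-identical matrices", {
  base <- list(effect_size = 1, age_decay_rate = 0, noise_sd = 0, seed = 5)
  case_cfg <- do.call(synthetic_config,
                      c(base, list(n_case = 1, n_control = 0)))
  ctrl_cfg <- do.call(synthetic_config,
                      c(base, list(n_case = 0, n_control = 1)))
  expect_identical(generate_faims_cohort(case_cfg)[[1]]$matrix,
                   generate_faims_cohort(ctrl_cfg)[[1]]$matrix)
  expect_identical(generate_enose_cohort(case_cfg)[[1]]$traces,
                   generate_enose_cohort(ctrl_cfg)[[1]]$traces)
})

test_that("planted marker amplitude decays strictly with sample age", {
  ages <- c(0, 100, 400, 900, 1460)
  cfg <- synthetic_config(n_case = 5, n_control = 0, seed = 1,
                          age_decay_rate = 0.002, noise_sd = 0,
                          age_distribution = ages)
  co <- generate_faims_cohort(cfg)
  amp <- vapply(co, attr, numeric(1), "marker_amplitude")
  expect_true(all(diff(amp) < 0))
  # and the matrices themselves carry the decay at a marker locus
  loc <- vocdx:::faims_marker_loci(cfg$n_marker_peaks)
  peak <- vapply(co, function(s) s$matrix[loc[1, "cv"], loc[1, "df"]],
                 numeric(1))
  expect_true(all(diff(peak) < 0))
  en <- generate_enose_cohort(cfg)
  eamp <- t(vapply(en, attr, numeric(3), "marker_amplitude"))
  expect_true(all(apply(eamp, 2, function(a) all(diff(a) < 0))))
})

test_that("explicit age vectors are honoured and lambda = 0 leaves amplitude flat", {
  cfg <- synthetic_config(n_case = 3, n_control = 0, seed = 2,
                          age_decay_rate = 0, noise_sd = 0,
                          age_distribution = c(10, 20, 30))
  co <- generate_faims_cohort(cfg)
  expect_equal(vapply(co, `[[`, numeric(1), "age_days"), c(10, 20, 30))
  amp <- vapply(co, attr, numeric(1), "marker_amplitude")
  expect_equal(length(unique(amp)), 1L)
})

test_that("cohorts round-trip through the on-disk layout", {
  cfg <- synthetic_config(n_case = 2, n_control = 1, seed = 8,
                          age_distribution = c(5, 15, 25))
  dir_f <- tempfile(); dir_e <- tempfile()
  fa <- generate_faims_cohort(cfg)
  write_cohort(fa, dir_f)
  rf <- read_cohort(dir_f, "faims")
  expect_identical(lapply(rf, `[[`, "matrix"), lapply(fa, `[[`, "matrix"))
  expect_identical(vapply(rf, `[[`, character(1), "label"),
                   vapply(fa, `[[`, character(1), "label"))
  en <- generate_enose_cohort(cfg)
  write_cohort(en, dir_e)
  re <- read_cohort(dir_e, "enose")
  expect_identical(lapply(re, `[[`, "traces"), lapply(en, `[[`, "traces"))
  unlink(c(dir_f, dir_e), recursive = TRUE)
})
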