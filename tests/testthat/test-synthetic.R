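test_that("presets carry the published marginal parameters and validate", {
  p1 <- preset_config(1)
  expect_equal(p1$biometry_means, c(24.0922, 3.1848, 4.6215, 7.7641))
  expect_equal(p1$biometry_sds, c(1.4034, 0.4072, 0.4499, 0.2681))
  expect_equal(p1$n, 886L)
  expect_equal(preset_config(2)$n, 613L)
  expect_equal(preset_config(3)$n, 821L)
  expect_equal(preset_config(4)$n, 467L)
  for (d in 1:4) expect_s3_class(preset_config(d), "iol_synth_config")
  expect_error(preset_config(5), "unknown dataset")

  bad_corr <- matrix(c(1, 0.99, 0.99, 0.99, 1, -0.99, 0.99, -0.99, 1), 3)
  expect_error(synthetic_config(100, correlation = bad_corr),
               "positive-definite")
})

test_that("generation is deterministic under the seed and leaves the global RNG alone", {
  cfg <- preset_config(1, n = 150, seed = 99)
  set.seed(123)
  before <- .Random.seed
  g1 <- suppressMessages(generate_cohort(cfg))
  expect_identical(.Random.seed, before)  # RNG state restored
  g2 <- suppressMessages(generate_cohort(cfg))
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth$fc_true, g2$truth$fc_true)
  g3 <- suppressMessages(generate_cohort(preset_config(1, n = 150, seed = 100)))
  expect_false(identical(g1$cohort, g3$cohort))
})

test_that("generated cohorts respect the construction constraints", {
  gen <- make_cohort("HAIGIS", n = 300, seed = 5, ro_true = 0.4)
  co <- gen$cohort
  expect_equal(nrow(co), 300)
  # labelled powers on the half-diopter grid
  expect_true(all(abs(co$iolp / 0.5 - round(co$iolp / 0.5)) < 1e-9))
  # records inside the plausibility limits (cohort() re-validated them)
  expect_s3_class(co, "iol_cohort")
  # flat radius not steeper than steep radius
  expect_true(all(co$r1 >= co$r2 - 1e-12))
  # truth record matches the generating configuration
  expect_equal(gen$truth$ro_true, 0.4)
  expect_equal(gen$truth$formula, "HAIGIS")

  # zero-noise, zero-offset cohort: the suite reproduces the truth exactly
  gen0 <- make_cohort("SRKT", n = 100, seed = 8, noise_sd = 0)
  res <- optimize_fc("SRKT", gen0$cohort, "min_rmspe")
  expect_equal(res$constants$fc, gen0$truth$fc_true, tolerance = 1e-4)
  expect_lt(res$stats$rmspe, 1e-7)
})

test_that("dataset-1 marginals reproduce the published means within sampling error", {
  cfg <- preset_config(1, n = 2000, seed = 7)
  gen <- suppressMessages(generate_cohort(cfg))
  co <- gen$cohort
  means <- c(24.0922, 3.1848, 4.6215, 7.7641)
  sds <- c(1.4034, 0.4072, 0.4499, 0.2681)
  obs <- c(mean(co$al), mean(co$acd), mean(co$lt),
           mean(mean_corneal_radius(co$r1, co$r2)))
  se <- sds / sqrt(2000)
  # truncation shrinks tails slightly; 3 standard errors is the agreed band
  expect_true(all(abs(obs - means) < 3 * se),
              info = paste(round(obs - means, 4), collapse = ", "))
})

test_that("refraction noise propagates to the prediction-error SD at the truth", {
  gen <- make_cohort("HOLLADAY1", n = 800, seed = 21, noise_sd = 0.42)
  k <- formula_constants("HOLLADAY1", fc = gen$truth$fc_true)
  s <- summarize_pe(prediction_errors(k, gen$cohort))
  # SDPE concentrates near sigma (3 * sigma / sqrt(2n) band)
  expect_lt(abs(s$sdpe - 0.42), 3 * 0.42 / sqrt(2 * 800))
  expect_lt(abs(s$mpe), 3 * 0.42 / sqrt(800))
})
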