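test_that("noise-free cohorts return the generating constant under all objectives", {
  for (fm in c("SRKT", "HAIGIS")) {
    gen <- make_cohort(fm, n = 120, seed = 4, noise_sd = 0)
    for (objective in c("zero_mpe", "min_sdpe", "min_rmspe")) {
      res <- optimize_fc(fm, gen$cohort, objective)
      expect_equal(res$constants$fc, gen$truth$fc_true, tolerance = 1e-4,
                   label = paste(fm, objective))
      expect_lt(res$stats$rmspe, 1e-6)
      expect_true(res$converged)
    }
  }
})

test_that("single-constant optimizers match the exhaustive grid oracle", {
  # one formula here at full 1e-4 refinement; all four run in the
  # acceptance suite
  gen <- make_cohort("HOFFERQ", n = 100, seed = 42)
  co <- gen$cohort
  for (objective in c("min_sdpe", "min_rmspe")) {
    metric <- sub("min_", "", objective)
    g <- oracle_grid_min(pe_objective("HOFFERQ", co, metric), c(2, 9))
    res <- optimize_fc("HOFFERQ", co, objective)
    expect_lt(abs(res$constants$fc - g$minimum), 1e-3)
    expect_lte(res$objective_value, g$objective + 1e-9)
  }
  g0 <- oracle_grid_min(pe_objective("HOFFERQ", co, "absmpe"), c(2, 9))
  res0 <- optimize_fc("HOFFERQ", co, "zero_mpe")
  expect_lt(abs(res0$constants$fc - g0$minimum), 1e-3)
  expect_lt(abs(res0$stats$mpe), 1e-9)
})

test_that("zero-mean optimization re-zeroes after a uniform refraction shift", {
  gen <- make_cohort("HOLLADAY1", n = 150, seed = 9)
  res1 <- optimize_fc("HOLLADAY1", gen$cohort, "zero_mpe")
  shifted <- as.data.frame(gen$cohort)
  shifted$seq_achieved <- shifted$seq_achieved + 0.25
  res2 <- optimize_fc("HOLLADAY1", cohort(shifted), "zero_mpe")
  expect_false(isTRUE(all.equal(res1$constants$fc, res2$constants$fc)))
  expect_lt(abs(res2$stats$mpe), 1e-9)
})

test_that("joint constant/offset optimization recovers an injected pure offset", {
  gen <- make_cohort("HOFFERQ", n = 150, seed = 6, noise_sd = 0, ro_true = 0.75)
  res <- optimize_joint("HOFFERQ", gen$cohort, "ro")
  expect_equal(res$constants$ro, 0.75, tolerance = 1e-5)
  expect_equal(res$constants$fc, gen$truth$fc_true, tolerance = 1e-3)
  expect_lt(res$stats$rmspe, 1e-7)
})

test_that("the joint optimum is nested below every single-constant strategy", {
  gen <- make_cohort("HAIGIS", n = 300, seed = 12)
  co <- gen$cohort
  r_a <- optimize_fc("HAIGIS", co, "zero_mpe")
  r_b <- optimize_fc("HAIGIS", co, "min_sdpe")
  r_c <- optimize_fc("HAIGIS", co, "min_rmspe")
  r_d <- optimize_joint("HAIGIS", co, "ro")
  expect_lte(r_d$stats$rmspe, r_c$stats$rmspe + 1e-9)
  expect_lte(r_c$stats$rmspe, min(r_a$stats$rmspe, r_b$stats$rmspe) + 1e-9)
  # strategy B's residual mean equals strategy D's offset
  expect_equal(r_b$stats$mpe, r_d$constants$ro, tolerance = 1e-6)
})

test_that("profiled and naive 2-D constant/offset searches agree", {
  gen <- make_cohort("SRKT", n = 200, seed = 18)
  prof <- optimize_joint("SRKT", gen$cohort, "ro", profile = TRUE)
  naive <- optimize_joint("SRKT", gen$cohort, "ro", profile = FALSE)
  expect_equal(prof$stats$rmspe, naive$stats$rmspe, tolerance = 1e-6)
  expect_equal(prof$constants$ro, naive$constants$ro, tolerance = 1e-3)
})

test_that("joint constant/index search matches a 2-D refinement grid oracle", {
  gen <- make_cohort("HOFFERQ", n = 100, seed = 7)
  co <- gen$cohort
  res <- optimize_joint("HOFFERQ", co, "nk")
  # oracle: for each nk on a fine grid, exhaustive fc refinement grid
  nk_grid <- seq(1.301, 1.379, by = 1e-3)
  best <- Inf; best_nk <- NA
  for (nk in nk_grid) {
    g <- oracle_grid_min(pe_objective("HOFFERQ", co, "rmspe", nk = nk),
                         c(2, 9), coarse = 2e-2, fine = 1e-3, window = 0.06)
    if (g$objective < best) { best <- g$objective; best_nk <- nk }
  }
  expect_lte(res$objective_value, best + 1e-6)
  expect_lt(abs(res$objective_value - best), 1e-3)
  expect_lt(abs(res$constants$nk - best_nk), 2e-3)
})

test_that("two-step procedure: offset equals the step-1 residual mean and zeroes it", {
  gen <- make_cohort("HOFFERQ", n = 250, seed = 23)
  co <- gen$cohort
  res <- optimize_two_step("HOFFERQ", co)
  k0 <- res$constants
  k0$ro <- 0
  expect_equal(res$constants$ro, mean(prediction_errors(k0, co)),
               tolerance = 1e-12)
  expect_lt(abs(res$stats$mpe), 1e-12)

  # noise-free cohort with a true offset: exact recovery
  gen0 <- make_cohort("SRKT", n = 120, seed = 2, noise_sd = 0, ro_true = 0.75)
  r0 <- optimize_two_step("SRKT", gen0$cohort)
  expect_equal(r0$constants$fc, gen0$truth$fc_true, tolerance = 1e-3)
  expect_equal(r0$constants$ro, 0.75, tolerance = 1e-4)
  expect_lt(r0$stats$sdpe, 1e-7)

  # exact two-step equals the joint constant/offset optimum
  r_d <- optimize_joint("HOFFERQ", co, "ro")
  expect_lt(abs(res$stats$rmspe - r_d$stats$rmspe), 1e-6)
})

test_that("single-update two-step mode improves the SD without full iteration", {
  gen <- make_cohort("HOLLADAY1", n = 250, seed = 14)
  co <- gen$cohort
  st <- optimizer_settings(two_step_mode = "single_update")
  start <- formula_constants("HOLLADAY1", fc = 2.5)
  res <- optimize_two_step("HOLLADAY1", co, st, constants = start)
  sd_at <- function(fc) pe_objective("HOLLADAY1", co, "sdpe")(fc)
  expect_lte(res$stats$sdpe, sd_at(2.5) + 1e-12)   # monotone damping
  expect_lt(abs(res$stats$mpe), 1e-12)             # step 2 still zeroes the mean
  # one damped Newton step covers most of the distance to the exact minimizer
  exact <- optimize_two_step("HOLLADAY1", co)
  expect_lt(abs(res$constants$fc - exact$constants$fc),
            0.25 * abs(2.5 - exact$constants$fc))
})

test_that("results are start-value insensitive and flagged on degenerate cohorts", {
  gen <- make_cohort("SRKT", n = 150, seed = 77)
  r1 <- optimize_fc("SRKT", gen$cohort, "min_rmspe",
                    constants = formula_constants("SRKT", fc = 115))
  r2 <- optimize_fc("SRKT", gen$cohort, "min_rmspe",
                    constants = formula_constants("SRKT", fc = 122))
  expect_equal(r1$constants$fc, r2$constants$fc, tolerance = 1e-6)

  small <- cohort(random_eyes(5, seed = 1))
  expect_error(optimize_fc("SRKT", small, "zero_mpe"), "allow_small")
  expect_warning(optimize_fc("SRKT", small, "zero_mpe", allow_small = TRUE),
                 "only 5 eyes")
})

test_that("the strategy suite is self-consistent and reports per-cell results", {
  gen <- make_cohort("SRKT", n = 200, seed = 33)
  co <- gen$cohort
  suite <- run_strategy_suite(co, formulas = c("SRKT", "HAIGIS"))
  expect_s3_class(suite, "iol_suite")
  expect_length(suite$results, 12)
  expect_length(suite$failures, 0)

  met <- metrics_table(suite)
  con <- constants_table(suite)
  expect_equal(nrow(met), 12)
  # zero-mean strategies
  expect_true(all(abs(met$mpe[met$strategy %in% c("A_ZERO_MPE", "F_TWO_STEP")]) < 1e-6))
  # nested-objective ordering per formula
  for (fm in c("SRKT", "HAIGIS")) {
    m <- met[met$formula == fm, ]
    rms <- function(s) m$rmspe[m$strategy == s]
    expect_lte(rms("D_JOINT_FC_RO"), rms("C_MIN_RMSPE") + 1e-9)
    expect_lte(rms("C_MIN_RMSPE"),
               min(rms("A_ZERO_MPE"), rms("B_MIN_SDPE")) + 1e-9)
  }
  # suite cells equal the corresponding single calls bit-for-bit
  single <- optimize_fc("HAIGIS", co, "min_sdpe")
  expect_identical(single$constants$fc,
                   con$fc[con$formula == "HAIGIS" & con$strategy == "B_MIN_SDPE"])
  single_f <- optimize_two_step("SRKT", co)
  expect_identical(single_f$constants$ro,
                   con$ro[con$formula == "SRKT" & con$strategy == "F_TWO_STEP"])
  # objective value is reproduced by the reported stats
  for (key in names(suite$results)) {
    r <- suite$results[[key]]
    recomputed <- switch(r$strategy,
                         A_ZERO_MPE = r$stats$mpe,
                         B_MIN_SDPE = r$stats$sdpe,
                         r$stats$rmspe)
    expect_lt(abs(recomputed - r$objective_value), 1e-8)
  }
})
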