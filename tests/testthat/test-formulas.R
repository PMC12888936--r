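toy_eye <- data.frame(eye_id = "toy", al = 23.5, acd = 3.2, lt = 4.6,
                      r1 = 7.7, r2 = 7.7, iolp = 21, seq_achieved = -0.25)

test_that("effective lens position matches the published ELP models", {
  # Haigis ELP is the stated linear form
  kh <- formula_constants("HAIGIS", fc = 1.0)
  expect_equal(effective_lens_position(kh, toy_eye), 1.0 + 0.4 * 3.2 + 0.1 * 23.5)
  kh0 <- formula_constants("HAIGIS", fc = 2.2, a1 = 0, a2 = 0)
  eyes <- random_eyes(20, seed = 5)
  expect_equal(effective_lens_position(kh0, eyes), rep(2.2, 20))

  # SRK/T corneal-height ELP, frozen from an independent transcription
  ks <- formula_constants("SRKT", fc = 118.4)
  expect_equal(effective_lens_position(ks, toy_eye), 5.1594856616,
               tolerance = 1e-9)
})

test_that("predicted refraction agrees with second-transcription oracles", {
  # frozen toy-eye fixtures (computed from the oracle transcriptions)
  fixtures <- c(SRKT = -0.5476133625, HOFFERQ = -0.0667145522,
                HOLLADAY1 = -0.0752102388, HAIGIS = -0.1697609272)
  fcs <- c(SRKT = 118.4, HOFFERQ = 5.6, HOLLADAY1 = 1.8, HAIGIS = 1.3)
  for (fm in names(fixtures)) {
    k <- formula_constants(fm, fc = fcs[[fm]])
    expect_equal(predict_refraction(k, toy_eye)$seq_pred, fixtures[[fm]],
                 tolerance = 1e-8, label = fm)
  }
  # and across random eyes
  eyes <- random_eyes(200, seed = 77)
  for (fm in names(fixtures)) {
    k <- formula_constants(fm, fc = fcs[[fm]])
    expect_equal(suppressWarnings(predict_refraction(k, eyes)$seq_pred),
                 suppressWarnings(oracle_ref(fm, k, eyes)),
                 tolerance = 1e-9, label = fm)
  }
})

test_that("the refractive offset is purely additive", {
  eyes <- random_eyes(50, seed = 8)
  for (fm in c("SRKT", "HOFFERQ", "HOLLADAY1", "HAIGIS")) {
    k0 <- formula_constants(fm, ro = 0)
    k1 <- formula_constants(fm, ro = 0.5)
    expect_equal(predict_refraction(k1, eyes)$seq_pred,
                 predict_refraction(k0, eyes)$seq_pred + 0.5,
                 tolerance = 1e-12, label = fm)
  }
})

test_that("power calculation and refraction prediction are mutually inverse", {
  eyes <- random_eyes(100, seed = 13)
  for (fm in c("SRKT", "HOFFERQ", "HOLLADAY1", "HAIGIS")) {
    k <- formula_constants(fm, ro = 0.25)
    target <- runif(100, -2.5, 0.5)
    eyes$iolp <- calc_iol_power(k, eyes, target, rounding_step = NULL)
    expect_equal(predict_refraction(k, eyes)$seq_pred, target,
                 tolerance = 1e-6, label = fm)
  }
})

test_that("rounding, monotonicity, and range guards behave", {
  k <- formula_constants("SRKT")
  eyes <- random_eyes(40, seed = 21)
  p <- calc_iol_power(k, eyes, -0.25, rounding_step = 0.5)
  expect_true(all(abs(p / 0.5 - round(p / 0.5)) < 1e-9))

  # longer eye (all else equal) needs less power
  for (fm in c("SRKT", "HOFFERQ", "HOLLADAY1", "HAIGIS")) {
    kf <- formula_constants(fm)
    sweep <- data.frame(al = seq(21, 27, by = 0.5), acd = 3.2, lt = 4.6,
                        r1 = 7.7, r2 = 7.7)
    pw <- calc_iol_power(kf, sweep, -0.25)
    expect_true(all(diff(pw) < 0), label = fm)
    # more implanted power -> more myopic prediction
    one <- data.frame(al = 23.5, acd = 3.2, lt = 4.6, r1 = 7.7, r2 = 7.7,
                      iolp = seq(10, 30, by = 1))
    expect_true(all(diff(predict_refraction(kf, one)$seq_pred) < 0), label = fm)
    # monotone in the primary constant
    b <- switch(fm, SRKT = c(116, 122), HOFFERQ = c(4, 7),
                HOLLADAY1 = c(0.5, 3), HAIGIS = c(0, 2.5))
    preds <- sapply(seq(b[1], b[2], length.out = 9), function(fc)
      predict_refraction(formula_constants(fm, fc = fc), toy_eye)$seq_pred)
    expect_true(all(diff(preds) > 0) || all(diff(preds) < 0), label = fm)
  }

  # unreachable target raises a range error naming the record
  expect_error(calc_iol_power(k, toy_eye, -60), "toy")
})

test_that("out-of-domain intermediates clamp with a classed warning", {
  # very flat, tiny cornea drives the SRK/T corneal-height root negative
  weird <- data.frame(al = 30, acd = 3.2, lt = 4.6, r1 = 5.6, r2 = 5.6,
                      iolp = 5, seq_achieved = 0)
  expect_warning(predict_refraction(formula_constants("SRKT"), weird),
                 class = "iolconst_clamp")
  # Hoffer Q clamps extreme axial lengths
  long <- data.frame(al = 34, acd = 3.4, lt = 4.6, r1 = 7.9, r2 = 7.9,
                     iolp = 5, seq_achieved = 0)
  expect_warning(predict_refraction(formula_constants("HOFFERQ"), long),
                 class = "iolconst_clamp")
})

test_that("constant plausibility bounds and conversions", {
  expect_error(formula_constants("SRKT", fc = 100), "bounds")
  expect_error(formula_constants("HAIGIS", fc = 7), "bounds")
  expect_equal(convert_a_constant(118.4, "acd"), 0.62467 * 118.4 - 68.747)
  expect_equal(convert_a_constant(118.4, "pacd"), 0.58357 * 118.4 - 63.896)
  expect_equal(convert_a_constant(118.4, "sf"), 0.5663 * 118.4 - 65.60)
})
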