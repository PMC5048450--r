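test_that("noiseless monoexponential curves are recovered exactly", {
  b <- dwi_b_scheme()
  cur <- decay_curve(b, monoexp_signal(monoexp_params(500, 1.1e-3), b))
  fit <- fit_adc(cur)
  expect_true(fit$converged)
  expect_equal(fit$params$adc, 1.1e-3, tolerance = 1e-8)
  expect_equal(fit$params$s0, 500, tolerance = 1e-6)

  te <- bold_te_scheme()
  curb <- decay_curve(te, t2star_signal(t2star_params(200, 33), te),
                      kind = "bold")
  fitb <- fit_t2star(curb)
  expect_true(fitb$converged)
  expect_equal(fitb$params$t2_star, 33, tolerance = 1e-8)
})

test_that("two-point fits reproduce the closed-form log-linear solution", {
  cur <- decay_curve(c(200, 800), c(100, 50))
  fit <- fit_adc(cur)
  expect_equal(fit$params$adc, log(2) / 600, tolerance = 1e-8)
  expect_equal(fit$params$adc, 1.155e-3, tolerance = 1e-3)

  s40 <- 200 * exp(-40 / 33)
  curb <- decay_curve(c(5, 40), c(171.9, s40), kind = "bold")
  fitb <- fit_t2star(curb)
  expect_equal(fitb$params$t2_star, 35 / log(171.9 / s40), tolerance = 1e-8)
  expect_equal(fitb$params$t2_star, 33, tolerance = 1e-2)
})

test_that("high-b ADC of a noiseless IVIM curve approximates D", {
  truth <- ivim_params(1000, 0.269, 1.245e-3, 4.0e-2)
  b <- dwi_b_scheme()
  cur <- decay_curve(b, ivim_signal(truth, b))
  fit <- fit_adc(cur)
  expect_lt(abs(fit$params$adc - truth$d) / truth$d, 0.005)
})

test_that("degenerate decay inputs yield non-converged results, not errors", {
  cur <- decay_curve(c(200, 400, 800), c(-1, -2, -3))
  fit <- fit_adc(cur)
  expect_false(fit$converged)
  expect_match(fit$note, "non-positive")

  flat <- decay_curve(bold_te_scheme(), rep(100, 5), kind = "bold")
  fitb <- fit_t2star(flat)
  expect_false(fitb$converged)

  expect_error(fit_adc(decay_curve(c(0, 100), c(10, 5))), "at least two")
})

test_that("segmented initialisation recovers f and D from the intercept", {
  truth <- ivim_params(1000, 0.20, 1.2e-3, 4.0e-2)
  b <- dwi_b_scheme()
  init <- segmented_init(decay_curve(b, ivim_signal(truth, b)))
  expect_gte(init$f, 0.195); expect_lte(init$f, 0.205)
  expect_lt(abs(init$d - 1.2e-3) / 1.2e-3, 0.01)
  expect_false(attr(init, "clamped"))
})

test_that("segmented f is clamped at zero, never negative", {
  b <- dwi_b_scheme()
  mono <- monoexp_signal(monoexp_params(800, 1.3e-3), b)
  init <- segmented_init(decay_curve(b, mono))
  expect_equal(init$f, 0, tolerance = 1e-6)
  # suppressed b = 0 value puts the extrapolated intercept above S(0)
  low <- mono; low[1] <- 0.9 * low[1]
  init2 <- segmented_init(decay_curve(b, low))
  expect_identical(init2$f, 0)
  expect_true(attr(init2, "clamped"))
  expect_error(segmented_init(decay_curve(c(200, 400, 800), c(3, 2, 1))),
               "b = 0")
})

test_that("decay_fit methods are coherent", {
  b <- dwi_b_scheme()
  cur <- decay_curve(b, monoexp_signal(monoexp_params(500, 1.1e-3), b))
  fit <- fit_adc(cur, b_min = 0)
  expect_equal(unname(coef(fit)), c(500, 1.1e-3), tolerance = 1e-6)
  expect_equal(predict(fit, 0), 500, tolerance = 1e-6)
  expect_equal(residuals(fit), rep(0, 9), tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-10)
  expect_output(print(fit), "converged")
})
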