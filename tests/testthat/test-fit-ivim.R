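test_that("noiseless curves at renal truth are recovered to grid precision", {
  truth <- ref_kidney()
  b <- dwi_b_scheme()
  fit <- fit_ivim_bayesian(decay_curve(b, ivim_signal(truth, b)))
  expect_true(fit$converged)
  cf <- coef(fit)
  expect_lt(abs(cf[["f"]] - truth$f) / truth$f, 0.01)
  expect_lt(abs(cf[["d"]] - truth$d) / truth$d, 0.01)
  expect_lt(abs(cf[["d_star"]] - truth$d_star) / truth$d_star, 0.05)
  expect_lt(abs(cf[["s0"]] - truth$s0) / truth$s0, 0.01)
})

test_that("a purely monoexponential curve leaves D* unidentified", {
  b <- dwi_b_scheme()
  cur <- decay_curve(b, monoexp_signal(monoexp_params(1000, 1.3e-3), b))
  # a realistic noise scale: identifiability is a property of the
  # likelihood, which degenerates when sigma is taken to zero
  fit <- fit_ivim_bayesian(cur, sigma = 13.5)
  expect_lt(abs(coef(fit)[["d"]] - 1.3e-3) / 1.3e-3, 0.05)
  # the fast compartment is essentially absent ...
  expect_lt(coef(fit)[["f"]], 0.1)
  # ... and D* is reported unidentifiable: its credible interval spans
  # most of the prior range
  span <- fit$diagnostics$d_star_prior_span
  expect_gte(fit$diagnostics$ci_width[["d_star"]], span / 2)
})

test_that("the grid engine is deterministic and seeds fix the MCMC engine", {
  cur <- noisy_dwi_curve(seed = 5)
  a <- fit_ivim_bayesian(cur)
  b <- fit_ivim_bayesian(cur)
  expect_identical(coef(a), coef(b))
  m1 <- fit_ivim_bayesian(cur, engine = "mcmc", seed = 7,
                          mcmc_iter = 4000, mcmc_burn = 1000)
  m2 <- fit_ivim_bayesian(cur, engine = "mcmc", seed = 7,
                          mcmc_iter = 4000, mcmc_burn = 1000)
  expect_identical(coef(m1), coef(m2))
})

test_that("degenerate curves give non-converged results", {
  b <- dwi_b_scheme()
  flat <- decay_curve(b, rep(500, 9))
  expect_false(fit_ivim_bayesian(flat)$converged)
  bad <- decay_curve(b, c(NaN, 900, 800, 700, 600, 500, 400, 300, 200))
  expect_false(fit_ivim_bayesian(bad)$converged)
})

test_that("prior specification is validated and recorded in the fit", {
  expect_error(prior_spec(f = c(0.5, 0.2)), "lower, upper")
  expect_error(prior_spec(d = c(-1, 1e-2)), "positive")
  expect_error(prior_spec(f = c(0, 2)), "within")
  fit <- fit_ivim_bayesian(noisy_dwi_curve(seed = 2))
  expect_s3_class(fit$priors, "prior_spec")
  expect_equal(fit$priors$d, c(1e-5, 1e-2))
  expect_equal(fit$priors$s0_hi, 2 * max(noisy_dwi_curve(seed = 2)$signal))
})

test_that("both engines agree with the brute-force posterior oracle", {
  # full oracle equivalence over 25 curves lives in the acceptance suite;
  # here a spot check of grid and MCMC on the same two curves
  pr <- prior_spec()
  for (seed in c(3, 8)) {
    cur <- noisy_dwi_curve(seed = seed)
    pr$s0_hi <- 2 * max(cur$signal)
    o <- oracle_ivim_posterior(cur$abscissa, cur$signal, 13.5, pr, n = 100L)
    rng <- c(f = diff(pr$f), d = diff(pr$d), d_star = diff(pr$d_star),
             s0 = pr$s0_hi)
    g <- coef(fit_ivim_bayesian(cur, sigma = 13.5))
    m <- coef(fit_ivim_bayesian(cur, sigma = 13.5, engine = "mcmc",
                                seed = 1, mcmc_iter = 12000,
                                mcmc_burn = 2000))
    for (p in names(rng)) {
      expect_lt(abs(g[[p]] - o[[p]]) / rng[[p]], 0.02)
      expect_lt(abs(m[[p]] - o[[p]]) / rng[[p]], 0.02)
    }
  }
})

test_that("ivim_fit methods expose estimates, intervals and residuals", {
  cur <- noisy_dwi_curve(seed = 4)
  fit <- fit_ivim_bayesian(cur)
  expect_named(coef(fit), c("s0", "f", "d", "d_star"))
  expect_equal(predict(fit, 0), fit$params$s0, tolerance = 1e-12)
  expect_equal(residuals(fit), cur$signal - predict(fit), tolerance = 1e-12)
  expect_true(all(fit$diagnostics$ci[, "hi95"] >=
                    fit$diagnostics$ci[, "lo95"]))
  expect_gte(fit$residual_norm, 0)
  expect_output(print(fit), "D\\*")
  expect_output(summary(fit), "credible")
})

test_that("noise-scale estimate tracks the true sigma", {
  sig_hat <- vapply(1:20, function(s) {
    fit_ivim_bayesian(noisy_dwi_curve(sigma = 13.5, seed = 100 + s))$sigma
  }, numeric(1))
  expect_gt(median(sig_hat), 13.5 * 0.5)
  expect_lt(median(sig_hat), 13.5 * 1.7)
})
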