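test_that("default phantom geometry matches renal ROI sizes", {
  ph <- make_phantom()
  n <- ph$regions$n_voxels
  expect_gte(n[["whole_kidney"]], 79)
  expect_lte(n[["whole_kidney"]], 103)
  # cortex rim of the default ellipse sits in the reported 28 +/- 7 band
  expect_gte(n[["cortex"]], 21)
  expect_lte(n[["cortex"]], 35)
  expect_identical(n[["cortex"]] + n[["medulla"]], n[["whole_kidney"]])
})

test_that("phantom construction is deterministic and validates geometry", {
  a <- make_phantom(phantom_spec(seed = 5))
  b <- make_phantom(phantom_spec(seed = 5))
  expect_identical(a$regions$labels, b$regions$labels)
  expect_identical(a$truth, b$truth)
  expect_error(make_phantom(phantom_spec(semi_axes = c(2, 2))),
               "outside the accepted band")
  # too-thin geometry cannot host a rim plus interior
  expect_error(
    make_phantom(phantom_spec(semi_axes = c(10, 0.9),
                              kidney_count_band = c(1, 200))),
    "too thin")
})

test_that("noiseless simulation reproduces the forward model exactly", {
  ph <- uniform_phantom()
  dwi <- simulate_dwi(ph, noise_sigma = 0)
  in_kid <- ph$regions$labels > 0L
  for (k in seq_along(dwi_b_scheme())) {
    expected <- ivim_signal(ref_kidney(), dwi_b_scheme()[k])
    expect_equal(unique(dwi[, , k][in_kid]), expected, tolerance = 1e-12)
    expect_true(all(dwi[, , k][!in_kid] == 0))
  }
  bold <- simulate_bold(ph, noise_sigma = 0)
  r <- bold[, , 1][in_kid] / bold[, , 5][in_kid]
  expect_equal(unique(r), exp(35 / 32.8), tolerance = 1e-12)
})

test_that("simulation noise is seeded, reproducible, and well calibrated", {
  ph <- make_phantom()
  a <- simulate_dwi(ph, seed = 11)
  b <- simulate_dwi(ph, seed = 11)
  c <- simulate_dwi(ph, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
  # background voxels are pure noise; their SD estimates noise_sigma
  bg <- ph$regions$labels == 0L
  a2 <- simulate_dwi(ph, seed = 13)
  noise <- c(as.vector(a)[rep(bg, length(dwi_b_scheme()))],
             as.vector(a2)[rep(bg, length(dwi_b_scheme()))])
  expect_gt(length(noise), 1e4)
  expect_equal(sd(noise), attr(a, "noise_sigma"), tolerance = 0.05)
  # b = 0 kidney mean is unbiased
  in_kid <- ph$regions$labels > 0L
  s0_mean <- mean(a[, , 1][in_kid])
  tol <- 3 * attr(a, "noise_sigma") / sqrt(sum(in_kid))
  expect_lt(abs(s0_mean - 1000), tol)
  expect_error(simulate_dwi(ph, noise_sigma = -1), ">= 0")
})

test_that("noise SD is anchored to the weakest image of the series", {
  ph <- uniform_phantom()
  dwi <- simulate_dwi(ph, seed = 1)
  s_min <- ivim_signal(ref_kidney(), max(dwi_b_scheme()))
  expect_equal(attr(dwi, "noise_sigma"), s_min / 20, tolerance = 1e-12)
  bold <- simulate_bold(ph, seed = 1)
  expect_equal(attr(bold, "noise_sigma"),
               1000 * exp(-40 / 32.8) / 20, tolerance = 1e-12)
})

test_that("challenge transforms rescale truth and compose to identity", {
  ph <- make_phantom()
  none <- apply_challenge(ph, challenge_transform("none"))
  expect_equal(none$truth, ph$truth, tolerance = 1e-15)

  hyd <- challenge_transform("hydralazine")
  expect_equal(hyd$multipliers$d, 100.2 / 133.9, tolerance = 1e-12)
  expect_equal(hyd$multipliers$d, 0.748, tolerance = 1e-3)
  post <- apply_challenge(ph, hyd)
  expect_lt(max(post$truth$d, na.rm = TRUE), max(ph$truth$d, na.rm = TRUE))
  expect_gt(max(post$truth$f, na.rm = TRUE), max(ph$truth$f, na.rm = TRUE))

  fur <- challenge_transform("furosemide")
  expect_equal(fur$multipliers$t2_star[2], 48.5 / 38.5, tolerance = 1e-12)
  expect_equal(fur$multipliers$t2_star[2], 1.26, tolerance = 1e-2)

  # applying m then 1/m restores the original exactly
  inv <- challenge_transform("none", multipliers = list(
    f = 1 / hyd$multipliers$f, d = 1 / hyd$multipliers$d,
    d_star = 1 / hyd$multipliers$d_star,
    t2_star = 1 / hyd$multipliers$t2_star))
  back <- apply_challenge(apply_challenge(ph, hyd, 2), inv, 2)
  expect_equal(back$truth, ph$truth, tolerance = 1e-12)

  expect_error(challenge_transform("saline"), "unknown drug")
})

test_that("noiseless BOLD round-trips through the T2* fit exactly", {
  ph <- make_phantom()
  bold <- simulate_bold(ph, noise_sigma = 0)
  i <- which(ph$regions$labels > 0L, arr.ind = TRUE)[1, ]
  cur <- decay_curve(bold_te_scheme(), bold[i[1], i[2], ], kind = "bold")
  fit <- fit_t2star(cur)
  expect_true(fit$converged)
  expect_equal(fit$params$t2_star, 32.8, tolerance = 1e-7)
})

test_that("phantom stacks round-trip through NIfTI with a JSON sidecar", {
  ph <- make_phantom()
  dwi <- simulate_dwi(ph, seed = 3)
  prefix <- file.path(tempdir(), "phantom_test")
  write_phantom_stack(dwi, ph, prefix, seed = 3)
  back <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  expect_equal(dim(back), c(32L, 32L, 1L, 9L))
  expect_equal(as.vector(back), as.vector(dwi), tolerance = 1e-6)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(side$abscissa, dwi_b_scheme())
  expect_equal(side$seed, 3)
  lab <- drop(as.array(RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))))
  expect_equal(matrix(lab, 32, 32), ph$regions$labels + 0)
})
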