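test_that("a 5x5 square splits into a 16-voxel rim and 9-voxel interior", {
  m <- matrix(0, 9, 9); m[3:7, 3:7] <- 1
  rs <- derive_regions(m)
  expect_identical(rs$n_voxels[["cortex"]], 16L)
  expect_identical(rs$n_voxels[["medulla"]], 9L)
  expect_identical(rs$n_voxels[["whole_kidney"]], 25L)
})

test_that("degenerate masks are rejected with an informative error", {
  m <- matrix(0, 5, 5); m[2:4, 3] <- 1
  expect_error(derive_regions(m), "too thin")
  expect_error(derive_regions(matrix(0, 5, 5)), "empty")
})

test_that("cortex and medulla partition the kidney for varied geometries", {
  set.seed(14)
  for (i in 1:15) {
    ax <- c(runif(1, 2.5, 8), runif(1, 2.5, 6))
    mask <- matrix(0, 24, 24)
    xs <- row(mask); ys <- col(mask)
    mask[((xs - 12) / ax[1])^2 + ((ys - 12) / ax[2])^2 <= 1] <- 1
    rs <- derive_regions(mask)
    lab <- rs$labels
    expect_true(all((lab == 1) + (lab == 2) == (mask == 1)))
    expect_identical(sum(lab == 1) + sum(lab == 2), sum(mask == 1))
  }
})

test_that("8-connectivity erosion gives a thicker rim than 4-connectivity", {
  ph <- make_phantom()
  mask <- (ph$regions$labels > 0) * 1
  r4 <- derive_regions(mask, connectivity = 4)
  r8 <- derive_regions(mask, connectivity = 8)
  expect_gte(r8$n_voxels[["cortex"]], r4$n_voxels[["cortex"]])
})

test_that("region medians use converged voxels only and ignore ordering", {
  labels <- matrix(0L, 4, 4)
  labels[2:3, 2:3] <- 2L; labels[2, 2] <- 1L
  rs <- structure(list(labels = labels, connectivity = 4,
                       provenance = "fixture",
                       n_voxels = c(whole_kidney = 4L, cortex = 1L,
                                    medulla = 3L)),
                  class = "region_set")
  vals <- matrix(NA_real_, 4, 4)
  vals[2, 2] <- 1; vals[3, 2] <- 2; vals[2, 3] <- 3; vals[3, 3] <- 999
  conv <- matrix(FALSE, 4, 4)
  conv[2, 2] <- conv[3, 2] <- conv[2, 3] <- TRUE   # 999 never converged
  pm <- structure(list(values = list(t2_star = vals), converged = conv,
                       in_mask = labels > 0L, model = "t2star",
                       n_voxels = 4L, n_nonconverged = 1L),
                  class = "parameter_map")
  sm <- summarise_regions(pm, rs, subregions = FALSE)
  expect_equal(sm$median, 2)        # median of 1, 2, 3; 999 excluded
  expect_equal(sm$n_voxels, 3L)
  expect_equal(sm$n_excluded, 1L)
  # value of the non-converged voxel is irrelevant
  vals[3, 3] <- -1e6
  pm$values$t2_star <- vals
  expect_equal(summarise_regions(pm, rs, subregions = FALSE)$median, 2)
})

test_that("noiseless uniform phantom summaries equal the seeded truth", {
  ph <- uniform_phantom()
  dwi <- simulate_dwi(ph, noise_sigma = 0)
  m <- fit_map(dwi, ph$regions, model = "ivim")
  sm <- summarise_regions(m, ph$regions)
  expect_equal(whole_kidney_median(sm, "d"), 124.5, tolerance = 1e-4)
  expect_equal(whole_kidney_median(sm, "f"), 26.9, tolerance = 1e-3)
  expect_equal(whole_kidney_median(sm, "d_star"), 4.0, tolerance = 1e-3)
})

test_that("distinct cortex/medulla truths are recovered per region", {
  ph <- make_phantom()    # distinct region parameters
  dwi <- simulate_dwi(ph, noise_sigma = 0)
  m <- fit_map(dwi, ph$regions, model = "ivim")
  sm <- summarise_regions(m, ph$regions)
  ctx <- sm[sm$region == "cortex", ]
  med <- sm[sm$region == "medulla", ]
  expect_equal(ctx$median[ctx$parameter == "d"], 105.0, tolerance = 1e-4)
  expect_equal(med$median[med$parameter == "d"], 133.0, tolerance = 1e-4)
  expect_equal(ctx$median[ctx$parameter == "f"], 27.1, tolerance = 1e-3)
  expect_equal(med$median[med$parameter == "f"], 23.4, tolerance = 1e-3)
})

test_that("exclusion log drops kidneys and refuses an empty cohort", {
  log <- exclusion_log()
  expect_identical(nrow(log), 0L)
  log <- exclude_kidney(log, "k02", "slice positioning precluded ROI")
  expect_identical(log$kidney_id, "k02")
  s <- data.frame(kidney_id = c("k01", "k02"), region = "whole_kidney",
                  parameter = "d", median = c(124, 130))
  kept <- apply_exclusions(s, log)
  expect_identical(kept$kidney_id, "k01")
  log2 <- exclude_kidney(log, "k01", "signal dropout")
  expect_error(apply_exclusions(s, log2), "all kidneys are excluded")
  expect_error(exclude_kidney(log, "k03", ""), "reason is required")
})
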