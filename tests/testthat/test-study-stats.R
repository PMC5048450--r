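test_that("within-subject CoV matches hand-evaluated values", {
  expect_equal(cov_repeatability(c(100, 50), c(100, 50)), 0)
  expect_equal(cov_repeatability(100, 110),
               100 * sqrt((10 / 105)^2 / 2), tolerance = 1e-12)
  expect_equal(cov_repeatability(100, 110), 6.73, tolerance = 1e-2)
})

test_that("CoV is invariant to rescaling and to scan order", {
  set.seed(8)
  for (i in 1:10) {
    v1 <- runif(6, 50, 150); v2 <- v1 * (1 + rnorm(6, 0, 0.1))
    base <- cov_repeatability(v1, v2)
    expect_equal(cov_repeatability(3.7 * v1, 3.7 * v2), base,
                 tolerance = 1e-12)
    swap <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    expect_equal(cov_repeatability(ifelse(swap, v2, v1),
                                   ifelse(swap, v1, v2)),
                 base, tolerance = 1e-12)
  }
  expect_warning(cov_repeatability(c(100, -5), c(110, -6)), "non-positive")
  expect_error(suppressWarnings(cov_repeatability(-1, -2)), "no usable")
})

test_that("paired Wilcoxon matches exact sign-assignment enumeration", {
  # six uniformly positive differences: two-sided p = 2/64
  pre <- c(10, 12, 14, 16, 18, 20)
  post <- pre - c(1.1, 0.9, 1.3, 0.8, 1.2, 1.0)
  res <- paired_test(pre, post)
  expect_equal(res$p_value, 2 / 64, tolerance = 1e-12)
  expect_true(res$significant)
  # random small samples against the brute-force null distribution
  set.seed(31)
  for (i in 1:8) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n, 0.3, 1), 3)
    while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(n, 0.3, 1), 3)
    v1 <- 100 + d; v2 <- rep(100, n)
    expect_equal(paired_test(v1, v2)$p_value, oracle_signed_rank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("degenerate paired data reports p = 1 with a note", {
  res <- paired_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_match(res$note, "degenerate")
})

test_that("significance flag follows the 5 percent threshold", {
  pre <- c(10, 12, 14, 16, 18, 20)
  res_sig <- paired_test(pre, pre - 1)
  expect_identical(res_sig$significant, res_sig$p_value < 0.05)
  res_ns <- paired_test(pre, pre + c(-1, 1, -1, 1, -1, 1) * 0.5)
  expect_identical(res_ns$significant, res_ns$p_value < 0.05)
  expect_false(res_ns$significant)
})

test_that("repeated-measures BOLD test flags an injected step response", {
  tps <- c("baseline", "2m15s", "6m51s", "11m24s")
  set.seed(12)
  units <- sprintf("k%02d", 1:6)
  mk <- function(effect) {
    do.call(rbind, lapply(seq_along(units), function(i) {
      data.frame(unit_id = units[i], timepoint = tps,
                 value = 33 + effect * c(0, 0, 1, 1) + rnorm(4, 0, 0.3))
    }))
  }
  tc <- mk(8)   # large step from the second post timepoint
  res <- bold_timecourse_test(tc)
  expect_lt(res$omnibus_p, 0.05)
  tab <- res$table
  expect_true(tab$sig_vs_baseline[tab$timepoint == "6m51s"])
  expect_true(tab$sig_vs_baseline[tab$timepoint == "11m24s"])
  expect_true(tab$sig_vs_previous[tab$timepoint == "6m51s"])
  # permutation oracle agrees that the omnibus effect is real
  wide <- tapply(tc$value, list(tc$unit_id, tc$timepoint), mean)[, tps]
  expect_lt(oracle_rm_anova_p(wide), 0.05)

  flat <- mk(0)
  res0 <- bold_timecourse_test(flat)
  expect_gte(res0$omnibus_p, 0.05)
  expect_false(any(res0$table$sig_vs_baseline))
})

test_that("incomplete timecourses are dropped with a warning", {
  tc <- data.frame(unit_id = c("a", "a", "a", "a", "b", "b", "c", "c", "c", "c"),
                   timepoint = c("t0", "t1", "t2", "t3", "t0", "t1",
                                 "t0", "t1", "t2", "t3"),
                   value = c(30, 31, 32, 33, 30, 31, 29, 30, 31, 32))
  expect_warning(res <- bold_timecourse_test(tc), "incomplete")
  expect_identical(res$n_units, 2L)
})

test_that("percent change is 100 at baseline and matches arithmetic", {
  tc <- data.frame(unit_id = "k1",
                   timepoint = c("baseline", "2m15s", "6m51s", "11m24s"),
                   value = c(38.5, 44.7, 48.5, 47.8))
  pc <- percent_change(tc)
  expect_equal(pc$per_unit$percent[1], 100)
  expect_equal(pc$per_unit$percent[3], 100 * 48.5 / 38.5, tolerance = 1e-12)
  expect_equal(pc$per_unit$percent[3], 126, tolerance = 1e-2)
  flat <- within(tc, value <- 40)
  expect_true(all(percent_change(flat)$per_unit$percent == 100))
  bad <- tc; bad$value[1] <- -1
  expect_error(percent_change(bad), "positive")
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate_adc_d(x, x)$r, 1)
  expect_equal(correlate_adc_d(x, -x)$r, -1)
  res <- correlate_adc_d(x, rep(2, 4))
  expect_true(is.na(res$r))
  expect_match(res$note, "zero variance")
  expect_error(correlate_adc_d(c(1, 2), c(1, 2)), "three")
})
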