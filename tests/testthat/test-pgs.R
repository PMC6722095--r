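test_that("PGS group models keep exact likelihood-ratio bookkeeping", {
  d <- small_pgs_cohort(seed = 2)
  out <- pgs_by_ses_tests(d)
  expect_equal(out$stratified$n_free - out$means_equated$n_free, 3L)
  expect_equal(out$stratified$n_free - out$variances_equated$n_free, 3L)
  expect_equal(out$means_test$delta_df, 3L)
  # generated with SES-rising PGS means: the equality test must reject
  expect_lt(out$means_test$p_value, 1e-4)
  # and with a shared variance: the variance test must retain
  expect_gt(out$variances_test$p_value, 0.01)
})

test_that("PGS mean-equality test retains under an equal-means truth", {
  d <- small_pgs_cohort(seed = 5, pgs_means = c(0, 0, 0, 0))
  out <- pgs_by_ses_tests(d)
  expect_gt(out$means_test$p_value, 0.01)
})

test_that("a group without scores is refused", {
  d <- small_pgs_cohort(seed = 3)
  d$pgs1[d$ses == 2] <- NA_real_
  d$pgs2[d$ses == 2] <- NA_real_
  class(d) <- c("twin_data", "data.frame")
  expect_error(pgs_by_ses_tests(d), "without polygenic scores")
})

test_that("DZ PGS correlation matches its oracles and guards", {
  d <- small_pgs_cohort(seed = 7)
  dz <- d$zygosity == "DZ"
  out <- dz_pgs_correlation(d)
  # uncensored bivariate-normal ML correlation = product-moment correlation
  expect_equal(out$r, cor(d$pgs1[dz], d$pgs2[dz]), tolerance = 1e-3)
  expect_equal(out$r, 0.5, tolerance = 0.06)
  expect_lt(out$lower, out$r); expect_gt(out$upper, out$r)
  dmz <- d[d$zygosity == "MZ", ]; class(dmz) <- class(d)
  expect_error(dz_pgs_correlation(dmz), "fixed at 1")
})

test_that("EA-on-PGS slopes center on zero under a null PGS effect", {
  d <- small_pgs_cohort(seed = 11, beta_pgs = 0)
  f <- ea_on_pgs_fit(d, slopes = "shared", variances = "shared",
                     n_starts = 1)
  expect_lt(abs(f$estimates$beta_pgs[1]), 0.5)
})

test_that("slope- and intercept-equality tests behave as generated", {
  d <- small_pgs_cohort(seed = 13)   # shared slope, SES-shifted intercepts
  fb <- ea_on_pgs_fit(d, slopes = "by_ses", variances = "shared",
                      n_starts = 1)
  fs <- ea_on_pgs_fit(d, slopes = "shared", variances = "shared",
                      n_starts = 1)
  fi <- ea_on_pgs_fit(d, slopes = "by_ses", intercepts = "shared",
                      variances = "shared", n_starts = 1)
  st <- lrt(fb, fs); it <- lrt(fb, fi)
  expect_equal(st$delta_df, 3L); expect_equal(it$delta_df, 3L)
  expect_gt(st$p_value, 0.01)      # slopes generated homogeneous
  expect_lt(it$p_value, 1e-6)      # intercepts generated heterogeneous
})

test_that("the within-family contrast detects a positive PGS effect", {
  d <- small_pgs_cohort(seed = 17)
  out <- within_family_test(d)
  expect_gt(out$mean_pgs_gap, 0)
  expect_equal(out$mean_pgs_gap, 0.76, tolerance = 0.1)  # E|N(0, sqrt(2(1-r)))|
  expect_gt(out$mean_ea_gap, 0)
  expect_lt(out$lrt$p_value, 0.001)
  expect_equal(out$lrt$delta_df, 1L)
})

test_that("the within-family gap is null-calibrated and centered at zero", {
  d <- small_pgs_cohort(seed = 19, beta_pgs = 0)
  out <- within_family_test(d)
  expect_lt(abs(out$mean_ea_gap), 1)
  expect_gt(out$lrt$p_value, 0.01)
})

test_that("group-constant shifts in achievement do not move the gap", {
  d <- small_pgs_cohort(seed = 23)
  base <- within_family_test(d, censoring = FALSE)
  shifted <- d
  shifted$ea1 <- d$ea1 - c(6, 2, -3, -8)[d$ses]
  shifted$ea2 <- d$ea2 - c(6, 2, -3, -8)[d$ses]
  class(shifted) <- class(d)
  out <- within_family_test(shifted, censoring = FALSE)
  expect_equal(out$mean_ea_gap, base$mean_ea_gap, tolerance = 1e-4)
  expect_equal(out$gap_ols, base$gap_ols, tolerance = 1e-10)
})

test_that("doubling the PGS effect raises the expected achievement gap", {
  g1 <- within_family_test(small_pgs_cohort(seed = 29,
                                            beta_pgs = 1.3))$mean_ea_gap
  g2 <- within_family_test(small_pgs_cohort(seed = 29,
                                            beta_pgs = 2.6))$mean_ea_gap
  expect_gt(g2, g1)
})

test_that("tied PGS pairs are dropped and tiny samples refused", {
  d <- small_pgs_cohort(seed = 31)
  dz <- which(d$zygosity == "DZ")
  d$pgs2[dz[1:3]] <- d$pgs1[dz[1:3]]
  class(d) <- c("twin_data", "data.frame")
  expect_message(out <- within_family_test(d), "tied")
  expect_equal(out$n_ties_dropped, 3L)
  small <- d[dz[1:8], ]; class(small) <- class(d)
  expect_error(suppressMessages(within_family_test(small)), "fewer than 10")
})

test_that("between-family slope agrees with the within-family contrast when genotype and SES are uncorrelated", {
  d <- small_pgs_cohort(seed = 37, pgs_means = c(0, 0, 0, 0))
  between <- ea_on_pgs_fit(d, slopes = "shared", variances = "shared",
                           n_starts = 1)$estimates$beta_pgs[1]
  wf <- within_family_test(d)
  implied <- wf$mean_ea_gap / wf$mean_pgs_gap
  expect_equal(between, implied, tolerance = 0.35)
})
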