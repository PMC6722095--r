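test_that("the default configuration carries the cohort point estimates", {
  cfg <- sim_config()
  expect_equal(c(cfg$a2[1], cfg$c2[1], cfg$e2[1]), c(65.9, 2.7, 17.9))
  expect_equal(cfg$threshold, 550)
  expect_equal(cfg$pgs_dz_correlation, 0.5)
  expect_equal(cfg$incomplete_fraction, 0.14)
  expect_true(all(diff(cfg$mean_girls) > 0))      # means rise with SES
  expect_true(all(diff(cfg$a2 + cfg$c2 + cfg$e2) < 0))  # variances shrink
})

test_that("configuration validation rejects impossible generating models", {
  expect_error(sim_config(a2 = c(-1, 60, 52, 47)), "non-negative")
  expect_error(sim_config(threshold = 500, floor_value = 501), "exceed")
  expect_error(sim_config(incomplete_fraction = 1), "\\[0, 1\\)")
  expect_error(sim_config(pgs_dz_correlation = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(beta_pgs = 10), "cannot carry more than A")
})

test_that("generation is deterministic given config and seed", {
  cfg <- sim_config(n_pairs = 50)
  a <- simulate_cohort(cfg, seed = 9)
  b <- simulate_cohort(cfg, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(a$ea1, c2$ea1))
})

test_that("with only shared components MZ co-twins are exactly equal", {
  cfg <- sim_config(n_pairs = matrix(c(50, 0), 1, 2), mean_girls = 535,
                    sex_effect = 0, a2 = 60, c2 = 0, e2 = 0,
                    pgs_means = 0, beta_pgs = 0, incomplete_fraction = 0)
  d <- simulate_twins(cfg, seed = 4)
  expect_identical(d$ea1, d$ea2)
  expect_identical(d$pgs1, d$pgs2)
})

test_that("twin correlations and moments converge to their closed forms", {
  cfg <- one_group_config(a2 = 58, c2 = 7, e2 = 16, n_mz = 10000,
                          n_dz = 10000)
  d <- simulate_twins(cfg, seed = 21)
  mz <- d$zygosity == "MZ"; dz <- !mz
  expect_equal(cor(d$lat1[mz], d$lat2[mz]), 65 / 81, tolerance = 0.02)
  expect_equal(cor(d$lat1[dz], d$lat2[dz]), (29 + 7) / 81, tolerance = 0.035)
  expect_equal(mean(c(d$lat1, d$lat2)), 535, tolerance = 0.15)
  expect_equal(sd(c(d$lat1, d$lat2)), 9, tolerance = 0.1)
})

test_that("DZ PGS pairs carry the configured correlation, MZ are identical", {
  cfg <- one_group_config(n_mz = 4000, n_dz = 8000)
  cfg$pgs_dz_correlation <- 0.55
  d <- simulate_twins(cfg, seed = 13)
  mz <- d$zygosity == "MZ"
  expect_identical(d$pgs1[mz], d$pgs2[mz])
  expect_equal(cor(d$pgs1[!mz], d$pgs2[!mz]), 0.55, tolerance = 0.025)
})

test_that("censoring replaces ceiling scores and is monotone in the threshold", {
  d0 <- simulate_twins(sim_config(n_pairs = 200), seed = 2)
  # explicit example: one score above, one below the ceiling
  d0$ea1[1] <- 548.0; d0$ea2[1] <- 553.2
  d <- apply_censoring(d0, 550)
  expect_equal(d$ea1[1], 548.0); expect_false(d$cens1[1])
  expect_equal(d$ea2[1], 550); expect_true(d$cens2[1])
  expect_true(all(d$ea1 <= 550 & d$ea2 <= 550))
  # infinite threshold is a no-op
  dinf <- apply_censoring(d0, Inf, floor_value = -Inf)
  expect_equal(dinf$ea1, d0$ea1)
  expect_false(any(dinf$cens1 | dinf$cens2))
  # raising the threshold never censors more
  n549 <- sum(apply_censoring(d0, 549)$cens1)
  n551 <- sum(apply_censoring(d0, 551)$cens1)
  expect_lte(n551, n549)
  expect_error(apply_censoring(d0, 500, floor_value = 501), "exceed")
})

test_that("the censored fraction rises strictly with SES under the defaults", {
  d <- apply_censoring(simulate_twins(sim_config(), seed = 31), 550)
  frac <- tapply(c(d$cens1, d$cens2), rep(d$ses, 2), mean)
  expect_true(all(diff(frac) > 0))
})

test_that("incomplete pairs lose exactly one score, never two", {
  cfg <- one_group_config(n_mz = 2500, n_dz = 2500)
  d <- apply_censoring(simulate_twins(cfg, seed = 6), 550)
  expect_identical(make_incomplete(d, 0), d)
  di <- make_incomplete(d, 0.14, seed = 6)
  n_inc <- sum(is.na(di$ea1) | is.na(di$ea2))
  expect_equal(n_inc, round(0.14 * nrow(d)))
  expect_false(any(is.na(di$ea1) & is.na(di$ea2)))
  expect_identical(di$pgs1, d$pgs1)  # PGS missingness is independent
})
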