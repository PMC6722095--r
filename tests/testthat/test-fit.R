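test_that("censored FIML recovers a single-group generating model", {
  cfg <- one_group_config(mean_girls = 538, sex_effect = 1.2,
                          a2 = 58, c2 = 7, e2 = 16,
                          n_mz = 1200, n_dz = 1200)
  d <- simulate_cohort(cfg, seed = 17)
  f <- fit_twin_model(d, twin_spec(means = "shared", variances = "shared",
                                   sex = "shared"), n_starts = 2)
  expect_true(f$converged)
  e <- f$estimates
  expect_equal(e$intercept[1], 538, tolerance = 0.002)  # relative: ~1 point
  expect_equal(e$total[1], 81, tolerance = 0.08)
  expect_equal(e$a2[1] + e$c2[1], 65, tolerance = 0.12)  # MZ covariance
  expect_equal(e$e2[1], 16, tolerance = 0.15)
  expect_equal(e$beta_sex[1], 1.2, tolerance = 0.6)
})

test_that("a zero common-environment truth is recovered at the boundary", {
  cfg <- one_group_config(a2 = 60, c2 = 0, e2 = 20, n_mz = 1500, n_dz = 1500)
  d <- simulate_twins(cfg, seed = 23)          # uncensored on purpose
  f <- fit_twin_model(d, shared_spec(), n_starts = 3)
  expect_lt(f$estimates$c2[1], 4)
})

test_that("nested models never beat their parents and LRT bookkeeping holds", {
  d <- simulate_cohort(sim_config(n_pairs = cbind(MZ = rep(80, 4),
                                                  DZ = rep(140, 4)),
                                  incomplete_fraction = 0), seed = 3)
  ace <- fit_twin_model(d, twin_spec(means = "by_ses", variances = "shared",
                                     sex = "shared"), n_starts = 1)
  ae <- fit_twin_model(d, twin_spec(means = "by_ses", variances = "shared",
                                    include_c = FALSE, sex = "shared"),
                       n_starts = 1)
  sh <- fit_twin_model(d, twin_spec(means = "shared", variances = "shared",
                                    sex = "shared"), n_starts = 1)
  expect_gte(ae$minus2ll, ace$minus2ll - 1e-6)
  expect_gte(sh$minus2ll, ace$minus2ll - 1e-6)
  t1 <- lrt(ace, ae)
  expect_equal(t1$delta_df, 1L)
  expect_gte(t1$delta_minus2ll, 0)
  t2 <- lrt(ace, sh)
  expect_equal(t2$delta_df, 3L)
  expect_lt(t2$p_value, 1e-6)  # generated with strongly SES-shifted means
})

test_that("relabeling twin 1 and twin 2 leaves the deviance unchanged", {
  d <- simulate_cohort(one_group_config(n_mz = 150, n_dz = 250), seed = 8)
  f1 <- fit_twin_model(d, shared_spec(), n_starts = 1)
  dsw <- d
  for (cols in list(c("ea1", "ea2"), c("cens1", "cens2"),
                    c("sex1", "sex2"), c("pgs1", "pgs2"))) {
    dsw[[cols[1]]] <- d[[cols[2]]]; dsw[[cols[2]]] <- d[[cols[1]]]
  }
  f2 <- fit_twin_model(dsw, shared_spec(), n_starts = 1)
  expect_equal(f1$minus2ll, f2$minus2ll, tolerance = 1e-6)
})

test_that("preconditions are enforced before fitting", {
  d <- simulate_cohort(one_group_config(n_mz = 60, n_dz = 60), seed = 1)
  # stratified model with absent groups
  d4 <- d; d4$ses <- 4L; class(d4) <- class(d)
  expect_error(fit_twin_model(d4, twin_spec(means = "by_ses",
                                            variances = "shared",
                                            sex = "none")),
               "no data")
  # separating A from C needs both zygosities
  dmz <- d[d$zygosity == "MZ", ]; class(dmz) <- class(d)
  expect_error(fit_twin_model(dmz, shared_spec()), "MZ and DZ")
  # PGS spec without scores
  dnp <- d; dnp$pgs1 <- NA_real_; dnp$pgs2 <- NA_real_
  class(dnp) <- class(d)
  expect_error(fit_twin_model(dnp, twin_spec(means = "shared",
                                             variances = "shared",
                                             sex = "none", pgs = "shared")),
               "polygenic")
})

test_that("pinning one group's sex effect reduces the free-parameter count", {
  spec_all <- twin_spec(means = "by_ses", variances = "shared",
                        sex = "by_ses")
  spec_pin <- twin_spec(means = "by_ses", variances = "shared",
                        sex = "by_ses", sex_free = c(TRUE, TRUE, TRUE, FALSE))
  pm_all <- twincens:::make_parmap(spec_all, 4L)
  pm_pin <- twincens:::make_parmap(spec_pin, 4L)
  expect_equal(pm_all$n_free - pm_pin$n_free, 1L)
  expect_true(twincens:::is_nested_spec(spec_all, spec_pin))
  expect_false(twincens:::is_nested_spec(spec_pin, spec_all))
})
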