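# shared fixtures, all generated in code

# single-SES-group configuration (no PGS effect, no missingness)
one_group_config <- function(mean_girls = 535, sex_effect = 0,
                             a2 = 58.32, c2 = 6.48, e2 = 16.2,
                             n_mz = 500, n_dz = 500, ...) {
  sim_config(n_pairs = matrix(c(n_mz, n_dz), 1, 2),
             mean_girls = mean_girls, sex_effect = sex_effect,
             a2 = a2, c2 = c2, e2 = e2,
             pgs_means = 0, beta_pgs = 0, incomplete_fraction = 0, ...)
}

# the four per-group truth columns of the default generator
default_truth <- function() {
  cfg <- sim_config()
  list(mean_girls = cfg$mean_girls, sex_effect = cfg$sex_effect,
       a2 = cfg$a2, c2 = cfg$c2, e2 = cfg$e2,
       total = cfg$a2 + cfg$c2 + cfg$e2)
}

# a small 4-group cohort with PGS, scaled cell counts
small_pgs_cohort <- function(seed = 1, cells_mz = c(40, 120, 90, 45),
                             cells_dz = c(70, 220, 165, 75), ...) {
  cfg <- sim_config(n_pairs = cbind(MZ = cells_mz, DZ = cells_dz),
                    incomplete_fraction = 0, ...)
  standardize_pgs(simulate_cohort(cfg, seed = seed))
}

shared_spec <- function(...) {
  twin_spec(means = "shared", variances = "shared", sex = "none", ...)
}
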