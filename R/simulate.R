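# -------------------------------------------------------------------------
# Synthetic twin-cohort generator.
#
# Generating model for the latent (pre-censoring) score of twin i in pair j
# of SES group g:
#
#   EA_ij = m_g + b_g * male_ij + beta * (PGS_ij - p_g) + R_ij + C_j + E_ij
#
# (A_1, A_2) := beta*(PGS - p_g) + R is the additive-genetic component: PGS
# pairs are bivariate normal with within-pair correlation 1 (MZ) or
# pgs_dz_correlation (DZ) around the SES-group mean p_g, and the residual
# polygenic part R is bivariate normal with correlation 1 (MZ) / 0.5 (DZ)
# and variance a2 - beta^2 * pgs_variance. With the default DZ PGS
# correlation of 0.5 the total additive component has exactly variance a2
# and twin correlations 1 / 0.5, so the configured ACE variances are the
# true generating decomposition and the PGS captures part of A, mirroring
# how an educational-attainment PGS captures part of the heritability.
# C_j is shared within the pair (variance c2); E_ij is independent
# (variance e2). Group means are exact because the PGS is centered at p_g.
# -------------------------------------------------------------------------

#' Simulation configuration for a synthetic twin cohort
#'
#' Builds the full generating model for the cohort simulator. The defaults
#' are calibrated to a four-level SES twin cohort of 12-year-olds taking a
#' national test scored 501--550 with a hard ceiling at 550: group means
#' rise with SES, boys score slightly higher than girls (least so in the
#' highest group), and all three ACE variance components shrink with rising
#' SES. Cell counts default to the cohort's MZ/DZ pair counts per SES group.
#'
#' @param n_pairs number of pairs per (SES group x zygosity) cell: a G x 2
#'   matrix with columns MZ, DZ, or a single number used for every cell.
#' @param mean_girls latent mean score for girls, per SES group.
#' @param sex_effect score-point increment for boys, per group (recycled).
#' @param a2,c2,e2 additive-genetic, common-environment and
#'   unique-environment variances per group (score points squared).
#' @param pgs_means mean standardized PGS per SES group.
#' @param pgs_variance within-group PGS variance (shared across groups).
#' @param pgs_dz_correlation within-pair PGS correlation for DZ pairs; 0.5
#'   is the biometrical expectation, values up to 1 accommodate assortative
#'   mating.
#' @param beta_pgs score points per PGS standard deviation; the default
#'   makes the PGS account for roughly 10\% of within-group variance. Must
#'   satisfy \code{beta_pgs^2 * pgs_variance <= min(a2)}.
#' @param threshold,floor_value score ceiling (right-censoring point) and
#'   floor.
#' @param incomplete_fraction fraction of pairs in which one twin's score is
#'   made missing.
#' @param seed integer seed driving every random draw.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_pairs = NULL,
                       mean_girls = c(533.2, 535.8, 538.9, 542.0),
                       sex_effect = c(1.3, 1.2, 1.2, 0.3),
                       a2 = c(65.9, 60.8, 52.3, 47.8),
                       c2 = c(2.7, 1.8, 0.0, 0.0),
                       e2 = c(17.9, 16.5, 14.7, 11.2),
                       pgs_means = c(-0.30, -0.10, 0.10, 0.30),
                       pgs_variance = 1,
                       pgs_dz_correlation = 0.5,
                       beta_pgs = 2.7,
                       threshold = 550,
                       floor_value = 501,
                       incomplete_fraction = 0.14,
                       seed = 1L) {
  G <- length(mean_girls)
  if (is.null(n_pairs)) {
    n_pairs <- if (G == 4L) {
      cbind(MZ = c(320L, 1030L, 766L, 363L), DZ = c(571L, 1859L, 1378L, 642L))
    } else matrix(500L, G, 2, dimnames = list(NULL, c("MZ", "DZ")))
  }
  if (length(n_pairs) == 1L)
    n_pairs <- matrix(n_pairs, G, 2, dimnames = list(NULL, c("MZ", "DZ")))
  n_pairs <- as.matrix(n_pairs)
  if (nrow(n_pairs) != G || ncol(n_pairs) != 2L)
    stop("sim_config: n_pairs must be a ", G, " x 2 matrix (MZ, DZ)")
  colnames(n_pairs) <- c("MZ", "DZ")
  sex_effect <- rep_len(sex_effect, G)
  a2 <- rep_len(a2, G); c2 <- rep_len(c2, G); e2 <- rep_len(e2, G)
  pgs_means <- rep_len(pgs_means, G)

  if (any(!is.finite(c(a2, c2, e2, pgs_variance))) ||
      any(c(a2, c2, e2) < 0) || pgs_variance < 0)
    stop("sim_config: variances must be finite and non-negative")
  if (pgs_dz_correlation < 0 || pgs_dz_correlation > 1)
    stop("sim_config: pgs_dz_correlation must lie in [0, 1]")
  if (threshold <= floor_value)
    stop("sim_config: threshold must exceed floor_value")
  if (incomplete_fraction < 0 || incomplete_fraction >= 1)
    stop("sim_config: incomplete_fraction must lie in [0, 1)")
  if (beta_pgs^2 * pgs_variance > min(a2) + 1e-9)
    stop("sim_config: beta_pgs^2 * pgs_variance exceeds the smallest ",
         "additive-genetic variance; the PGS cannot carry more than A")

  structure(list(
    n_pairs = n_pairs, mean_girls = mean_girls, sex_effect = sex_effect,
    a2 = a2, c2 = c2, e2 = e2,
    pgs_means = pgs_means, pgs_variance = pgs_variance,
    pgs_dz_correlation = pgs_dz_correlation, beta_pgs = beta_pgs,
    threshold = threshold, floor_value = floor_value,
    incomplete_fraction = incomplete_fraction, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", sum(x$n_pairs), "pairs in", length(x$mean_girls),
      "SES group(s)\n")
  tab <- rbind(mean_girls = x$mean_girls, sex_effect = x$sex_effect,
               a2 = x$a2, c2 = x$c2, e2 = x$e2, pgs_mean = x$pgs_means)
  colnames(tab) <- ses_labels[seq_along(x$mean_girls)]
  print(round(tab, 2))
  cat(sprintf("beta_pgs = %.2f, DZ PGS correlation = %.2f, ceiling = %s, seed = %d\n",
              x$beta_pgs, x$pgs_dz_correlation, x$threshold, x$seed))
  invisible(x)
}

# bivariate normal pairs with common mean/variance and correlation r
rbvn_pairs <- function(n, mean, var, r) {
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  cbind(mean + sqrt(var) * z1, mean + sqrt(var) * z2)
}

#' Simulate latent (pre-censoring) twin pairs
#'
#' Draws a cohort from the generating model of a \code{\link{sim_config}}.
#' Scores are returned \emph{latent}: no censoring, clipping or missingness
#' is applied (use \code{\link{apply_censoring}} and
#' \code{\link{make_incomplete}}, or \code{\link{simulate_cohort}} for the
#' full recipe). The latent values are kept in columns \code{lat1, lat2}
#' alongside \code{ea1, ea2} so estimator tests can compare against truth.
#'
#' Randomness is drawn from named substreams (sexes, PGS, ACE components,
#' derived from \code{seed}) so switching one feature off does not perturb
#' the draws of the others; generation is deterministic given the config.
#'
#' Sex assignment: MZ pairs and half of DZ pairs are same-sex (F/F and M/M
#' equally likely); the remaining DZ pairs are opposite-sex in random order.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed overrides \code{config$seed} when given.
#' @return a \code{twin_data} data frame with latent-truth columns.
#' @export
simulate_twins <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  G <- length(config$mean_girls)
  nmz <- config$n_pairs[, "MZ"]; ndz <- config$n_pairs[, "DZ"]
  n <- sum(nmz) + sum(ndz)
  g <- c(rep(seq_len(G), nmz), rep(seq_len(G), ndz))
  zyg <- c(rep("MZ", sum(nmz)), rep("DZ", sum(ndz)))

  # substream 1: sexes
  set.seed(seed + 1L)
  sex1 <- character(n); sex2 <- character(n)
  mz <- zyg == "MZ"
  same_mz <- sample(c("F", "M"), sum(mz), replace = TRUE)
  sex1[mz] <- same_mz; sex2[mz] <- same_mz
  dz <- which(!mz)
  os <- rep(c(FALSE, TRUE), length.out = length(dz))[sample.int(length(dz))]
  same_dz <- sample(c("F", "M"), sum(!os), replace = TRUE)
  sex1[dz[!os]] <- same_dz; sex2[dz[!os]] <- same_dz
  ord <- sample(c(TRUE, FALSE), sum(os), replace = TRUE)
  sex1[dz[os]] <- ifelse(ord, "F", "M")
  sex2[dz[os]] <- ifelse(ord, "M", "F")

  # substream 2: polygenic scores
  set.seed(seed + 2L)
  pgs1 <- numeric(n); pgs2 <- numeric(n)
  zmz <- stats::rnorm(sum(mz))
  pgs1[mz] <- config$pgs_means[g[mz]] + sqrt(config$pgs_variance) * zmz
  pgs2[mz] <- pgs1[mz]
  pdz <- rbvn_pairs(length(dz), 0, config$pgs_variance,
                    config$pgs_dz_correlation)
  pgs1[dz] <- config$pgs_means[g[dz]] + pdz[, 1]
  pgs2[dz] <- config$pgs_means[g[dz]] + pdz[, 2]

  # substream 3: ACE components
  set.seed(seed + 3L)
  res_a2 <- config$a2 - config$beta_pgs^2 * config$pgs_variance
  a1 <- numeric(n); a2v <- numeric(n)
  rmz <- stats::rnorm(sum(mz))
  a1[mz] <- sqrt(res_a2[g[mz]]) * rmz
  a2v[mz] <- a1[mz]
  radz <- rbvn_pairs(length(dz), 0, 1, 0.5)
  a1[dz] <- sqrt(res_a2[g[dz]]) * radz[, 1]
  a2v[dz] <- sqrt(res_a2[g[dz]]) * radz[, 2]
  cc <- sqrt(config$c2[g]) * stats::rnorm(n)
  ee1 <- sqrt(config$e2[g]) * stats::rnorm(n)
  ee2 <- sqrt(config$e2[g]) * stats::rnorm(n)

  base <- config$mean_girls[g]
  bsx <- config$sex_effect[g]
  pc <- config$pgs_means[g]
  lat1 <- base + bsx * (sex1 == "M") +
    config$beta_pgs * (pgs1 - pc) + a1 + cc + ee1
  lat2 <- base + bsx * (sex2 == "M") +
    config$beta_pgs * (pgs2 - pc) + a2v + cc + ee2

  df <- data.frame(
    family_id = sprintf("fam%05d", seq_len(n)),
    zygosity = zyg, ses = g, sex1 = sex1, sex2 = sex2,
    ea1 = lat1, ea2 = lat2, cens1 = FALSE, cens2 = FALSE,
    pgs1 = pgs1, pgs2 = pgs2, lat1 = lat1, lat2 = lat2,
    stringsAsFactors = FALSE)
  class(df) <- c("twin_data", "data.frame")
  attr(df, "threshold") <- config$threshold
  attr(df, "floor_value") <- config$floor_value
  df
}

#' Apply ceiling censoring (and floor clipping) to latent scores
#'
#' Replaces every score at or above \code{threshold} by the threshold and
#' sets its censoring flag — the test records only that the child reached
#' the maximum. Scores below \code{floor_value} are clipped to the floor
#' \emph{without} a flag: the instrument's floor is not modeled in the
#' likelihood (its mass is negligible under realistic parameters).
#'
#' @param data a \code{twin_data} data frame with scores in \code{ea1, ea2}.
#' @param threshold censoring threshold; \code{Inf} leaves the data
#'   untouched.
#' @param floor_value lower clip; \code{-Inf} disables it.
#' @return the censored dataset.
#' @export
apply_censoring <- function(data, threshold = 550, floor_value = 501) {
  if (threshold <= floor_value)
    stop("apply_censoring: threshold must exceed floor_value")
  for (side in 1:2) {
    ea <- paste0("ea", side); cn <- paste0("cens", side)
    hit <- !is.na(data[[ea]]) & data[[ea]] >= threshold
    data[[ea]][hit] <- threshold
    data[[cn]] <- hit
    if (is.finite(floor_value)) {
      lo <- !is.na(data[[ea]]) & data[[ea]] < floor_value
      data[[ea]][lo] <- floor_value
    }
  }
  attr(data, "threshold") <- threshold
  data
}

#' Make a fraction of pairs incomplete
#'
#' In a uniformly random subset of pairs of the given fraction, exactly one
#' twin (random side) has their score set missing. No pair ever loses both
#' scores. Polygenic scores are untouched.
#'
#' @param data a \code{twin_data} data frame.
#' @param fraction proportion of pairs to make incomplete, in \eqn{[0, 1)}.
#' @param seed seed for the missingness substream.
#' @return the dataset with missing scores.
#' @export
make_incomplete <- function(data, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0 || nrow(data) == 0L) return(data)
  set.seed(seed + 4L)
  n_miss <- round(fraction * nrow(data))
  rows <- sample.int(nrow(data), n_miss)
  side <- sample(1:2, n_miss, replace = TRUE)
  for (s in 1:2) {
    r <- rows[side == s]
    data[[paste0("ea", s)]][r] <- NA_real_
    data[[paste0("cens", s)]][r] <- FALSE
  }
  data
}

#' Simulate a complete analysis-ready cohort
#'
#' Convenience wrapper: \code{\link{simulate_twins}}, then
#' \code{\link{apply_censoring}} at the configured threshold, then
#' \code{\link{make_incomplete}} at the configured fraction. The generating
#' config is attached as attribute \code{truth}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed overrides \code{config$seed}.
#' @return a censored, possibly incomplete \code{twin_data} cohort.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  d <- simulate_twins(config, seed = seed)
  d <- apply_censoring(d, config$threshold, config$floor_value)
  d <- make_incomplete(d, config$incomplete_fraction, seed = seed)
  attr(d, "truth") <- config
  d
}

#' Write the generating parameters of a configuration as JSON
#'
#' Persists the full generating model (the "truth manifest") next to a
#' simulated CSV so parameter-recovery tests can compare estimates against
#' truth without re-deriving it.
#'
#' @param config a \code{\link{sim_config}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_truth_manifest <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$n_pairs <- list(MZ = x$n_pairs[, "MZ"], DZ = x$n_pairs[, "DZ"])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
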