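#' Z-score the polygenic scores on the analysis sample
#'
#' Centers and scales both twins' PGS by the mean and SD over all children
#' with a score present (MZ co-twins therefore both count, with identical
#' values). Upstream corrections (ancestry principal components, array
#' effects) are assumed already done.
#'
#' @param data a \code{twin_data} dataset.
#' @return the dataset with standardized \code{pgs1, pgs2}.
#' @export
standardize_pgs <- function(data) {
  v <- c(data$pgs1, data$pgs2)
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("standardize_pgs: no polygenic scores present")
  m <- mean(v); s <- stats::sd(v)
  if (s <= 0) stop("standardize_pgs: polygenic scores are constant")
  data$pgs1 <- (data$pgs1 - m) / s
  data$pgs2 <- (data$pgs2 - m) / s
  data
}

# ---- PGS distribution model ---------------------------------------------
# One informative value per MZ pair (co-twins are genetically identical);
# DZ pairs bivariate normal with a free within-pair correlation shared
# across groups. No censoring: the PGS is a continuous unbounded score.
pgs_dist_m2ll_data <- function(data) {
  mz <- data$zygosity == "MZ"
  p1 <- data$pgs1; p2 <- data$pgs2
  mzv <- ifelse(is.na(p1[mz]), p2[mz], p1[mz])
  both <- !is.na(p1[mz]) & !is.na(p2[mz])
  if (any(both)) {
    d <- abs(p1[mz][both] - p2[mz][both])
    if (any(d > 1e-6))
      mzv[both] <- (p1[mz][both] + p2[mz][both]) / 2
  }
  y1 <- c(mzv, p1[!mz])
  y2 <- c(rep(NA_real_, length(mzv)), p2[!mz])
  g <- c(data$ses[mz], data$ses[!mz])
  dz <- c(rep(FALSE, length(mzv)), rep(TRUE, sum(!mz)))
  keep <- !(is.na(y1) & is.na(y2))
  list(y1 = y1[keep], y2 = y2[keep], g = g[keep], dz = dz[keep],
       n_units = sum(keep))
}

fit_pgs_dist <- function(pd, means, variances, G) {
  nm <- if (means == "by_ses") G else 1L
  nv <- if (variances == "by_ses") G else 1L
  n <- length(pd$y1)
  m2 <- function(th) {
    mu <- rep_len(th[seq_len(nm)], G)[pd$g]
    s2 <- rep_len(exp(2 * th[nm + seq_len(nv)]), G)[pd$g]
    rho <- tanh(th[nm + nv + 1L])
    cv <- ifelse(pd$dz, rho * s2, 0)
    cens_m2ll(pd$y1, pd$y2, rep(FALSE, n), rep(FALSE, n), mu, mu, s2, s2,
              cv, Inf)
  }
  allv <- c(pd$y1, pd$y2)
  th0 <- c(rep(mean(allv, na.rm = TRUE), nm),
           rep(log(stats::sd(allv, na.rm = TRUE)), nv), atanh(0.5))
  o <- stats::nlminb(th0, m2, control = list(eval.max = 3000L,
                                             iter.max = 800L,
                                             rel.tol = 1e-10))
  list(mean = rep_len(o$par[seq_len(nm)], G),
       variance = rep_len(exp(2 * o$par[nm + seq_len(nv)]), G),
       dz_correlation = tanh(o$par[nm + nv + 1L]),
       minus2ll = o$objective, n_free = nm + nv + 1L,
       converged = o$convergence == 0)
}

#' SES-stratified PGS means and variances with equality tests
#'
#' Fits the polygenic-score distribution with means and variances
#' stratified by SES group (MZ pairs contribute one value, DZ pairs a
#' bivariate normal with free within-pair correlation), then compares
#' against models equating the means or the variances across groups by
#' likelihood-ratio tests (3 df each with four groups).
#'
#' @param data a \code{twin_data} dataset with PGS present in every SES
#'   group.
#' @return a list: \code{stratified}, \code{means_equated},
#'   \code{variances_equated} fits, and \code{means_test},
#'   \code{variances_test} likelihood-ratio results.
#' @export
pgs_by_ses_tests <- function(data) {
  stopifnot(inherits(data, "twin_data"))
  G <- max(data$ses)
  has <- !is.na(data$pgs1) | !is.na(data$pgs2)
  cover <- sort(unique(data$ses[has]))
  if (!all(seq_len(G) %in% cover))
    stop("pgs_by_ses_tests: SES group(s) without polygenic scores: ",
         paste(setdiff(seq_len(G), cover), collapse = ", "))
  pd <- pgs_dist_m2ll_data(data)
  full <- fit_pgs_dist(pd, "by_ses", "by_ses", G)
  meq <- fit_pgs_dist(pd, "shared", "by_ses", G)
  veq <- fit_pgs_dist(pd, "by_ses", "shared", G)
  list(stratified = full, means_equated = meq, variances_equated = veq,
       means_test = new_lrt(meq$minus2ll - full$minus2ll,
                            full$n_free - meq$n_free, "PGS means by SES"),
       variances_test = new_lrt(veq$minus2ll - full$minus2ll,
                                full$n_free - veq$n_free,
                                "PGS variances by SES"),
       n_units = pd$n_units)
}

#' Between-family EA-on-PGS regression inside the censored twin model
#'
#' Regresses achievement on the child's polygenic score and sex within each
#' SES group, jointly with the residual ACE decomposition, under the
#' censored pair likelihood. Equality of slopes or intercepts across groups
#' is testable with \code{\link{lrt}} against the correspondingly equated
#' spec.
#'
#' @param data a \code{twin_data} dataset with PGS.
#' @param slopes \code{"by_ses"} (group-specific PGS slopes) or
#'   \code{"shared"}.
#' @param intercepts \code{"by_ses"} or \code{"shared"}.
#' @param variances residual ACE stratification, \code{"by_ses"} or
#'   \code{"shared"}.
#' @param censoring,threshold censoring correction switches.
#' @param ... passed to \code{\link{fit_twin_model}}.
#' @return a \code{twin_fit}.
#' @export
ea_on_pgs_fit <- function(data, slopes = c("by_ses", "shared"),
                          intercepts = c("by_ses", "shared"),
                          variances = c("by_ses", "shared"),
                          censoring = TRUE, threshold = 550, ...) {
  slopes <- match.arg(slopes)
  intercepts <- match.arg(intercepts)
  variances <- match.arg(variances)
  spec <- twin_spec(means = if (intercepts == "by_ses") "by_ses" else "shared",
                    variances = variances, include_c = TRUE, sex = "shared",
                    pgs = slopes, censoring = censoring,
                    threshold = threshold)
  fit_twin_model(data, spec, ...)
}

#' Within-pair DZ polygenic-score correlation
#'
#' Maximum-likelihood bivariate-normal correlation of the polygenic scores
#' of complete DZ pairs, with a profile-likelihood confidence interval. The
#' biometrical expectation is 0.5; assortative mating pushes it upward. MZ
#' pairs carry no information (their correlation is 1 by identity) and are
#' rejected if they are all that is supplied.
#'
#' @param data a \code{twin_data} dataset.
#' @param level confidence level.
#' @return a list: \code{r}, \code{lower}, \code{upper}, \code{n_pairs}.
#' @export
dz_pgs_correlation <- function(data, level = 0.95) {
  stopifnot(inherits(data, "twin_data"))
  dz <- data$zygosity == "DZ" & !is.na(data$pgs1) & !is.na(data$pgs2)
  if (sum(dz) < 2L) {
    if (any(data$zygosity == "MZ" & !is.na(data$pgs1) & !is.na(data$pgs2)))
      stop("dz_pgs_correlation: only MZ pairs supplied; the MZ PGS ",
           "correlation is fixed at 1 and carries no information")
    stop("dz_pgs_correlation: fewer than 2 complete DZ pairs with PGS")
  }
  f <- sat_pair_fit(data$pgs1[dz], data$pgs2[dz],
                    rep(FALSE, sum(dz)), rep(FALSE, sum(dz)),
                    Inf, censoring = FALSE)
  b <- sat_rho_ci(f, level)
  list(r = f$rho, lower = b[["lower"]], upper = b[["upper"]],
       n_pairs = sum(dz), level = level)
}

#' Within-family test: does the higher-PGS DZ twin score higher?
#'
#' Orders each complete DZ pair by polygenic score and estimates the mean
#' achievement gap (higher-PGS twin minus co-twin) under the censored pair
#' likelihood, with SES-group means absorbing family-level differences and
#' (optionally) the within-pair sex contrast as a covariate. The gap is
#' tested against a zero-gap nested model with a 1-df likelihood-ratio
#' test. Because both twins share the family's SES, a significant gap
#' demonstrates a PGS effect on achievement free of SES confounding.
#'
#' An ordinary-least-squares sensitivity estimator (pair score difference
#' regressed on an intercept and the sex contrast) is reported alongside.
#'
#' @param data a \code{twin_data} dataset.
#' @param adjust_sex include the within-pair sex contrast.
#' @param censoring,threshold censoring correction switches.
#' @return a list of class \code{within_family_result}: \code{mean_pgs_gap},
#'   \code{mean_ea_gap}, \code{gap_ols}, \code{lrt}, \code{n_pairs},
#'   \code{n_ties_dropped}.
#' @export
within_family_test <- function(data, adjust_sex = TRUE, censoring = TRUE,
                               threshold = 550) {
  stopifnot(inherits(data, "twin_data"))
  dz <- data$zygosity == "DZ" & !is.na(data$pgs1) & !is.na(data$pgs2) &
    !is.na(data$ea1) & !is.na(data$ea2)
  ties <- dz & data$pgs1 == data$pgs2
  n_ties <- sum(ties)
  if (n_ties > 0L)
    message("within_family_test: dropping ", n_ties,
            " pair(s) with exactly tied PGS")
  d <- data[dz & !ties, , drop = FALSE]
  if (nrow(d) < 10L)
    stop("within_family_test: fewer than 10 usable complete DZ pairs")
  swap <- d$pgs2 > d$pgs1
  hi <- function(a, b) ifelse(swap, b, a)
  p_hi <- hi(d$pgs1, d$pgs2); p_lo <- hi(d$pgs2, d$pgs1)
  y_hi <- hi(d$ea1, d$ea2);  y_lo <- hi(d$ea2, d$ea1)
  c_hi <- hi(d$cens1 %in% TRUE, d$cens2 %in% TRUE)
  c_lo <- hi(d$cens2 %in% TRUE, d$cens1 %in% TRUE)
  m_hi <- as.numeric(hi(d$sex1, d$sex2) == "M")
  m_lo <- as.numeric(hi(d$sex2, d$sex1) == "M")
  if (!censoring) { c_hi[] <- FALSE; c_lo[] <- FALSE }

  gl <- sort(unique(d$ses))
  gi <- match(d$ses, gl)
  k <- length(gl)
  n <- nrow(d)
  m2 <- function(th, free_delta) {
    mu_g <- th[seq_len(k)]
    delta <- if (free_delta) th[k + 1L] else 0
    off <- k + as.integer(free_delta)
    bsx <- if (adjust_sex) th[off + 1L] else 0
    off <- off + as.integer(adjust_sex)
    s2 <- exp(2 * th[off + 1L])
    rho <- tanh(th[off + 2L])
    mu1 <- mu_g[gi] + delta + bsx * m_hi
    mu2 <- mu_g[gi] + bsx * m_lo
    cens_m2ll(y_hi, y_lo, c_hi, c_lo, mu1, mu2,
              rep(s2, n), rep(s2, n), rep(rho * s2, n), threshold)
  }
  mu0 <- vapply(gl, function(gg) mean(c(y_hi[d$ses == gg],
                                        y_lo[d$ses == gg])), numeric(1))
  s0 <- log(stats::sd(c(y_hi, y_lo)))
  base <- c(mu0, if (adjust_sex) 0.5, s0, atanh(0.4))
  o1 <- stats::nlminb(append(base, 0, after = k),
                      function(th) m2(th, TRUE),
                      control = list(eval.max = 3000L, iter.max = 800L,
                                     rel.tol = 1e-10))
  o0 <- stats::nlminb(base, function(th) m2(th, FALSE),
                      control = list(eval.max = 3000L, iter.max = 800L,
                                     rel.tol = 1e-10))
  delta_hat <- o1$par[k + 1L]

  dy <- y_hi - y_lo
  ols <- if (adjust_sex) stats::lm(dy ~ I(m_hi - m_lo))
         else stats::lm(dy ~ 1)
  structure(list(
    mean_pgs_gap = mean(p_hi - p_lo),
    mean_ea_gap = delta_hat,
    gap_ols = unname(stats::coef(ols)[1]),
    lrt = new_lrt(o0$objective - o1$objective, 1L, "within-family PGS gap"),
    minus2ll = o1$objective,
    n_pairs = n, n_ties_dropped = n_ties,
    converged = o1$convergence == 0 && o0$convergence == 0
  ), class = "within_family_result")
}

#' @export
print.within_family_result <- function(x, ...) {
  cat(sprintf(
    "Within-family DZ contrast (%d pairs): higher-PGS twin leads by %.2f SD of PGS\n",
    x$n_pairs, x$mean_pgs_gap))
  cat(sprintf("  mean achievement gap: %.2f points (OLS sensitivity: %.2f)\n",
              x$mean_ea_gap, x$gap_ols))
  print(x$lrt)
  invisible(x)
}
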