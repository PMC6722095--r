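# -------------------------------------------------------------------------
# Vectorized censored bivariate-normal -2 log-likelihood kernel.
#
# Each twin pair contributes according to its observation pattern:
#   OO  both observed          bivariate normal log-density
#   OC  one observed, one at   density(obs) * P(other > t | obs), using the
#       the ceiling            conditional univariate normal
#   CC  both at the ceiling    P(Y1 > t, Y2 > t), a bvn rectangle
#   O_  singleton observed     univariate log-density
#   C_  singleton at ceiling   univariate survival
#
# y NA means the twin's score is missing (incomplete pair); a censoring flag
# TRUE means the stored value equals the threshold. All moment vectors are
# full length n. Returns +Inf on any infeasible (non-PD) moment row so the
# optimizer treats the point as out of bounds.
# -------------------------------------------------------------------------
cens_m2ll <- function(y1, y2, c1, c2, mu1, mu2, v1, v2, cv, threshold) {
  n <- length(y1)
  if (n == 0L) return(0)
  if (any(!is.finite(v1)) || any(!is.finite(v2)) ||
      any(v1 <= 0) || any(v2 <= 0) || any(cv * cv >= v1 * v2 * (1 + 1e-12)))
    return(Inf)
  s1 <- sqrt(v1); s2 <- sqrt(v2)
  rho <- cv / (s1 * s2)
  rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)

  m1 <- is.na(y1); m2 <- is.na(y2)
  ll <- numeric(n)

  both <- !m1 & !m2
  oo <- both & !c1 & !c2
  oc <- both & !c1 & c2
  co <- both & c1 & !c2
  cc <- both & c1 & c2

  if (any(oo)) {
    z1 <- (y1[oo] - mu1[oo]) / s1[oo]
    z2 <- (y2[oo] - mu2[oo]) / s2[oo]
    r <- rho[oo]
    omr2 <- 1 - r * r
    ll[oo] <- -log(2 * pi) - log(s1[oo]) - log(s2[oo]) - 0.5 * log(omr2) -
      (z1 * z1 - 2 * r * z1 * z2 + z2 * z2) / (2 * omr2)
  }
  cond_tail <- function(yo, muo, so, muc, sc, r) {
    # log P(Yc > threshold | Yo = yo)
    zm <- muc + r * sc * (yo - muo) / so
    zs <- sc * sqrt(1 - r * r)
    stats::pnorm((threshold - zm) / zs, lower.tail = FALSE, log.p = TRUE)
  }
  if (any(oc)) {
    ll[oc] <- stats::dnorm(y1[oc], mu1[oc], s1[oc], log = TRUE) +
      cond_tail(y1[oc], mu1[oc], s1[oc], mu2[oc], s2[oc], rho[oc])
  }
  if (any(co)) {
    ll[co] <- stats::dnorm(y2[co], mu2[co], s2[co], log = TRUE) +
      cond_tail(y2[co], mu2[co], s2[co], mu1[co], s1[co], rho[co])
  }
  if (any(cc)) {
    hs <- (threshold - mu1[cc]) / s1[cc]
    ks <- (threshold - mu2[cc]) / s2[cc]
    ll[cc] <- log(pmax(pbvn_upper_vec(hs, ks, rho[cc]), 1e-300))
  }
  s_o <- m2 & !m1 & !c1
  s_c <- m2 & !m1 & c1
  if (any(s_o)) ll[s_o] <- stats::dnorm(y1[s_o], mu1[s_o], s1[s_o], log = TRUE)
  if (any(s_c)) ll[s_c] <- stats::pnorm((threshold - mu1[s_c]) / s1[s_c],
                                        lower.tail = FALSE, log.p = TRUE)
  t_o <- m1 & !m2 & !c2
  t_c <- m1 & !m2 & c2
  if (any(t_o)) ll[t_o] <- stats::dnorm(y2[t_o], mu2[t_o], s2[t_o], log = TRUE)
  if (any(t_c)) ll[t_c] <- stats::pnorm((threshold - mu2[t_c]) / s2[t_c],
                                        lower.tail = FALSE, log.p = TRUE)

  tot <- sum(ll)
  if (!is.finite(tot)) return(Inf)
  -2 * tot
}

#' Log-likelihood of a single twin pair under the censored bivariate normal
#'
#' Evaluates the exact log-likelihood contribution of one twin pair given
#' its pair moments, covering every observation pattern: both scores
#' observed, one or both right-censored at the threshold, and singleton
#' (incomplete-pair) observations, censored or not.
#'
#' @param y1,y2 observed scores; \code{NA} for a missing twin. A censored
#'   score must be stored as the threshold value.
#' @param c1,c2 logical right-censoring flags.
#' @param mu1,mu2 means of the pair under the model.
#' @param v1,v2 variances (must be positive).
#' @param cov covariance; the implied correlation must lie strictly inside
#'   \eqn{(-1, 1)} for censored patterns.
#' @param threshold the fixed censoring threshold.
#' @return the log-likelihood (a scalar).
#' @examples
#' # independence: the pair log-density factorizes
#' pair_loglik(540, 530, FALSE, FALSE, 535, 535, 81, 81, 0, 550)
#' dnorm(540, 535, 9, log = TRUE) + dnorm(530, 535, 9, log = TRUE)
#' @export
pair_loglik <- function(y1, y2, c1, c2, mu1, mu2, v1, v2, cov,
                        threshold = 550) {
  if (is.na(y1) && is.na(y2))
    stop("pair_loglik: both scores missing; the pair carries no information")
  if (!is.finite(v1) || !is.finite(v2) || v1 <= 0 || v2 <= 0 ||
      cov * cov >= v1 * v2)
    stop("pair_loglik: pair moments are not positive definite")
  if (isTRUE(c1) && (is.na(y1) || abs(y1 - threshold) > 1e-8))
    stop("pair_loglik: censored score must equal the threshold")
  if (isTRUE(c2) && (is.na(y2) || abs(y2 - threshold) > 1e-8))
    stop("pair_loglik: censored score must equal the threshold")
  -0.5 * cens_m2ll(y1, y2, isTRUE(c1), isTRUE(c2), mu1, mu2, v1, v2, cov,
                   threshold)
}

#' Deviance (-2 log-likelihood) of a twin dataset under given pair moments
#'
#' Sums \code{\link{pair_loglik}} over a dataset, with one row of moments
#' per pair, and returns \eqn{-2\sum_i \ell_i} — the fit statistic used for
#' all model comparisons.
#'
#' @param data a \code{twin_data} data frame (see
#'   \code{\link{as_twin_data}}).
#' @param moments a data frame with columns \code{mu1, mu2, v1, v2, cov} and
#'   one row per pair in \code{data}.
#' @param threshold censoring threshold (default 550).
#' @return the deviance, a finite scalar (0 for an empty dataset).
#' @export
twin_minus2ll <- function(data, moments, threshold = 550) {
  if (nrow(data) == 0L) return(0)
  if (nrow(moments) != nrow(data))
    stop("twin_minus2ll: one row of moments per pair is required")
  need <- c("mu1", "mu2", "v1", "v2", "cov")
  if (!all(need %in% names(moments)))
    stop("twin_minus2ll: moments must have columns ",
         paste(need, collapse = ", "))
  if (any(is.na(data$ea1) & is.na(data$ea2)))
    stop("twin_minus2ll: pairs with both scores missing are not allowed")
  if (any(moments$v1 <= 0 | moments$v2 <= 0 |
          moments$cov^2 >= moments$v1 * moments$v2))
    stop("twin_minus2ll: non-positive-definite pair moments")
  out <- cens_m2ll(data$ea1, data$ea2, data$cens1 %in% TRUE,
                   data$cens2 %in% TRUE, moments$mu1, moments$mu2,
                   moments$v1, moments$v2, moments$cov, threshold)
  if (!is.finite(out)) stop("twin_minus2ll: likelihood is not finite")
  out
}
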