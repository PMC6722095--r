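# saturated censored bivariate-normal fit on a set of pairs:
# theta = (mu1, mu2, log s1, log s2, atanh rho)
sat_pair_fit <- function(y1, y2, c1, c2, threshold, censoring = TRUE) {
  if (!censoring) { c1[] <- FALSE; c2[] <- FALSE }
  comp <- !(is.na(y1) | is.na(y2))
  if (sum(comp) < 2L)
    stop("twin correlation: at least 2 complete pairs are required")
  if (all(c1[comp] & c2[comp]))
    stop("twin correlation: all complete pairs censored; correlation not estimable")
  m2 <- function(th) {
    cens_m2ll(y1, y2, c1, c2, rep(th[1], length(y1)), rep(th[2], length(y1)),
              rep(exp(2 * th[3]), length(y1)), rep(exp(2 * th[4]), length(y1)),
              rep(tanh(th[5]) * exp(th[3] + th[4]), length(y1)), threshold)
  }
  m1 <- mean(y1, na.rm = TRUE); mm2 <- mean(y2, na.rm = TRUE)
  s1 <- stats::sd(y1, na.rm = TRUE); s2 <- stats::sd(y2, na.rm = TRUE)
  if (!is.finite(s1) || s1 <= 0) s1 <- 5
  if (!is.finite(s2) || s2 <= 0) s2 <- 5
  r0 <- suppressWarnings(stats::cor(y1[comp], y2[comp]))
  if (!is.finite(r0)) r0 <- 0.5
  r0 <- max(min(r0, 0.98), -0.98)
  th0 <- c(m1, mm2, log(s1), log(s2), atanh(r0))
  o <- stats::nlminb(th0, m2, control = list(eval.max = 3000L,
                                             iter.max = 800L,
                                             rel.tol = 1e-10))
  list(mu = c(o$par[1], o$par[2]), sd = exp(o$par[3:4]),
       rho = tanh(o$par[5]), minus2ll = o$objective, theta = o$par,
       converged = o$convergence == 0, n_pairs = length(y1),
       n_complete = sum(comp), obj = m2)
}

# profile-likelihood CI on the correlation of a saturated pair fit
sat_rho_ci <- function(fit, level = 0.95) {
  target <- fit$minus2ll + stats::qchisq(level, 1)
  prof <- function(z) {
    fn <- function(th4) fit$obj(c(th4[1], th4[2], th4[3], th4[4], z))
    stats::nlminb(fit$theta[1:4], fn,
                  control = list(iter.max = 400L, rel.tol = 1e-9))$objective
  }
  zhat <- atanh(max(min(fit$rho, 1 - 1e-8), -1 + 1e-8))
  find <- function(dir) {
    step <- 0.1
    lo <- zhat
    for (i in 1:60) {
      cand <- zhat + dir * step * i
      if (prof(cand) > target)
        return(stats::uniroot(function(z) prof(z) - target,
                              lower = min(lo, cand), upper = max(lo, cand),
                              tol = 1e-5)$root)
      lo <- cand
    }
    NA_real_
  }
  tanh(c(lower = find(-1), upper = find(+1)))
}

#' Censoring-corrected twin correlation under the saturated model
#'
#' Maximum-likelihood estimate of the within-pair correlation under the
#' (censored) bivariate normal saturated model — free means, free
#' variances, free correlation — for the requested zygosity, overall or per
#' SES group. With no censored scores the estimate coincides with the
#' product-moment correlation of the complete pairs.
#'
#' @param data a \code{twin_data} dataset.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @param censoring apply the censoring correction (default TRUE).
#' @param by_ses estimate per SES group instead of marginally.
#' @param ci compute a profile-likelihood confidence interval.
#' @param level confidence level.
#' @return a data frame with columns \code{group, r, lower, upper,
#'   n_pairs}.
#' @export
twin_correlation <- function(data, zygosity = c("MZ", "DZ"),
                             censoring = TRUE, by_ses = FALSE,
                             ci = FALSE, level = 0.95) {
  zygosity <- match.arg(zygosity)
  stopifnot(inherits(data, "twin_data"))
  d <- data[data$zygosity == zygosity, , drop = FALSE]
  if (nrow(d) == 0L) stop("twin_correlation: no ", zygosity, " pairs")
  threshold <- attr(data, "threshold")
  if (is.null(threshold)) threshold <- 550
  groups <- if (by_ses) sort(unique(d$ses)) else NA_integer_
  out <- lapply(groups, function(gg) {
    dd <- if (is.na(gg)) d else d[d$ses == gg, , drop = FALSE]
    f <- sat_pair_fit(dd$ea1, dd$ea2, dd$cens1 %in% TRUE, dd$cens2 %in% TRUE,
                      threshold, censoring)
    b <- if (ci) sat_rho_ci(f, level) else c(lower = NA_real_,
                                             upper = NA_real_)
    data.frame(group = if (is.na(gg)) "all" else ses_labels[gg],
               r = f$rho, lower = b[["lower"]], upper = b[["upper"]],
               n_pairs = f$n_complete, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
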