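# partial order on spec dimensions: is `nested` a restriction of `parent`?
rank_of <- function(x) c(none = 0L, shared = 1L, by_ses = 2L)[[x]]

is_nested_spec <- function(parent, nested) {
  if (parent$censoring != nested$censoring ||
      !isTRUE(all.equal(parent$threshold, nested$threshold))) return(FALSE)
  ok <- rank_of(nested$means) <= rank_of(parent$means) &&
    rank_of(nested$variances) <= rank_of(parent$variances) &&
    rank_of(nested$sex) <= rank_of(parent$sex) &&
    rank_of(nested$pgs) <= rank_of(parent$pgs) &&
    (!nested$include_c || parent$include_c)
  if (!ok) return(FALSE)
  if (identical(nested$sex, "by_ses") && identical(parent$sex, "by_ses")) {
    pf <- if (is.null(parent$sex_free)) TRUE else parent$sex_free
    nf <- if (is.null(nested$sex_free)) TRUE else nested$sex_free
    G <- max(length(pf), length(nf))
    if (any(rep_len(nf, G) & !rep_len(pf, G))) return(FALSE)
  }
  TRUE
}

# internal constructor shared by all model families
new_lrt <- function(delta, df, label = NULL) {
  delta <- max(0, delta)
  structure(list(delta_minus2ll = delta, delta_df = as.integer(df),
                 p_value = stats::pchisq(delta, df, lower.tail = FALSE),
                 label = label), class = "twin_lrt")
}

#' Likelihood-ratio test of nested twin models
#'
#' Twice the log-likelihood difference between a model and a nested
#' restriction is asymptotically chi-squared with degrees of freedom equal
#' to the number of restricted parameters. The difference is clipped at 0
#' (a nested model can beat its parent only by optimizer noise).
#'
#' @param parent the richer \code{twin_fit}.
#' @param nested the restricted \code{twin_fit}.
#' @return a \code{twin_lrt}: \code{delta_minus2ll}, \code{delta_df},
#'   \code{p_value}.
#' @export
lrt <- function(parent, nested) {
  stopifnot(inherits(parent, "twin_fit"), inherits(nested, "twin_fit"))
  if (!is_nested_spec(parent$spec, nested$spec))
    stop("lrt: the second model is not a restriction of the first")
  df <- parent$n_free - nested$n_free
  if (df <= 0L) stop("lrt: nested model must have fewer free parameters")
  if (parent$n_pairs != nested$n_pairs)
    stop("lrt: fits use different numbers of pairs; refit on common data")
  new_lrt(nested$minus2ll - parent$minus2ll, df)
}

#' @export
print.twin_lrt <- function(x, ...) {
  cat(sprintf("LRT%s: delta(-2logL) = %.2f, df = %d, p = %s\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              x$delta_minus2ll, x$delta_df, format.pval(x$p_value, 3)))
  invisible(x)
}

#' Profile-likelihood confidence interval for a fitted parameter
#'
#' Bounds are the parameter values at which the profile deviance (with all
#' other parameters re-optimized) rises above the minimum by the
#' chi-squared(1) quantile of the requested level. Variance components are
#' profiled on the SD scale and reported on the variance scale; when the
#' profile at 0 stays below the cutoff the lower bound is exactly 0.0,
#' matching the boundary behavior of common-environment estimates.
#'
#' @param fit a converged \code{twin_fit}.
#' @param parameter a parameter name as printed in the fit's map, e.g.
#'   \code{"b0[2]"}, \code{"bsex"}, \code{"sd_c[1]"}; variance aliases
#'   \code{"a2[1]"}, \code{"c2"}, \code{"e2[3]"} are accepted and reported
#'   as variances.
#' @param level confidence level in (0, 1).
#' @param max_expand maximum number of bracketing expansions per bound.
#' @return named vector \code{c(lower, upper)}; a bound that cannot be
#'   bracketed is \code{NA} with a warning.
#' @export
profile_ci <- function(fit, parameter, level = 0.95, max_expand = 40L) {
  stopifnot(inherits(fit, "twin_fit"), level > 0, level < 1)
  if (!fit$converged)
    warning("profile_ci: fit not flagged converged; interval may be off")
  pm <- fit$parmap
  par_in <- parameter
  vscale <- grepl("^(a2|c2|e2)", parameter)
  if (vscale)
    parameter <- sub("^e2", "sd_e", sub("^c2", "sd_c",
                                        sub("^a2", "sd_a", parameter)))
  j <- match(parameter, pm$name)
  if (is.na(j)) stop("profile_ci: unknown parameter '", par_in, "'")
  spec <- fit$spec
  pd <- prep_model_data(fit$data, spec)
  obj <- make_objective(pd, pm, spec)
  base_fixed <- pm$fixed | !fit$free
  target <- fit$minus2ll + stats::qchisq(level, 1)
  theta_hat <- fit$theta
  is_sd <- pm$slot[j] %in% c("sd_a", "sd_c", "sd_e")

  prof <- function(val) {
    free <- !base_fixed
    free[j] <- FALSE
    th <- theta_hat
    th[j] <- val
    fn <- function(fr) { full <- th; full[free] <- fr; obj(full) }
    if (!any(free)) return(obj(th))
    stats::nlminb(th[free], fn,
                  control = list(eval.max = 2000L, iter.max = 500L,
                                 rel.tol = 1e-9))$objective
  }

  # step scale from a crude curvature probe
  est <- theta_hat[j]
  h <- max(abs(est) * 0.05, 0.05)
  curv <- (prof(est + h) + prof(est - h) - 2 * fit$minus2ll) / h^2
  step <- if (is.finite(curv) && curv > 0)
    sqrt(2 * stats::qchisq(level, 1) / curv) / 2 else max(abs(est) * 0.5, 1)

  bound <- function(dir) {
    lo <- est
    hi <- est
    found <- FALSE
    for (i in seq_len(max_expand)) {
      cand <- est + dir * step * i
      if (is_sd && dir < 0 && cand <= 0) {
        if (prof(0) <= target) return(0)   # pinned at the variance boundary
        cand <- max(cand, 1e-9)
      }
      if (prof(cand) > target) { hi <- cand; found <- TRUE; break }
      lo <- cand
    }
    if (!found) {
      warning("profile_ci: could not bracket the ",
              if (dir < 0) "lower" else "upper", " bound for ", par_in)
      return(NA_real_)
    }
    stats::uniroot(function(x) prof(x) - target, lower = min(lo, hi),
                   upper = max(lo, hi), tol = 1e-4)$root
  }
  up <- bound(+1)
  lo <- bound(-1)
  if (is_sd && !is.na(lo)) lo <- max(lo, 0)
  out <- if (vscale) c(lower = lo^2, upper = up^2) else c(lower = lo, upper = up)
  if (!anyNA(out)) out <- c(lower = min(out), upper = max(out))
  attr(out, "level") <- level
  attr(out, "parameter") <- par_in
  out
}
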