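# ---- data preparation for fitting ---------------------------------------
# Resolves the per-pair quantities the likelihood needs: SES group index,
# zygosity coefficient on a2 (1 MZ, 0.5 DZ), per-twin male indicators and
# PGS. When the spec includes a PGS slope, twins without a PGS cannot enter
# the mean model; their score is treated as missing, and pairs left with
# no usable twin are dropped (count recorded).
prep_model_data <- function(data, spec) {
  stopifnot(inherits(data, "twin_data"))
  if (nrow(data) == 0L) stop("fit: dataset is empty")
  y1 <- data$ea1; y2 <- data$ea2
  c1 <- data$cens1 %in% TRUE; c2 <- data$cens2 %in% TRUE
  if (!spec$censoring) { c1[] <- FALSE; c2[] <- FALSE }
  g <- data$ses
  G <- max(g)
  stratified <- spec$means == "by_ses" || spec$variances == "by_ses" ||
    spec$sex == "by_ses" || spec$pgs == "by_ses"
  if (stratified && !all(seq_len(G) %in% g))
    stop("fit: SES group(s) ", paste(setdiff(seq_len(G), unique(g)),
                                     collapse = ", "),
         " have no data but the model is SES-stratified")
  n_dropped <- 0L
  if (spec$pgs != "none") {
    if (all(is.na(data$pgs1)) && all(is.na(data$pgs2)))
      stop("fit: spec includes a PGS slope but no polygenic scores present")
    y1[is.na(data$pgs1)] <- NA; c1[is.na(data$pgs1)] <- FALSE
    y2[is.na(data$pgs2)] <- NA; c2[is.na(data$pgs2)] <- FALSE
  }
  usable <- !(is.na(y1) & is.na(y2))
  n_dropped <- sum(!usable)
  if (spec$pgs == "none" && n_dropped > 0L)
    stop("fit: pairs with both scores missing are not allowed")
  keep <- which(usable)
  if (spec$include_c) {
    zy <- data$zygosity[keep]
    if (!all(c("MZ", "DZ") %in% zy))
      stop("fit: separating A from C requires both MZ and DZ pairs")
  }
  list(y1 = y1[keep], y2 = y2[keep], c1 = c1[keep], c2 = c2[keep],
       g = g[keep], af = ifelse(data$zygosity[keep] == "MZ", 1, 0.5),
       m1 = as.numeric(data$sex1[keep] == "M"),
       m2 = as.numeric(data$sex2[keep] == "M"),
       p1 = data$pgs1[keep], p2 = data$pgs2[keep],
       G = G, n_pairs = length(keep), n_dropped = n_dropped,
       threshold = spec$threshold)
}

# objective factory: full-theta -2 log-likelihood
make_objective <- function(pd, pm, spec) {
  p1 <- pd$p1; p2 <- pd$p2
  if (spec$pgs == "none") { p1 <- rep(0, pd$n_pairs); p2 <- p1 }
  else { p1[is.na(p1)] <- 0; p2[is.na(p2)] <- 0 }
  function(theta) {
    par <- unpack_theta(theta, pm)
    a2 <- par$sd_a[pd$g]^2
    c2 <- par$sd_c[pd$g]^2
    e2 <- par$sd_e[pd$g]^2
    v <- a2 + c2 + e2
    cv <- pd$af * a2 + c2
    mu1 <- par$b0[pd$g] + par$bsex[pd$g] * pd$m1 + par$bpgs[pd$g] * p1
    mu2 <- par$b0[pd$g] + par$bsex[pd$g] * pd$m2 + par$bpgs[pd$g] * p2
    cens_m2ll(pd$y1, pd$y2, pd$c1, pd$c2, mu1, mu2, v, v, cv, pd$threshold)
  }
}

# moment-based starting values (censored values enter as stored; good
# enough as a start, the optimizer does the correction)
moment_starts <- function(pd, pm, spec) {
  G <- pm$G
  ally <- c(pd$y1, pd$y2); allg <- c(pd$g, pd$g)
  allm <- c(pd$m1, pd$m2); allp <- c(pd$p1, pd$p2)
  b0 <- vapply(seq_len(G), function(gg) {
    v <- ally[allg == gg & allm == 0]
    if (sum(!is.na(v)) >= 2L) mean(v, na.rm = TRUE)
    else mean(ally[allg == gg], na.rm = TRUE)
  }, numeric(1))
  b0[!is.finite(b0)] <- mean(ally, na.rm = TRUE)
  bsex <- vapply(seq_len(G), function(gg) {
    d <- mean(ally[allg == gg & allm == 1], na.rm = TRUE) -
      mean(ally[allg == gg & allm == 0], na.rm = TRUE)
    if (is.finite(d)) d else 0
  }, numeric(1))
  vv <- vapply(seq_len(G), function(gg) {
    v <- stats::var(ally[allg == gg], na.rm = TRUE)
    if (is.finite(v) && v > 0) v else 50
  }, numeric(1))
  comp <- !(is.na(pd$y1) | is.na(pd$y2))
  rz <- function(zf) {
    i <- comp & pd$af == zf
    if (sum(i) >= 3L) {
      r <- suppressWarnings(stats::cor(pd$y1[i], pd$y2[i]))
      if (is.finite(r)) return(max(min(r, 0.95), -0.2))
    }
    if (zf == 1) 0.75 else 0.4
  }
  rmz <- rz(1); rdz <- rz(0.5)
  h2 <- min(max(2 * (rmz - rdz), 0.15), 0.9)
  csh <- if (spec$include_c) min(max(2 * rdz - rmz, 0.02), 0.5) else 0
  esh <- max(1 - h2 - csh, 0.08)
  bpgs <- 0
  if (spec$pgs != "none") {
    ok <- !is.na(allp) & !is.na(ally)
    if (sum(ok) > 5L) {
      b <- stats::cov(allp[ok], ally[ok]) / max(stats::var(allp[ok]), 1e-8)
      if (is.finite(b)) bpgs <- b
    }
  }
  start_named <- list(b0 = b0, bsex = bsex, bpgs = rep(bpgs, G),
                      sd_a = sqrt(h2 * vv), sd_c = sqrt(pmax(csh * vv, 0.5)),
                      sd_e = sqrt(esh * vv))
  theta <- numeric(length(pm$slot))
  for (s in unique(pm$slot)) {
    v <- start_named[[s]]
    theta[pm$slot == s] <- if (pm$lens[[s]] == 1L) mean(v) else v
  }
  theta[pm$fixed] <- 0
  theta
}

#' Fit a censored-FIML twin model
#'
#' Maximizes the raw-data full-information likelihood of the twin model
#' described by a \code{\link{twin_spec}} over all free parameters.
#' Incomplete pairs contribute their univariate (possibly censored)
#' likelihood; censored scores contribute tail or rectangle probabilities
#' of the bivariate normal. Variances are optimized on the SD scale, so
#' non-negativity holds by construction and common-environment estimates
#' can sit exactly at the 0 boundary.
#'
#' A deterministic multi-start protocol is used: a moment-based start
#' (group means and variances, twin-correlation-based ACE split) plus
#' perturbed replicates (variance components scaled by fixed factors,
#' intercepts shifted by fixed offsets). The fit is flagged converged when
#' the best start reports optimizer convergence and, with two or more
#' starts, the two best deviances agree within \code{agree_tol}.
#'
#' @param data a \code{twin_data} dataset.
#' @param spec a \code{\link{twin_spec}}.
#' @param n_starts number of optimizer starts (first is the moment start).
#' @param agree_tol agreement tolerance on -2 log-likelihood between the
#'   two best starts.
#' @param start optional full starting vector (advanced use).
#' @param fixed optional named numeric vector pinning parameters (by theta
#'   name, e.g. \code{c("bsex[4]" = 0)}); pinned parameters are not counted
#'   as free.
#' @return a \code{twin_fit} object: estimates (means model and per-group
#'   ACE variances), \code{minus2ll}, free-parameter count, convergence
#'   flag, and the spec.
#' @export
fit_twin_model <- function(data, spec, n_starts = 5L, agree_tol = 1e-4,
                           start = NULL, fixed = NULL) {
  stopifnot(inherits(spec, "twin_spec"))
  pd <- prep_model_data(data, spec)
  pm <- make_parmap(spec, pd$G)
  obj <- make_objective(pd, pm, spec)

  fixed_mask <- pm$fixed
  fixed_val <- numeric(length(pm$slot))
  if (!is.null(fixed)) {
    j <- match(names(fixed), pm$name)
    if (anyNA(j)) stop("fit: unknown fixed parameter(s) ",
                       paste(names(fixed)[is.na(j)], collapse = ", "))
    fixed_mask[j] <- TRUE
    fixed_val[j] <- fixed
  }
  free <- !fixed_mask
  n_free <- sum(free)

  theta0 <- if (is.null(start)) moment_starts(pd, pm, spec) else start
  theta0[fixed_mask] <- fixed_val[fixed_mask]

  # deterministic start perturbations: (sd scale factor, intercept shift)
  jit <- list(c(1, 0), c(0.8, 1), c(1.25, -1), c(0.7, 2), c(1.4, -2),
              c(0.9, 0.5), c(1.1, -0.5))
  n_starts <- max(1L, min(n_starts, length(jit)))
  fit1 <- function(k) {
    th <- theta0
    sdslot <- pm$slot %in% c("sd_a", "sd_c", "sd_e")
    th[sdslot] <- th[sdslot] * jit[[k]][1]
    th[pm$slot == "b0"] <- th[pm$slot == "b0"] + jit[[k]][2]
    th[fixed_mask] <- fixed_val[fixed_mask]
    fn <- function(fr) {
      full <- th
      full[free] <- fr
      obj(full)
    }
    o <- stats::nlminb(th[free], fn,
                       control = list(eval.max = 4000L, iter.max = 1000L,
                                      rel.tol = 1e-10))
    list(par = o$par, m2ll = o$objective, code = o$convergence)
  }
  runs <- lapply(seq_len(n_starts), fit1)
  m2 <- vapply(runs, `[[`, numeric(1), "m2ll")
  best <- which.min(m2)
  theta <- theta0
  theta[free] <- runs[[best]]$par
  theta[fixed_mask] <- fixed_val[fixed_mask]
  agree <- n_starts < 2L ||
    (sort(m2)[2] - m2[best]) < max(agree_tol, 1e-8 * abs(m2[best]))
  conv <- is.finite(m2[best]) && runs[[best]]$code == 0 && agree

  par <- unpack_theta(theta, pm)
  G <- pd$G
  est <- list(
    intercept = par$b0,
    beta_sex = if (spec$sex == "none") NULL else par$bsex,
    beta_pgs = if (spec$pgs == "none") NULL else par$bpgs,
    a2 = par$sd_a^2, c2 = par$sd_c^2, e2 = par$sd_e^2)
  est$total <- est$a2 + est$c2 + est$e2

  structure(list(
    spec = spec, estimates = est, theta = theta, parmap = pm,
    free = free, fixed_val = fixed_val,
    minus2ll = m2[best], n_free = n_free, converged = conv,
    start_agreement = agree, start_m2ll = m2,
    n_pairs = pd$n_pairs, n_dropped = pd$n_dropped, G = G,
    data = data), class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, digits = 3, ...) {
  cat("Censored-FIML twin model fit\n")
  print(x$spec)
  cat(sprintf("  pairs: %d   -2logL: %.3f   free parameters: %d   converged: %s\n",
              x$n_pairs, x$minus2ll, x$n_free, x$converged))
  est <- x$estimates
  tab <- rbind(intercept = est$intercept,
               if (!is.null(est$beta_sex)) beta_sex = est$beta_sex,
               if (!is.null(est$beta_pgs)) beta_pgs = est$beta_pgs,
               a2 = est$a2, c2 = est$c2, e2 = est$e2, total = est$total)
  colnames(tab) <- ses_labels[seq_len(ncol(tab))]
  print(round(tab, digits))
  std <- standardize_ace(est$a2, est$c2, est$e2)
  if (is.matrix(std)) {
    rownames(std) <- ses_labels[seq_len(nrow(std))]
    cat("standardized proportions:\n"); print(round(std, digits))
  } else cat(sprintf("standardized: h2 = %.2f, c2 = %.2f, e2 = %.2f\n",
                     std[1], std[2], std[3]))
  invisible(x)
}
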