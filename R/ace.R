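#' Model-implied twin covariance block of the ACE model
#'
#' The classical twin design decomposes phenotypic variance into additive
#' genetic (A), common-environment (C) and unique-environment (E)
#' components. MZ co-twins share all their alleles, DZ co-twins on average
#' half, so the implied 2 x 2 phenotypic covariance of a pair has diagonal
#' \eqn{a^2 + c^2 + e^2} and off-diagonal \eqn{a^2 + c^2} (MZ) or
#' \eqn{0.5 a^2 + c^2} (DZ).
#'
#' @param a2,c2,e2 variance components (non-negative).
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @return a 2 x 2 covariance matrix.
#' @examples
#' implied_twin_cov(65.9, 2.7, 17.9, "MZ")  # total 86.5, covariance 68.6
#' @export
implied_twin_cov <- function(a2, c2, e2, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  stopifnot(a2 >= 0, c2 >= 0, e2 >= 0)
  v <- a2 + c2 + e2
  cv <- if (zygosity == "MZ") a2 + c2 else 0.5 * a2 + c2
  matrix(c(v, cv, cv, v), 2, 2)
}

#' Standardize ACE variance components
#'
#' Divides each component by the phenotypic total, yielding the heritability
#' \eqn{h^2 = a^2/V} and the common- and unique-environment proportions.
#'
#' @param a2,c2,e2 unstandardized variance components; total must be
#'   positive.
#' @return named numeric vector \code{c(a2, c2, e2)} of proportions summing
#'   to 1.
#' @examples
#' standardize_ace(65.9, 2.7, 17.9)  # heritability 0.76
#' @export
standardize_ace <- function(a2, c2, e2) {
  v <- a2 + c2 + e2
  if (any(v <= 0)) stop("standardize_ace: total variance must be positive")
  cbind(a2 = a2, c2 = c2, e2 = e2) / v -> out
  if (nrow(out) == 1L) out <- out[1L, ]
  out
}
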