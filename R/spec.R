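#' Declarative twin-model specification
#'
#' Describes which parameters of the censored-FIML twin model are
#' stratified by SES group, which are equated, which covariates enter the
#' means, and whether the censoring correction is applied. A spec uniquely
#' determines the free-parameter count, which is what the likelihood-ratio
#' bookkeeping relies on.
#'
#' Mean model per twin: \code{intercept[g] + sex[g]*male + pgs[g]*PGS};
#' covariance per pair from the (possibly stratified) ACE components, with
#' the DZ additive-genetic correlation fixed at 0.5.
#'
#' @param means \code{"shared"} or \code{"by_ses"}: one intercept or one per
#'   SES group.
#' @param variances \code{"shared"} or \code{"by_ses"} for the ACE
#'   components.
#' @param include_c keep the common-environment component (\code{FALSE}
#'   fixes it to zero).
#' @param sex sex covariate on the means: \code{"shared"}, \code{"by_ses"},
#'   or \code{"none"}.
#' @param sex_free when \code{sex = "by_ses"}, a logical vector marking
#'   which groups' sex effects are free (others fixed at 0); used for the
#'   one-group-at-a-time sex tests.
#' @param pgs PGS regression slope: \code{"none"}, \code{"shared"}, or
#'   \code{"by_ses"}.
#' @param censoring apply the censored bivariate-normal correction.
#' @param threshold fixed censoring threshold (score points).
#' @return an object of class \code{twin_spec}.
#' @export
twin_spec <- function(means = c("shared", "by_ses"),
                      variances = c("shared", "by_ses"),
                      include_c = TRUE,
                      sex = c("shared", "by_ses", "none"),
                      sex_free = NULL,
                      pgs = c("none", "shared", "by_ses"),
                      censoring = TRUE,
                      threshold = 550) {
  spec <- list(means = match.arg(means), variances = match.arg(variances),
               include_c = isTRUE(include_c), sex = match.arg(sex),
               sex_free = sex_free, pgs = match.arg(pgs),
               censoring = isTRUE(censoring), threshold = threshold)
  if (!is.null(sex_free) && spec$sex != "by_ses")
    stop("twin_spec: sex_free only applies when sex = 'by_ses'")
  structure(spec, class = "twin_spec")
}

#' @export
print.twin_spec <- function(x, ...) {
  cat(sprintf(
    "twin_spec: means %s, variances %s (%s), sex %s%s, pgs %s, censoring %s at %s\n",
    x$means, x$variances, if (x$include_c) "ACE" else "AE", x$sex,
    if (!is.null(x$sex_free)) paste0(" [free: ",
                                     paste(which(x$sex_free), collapse = ","),
                                     "]") else "",
    x$pgs, if (x$censoring) "on" else "off", x$threshold))
  invisible(x)
}

# ---- parameter map ------------------------------------------------------
# theta layout: b0 (1 or G), bsex (0/1/G), bpgs (0/1/G), sd_a (1 or G),
# sd_c (0/1/G), sd_e (1 or G). Variances are optimized on the SD scale so
# non-negativity is enforced by squaring while keeping the c -> 0 boundary
# well behaved. sex_free entries that are FALSE are pinned at 0 and do not
# count as free parameters.
make_parmap <- function(spec, G) {
  slot_len <- function(kind) switch(kind, none = 0L, shared = 1L, by_ses = G)
  lens <- c(b0 = if (spec$means == "by_ses") G else 1L,
            bsex = slot_len(spec$sex),
            bpgs = slot_len(spec$pgs),
            sd_a = if (spec$variances == "by_ses") G else 1L,
            sd_c = if (!spec$include_c) 0L
                   else if (spec$variances == "by_ses") G else 1L,
            sd_e = if (spec$variances == "by_ses") G else 1L)
  slot <- rep(names(lens), lens)
  idx <- unlist(lapply(lens[lens > 0L], seq_len), use.names = FALSE)
  nm <- ifelse(lens[slot] > 1L, sprintf("%s[%d]", slot, idx), slot)
  fixed <- rep(FALSE, length(slot))
  if (spec$sex == "by_ses" && !is.null(spec$sex_free)) {
    sf <- rep_len(spec$sex_free, G)
    fixed[slot == "bsex"][!sf] <- TRUE
  }
  list(slot = slot, idx = idx, name = nm, fixed = fixed,
       lens = lens, G = G, n_free = sum(!fixed))
}

# expand theta into per-group coefficient vectors (length G each)
unpack_theta <- function(theta, pm) {
  G <- pm$G
  get <- function(slotname, default = 0) {
    v <- theta[pm$slot == slotname]
    if (length(v) == 0L) rep(default, G)
    else if (length(v) == 1L) rep(v, G)
    else v
  }
  list(b0 = get("b0"), bsex = get("bsex"), bpgs = get("bpgs"),
       sd_a = get("sd_a"), sd_c = get("sd_c"), sd_e = get("sd_e"))
}
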