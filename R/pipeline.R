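#' Run the full gene-by-SES analysis ladder
#'
#' Executes, in order, the package's complete analysis sequence on a twin
#' dataset:
#' \enumerate{
#'   \item total-sample ACE model (sex covariate, censoring correction);
#'   \item 1-df test of the common-environment component;
#'   \item SES-stratified means model, test of C after SES stratification,
#'     and one-at-a-time per-group sex-effect tests;
#'   \item SES-stratified variance components and the 9-df variance
#'     moderation test;
#'   \item PGS means/variances by SES with equality tests;
#'   \item EA-on-PGS regression within the twin model with slope- and
#'     intercept-equality tests;
#'   \item DZ within-pair PGS correlation;
#'   \item within-family higher-vs-lower-PGS contrast.
#' }
#' Stages 5--8 are skipped with a notice when no polygenic scores are
#' present. Every likelihood-ratio row of the report names its parent
#' model, and all reported numbers are recomputable from the persisted
#' fits.
#'
#' @param data a \code{twin_data} dataset.
#' @param alpha decision threshold recorded with each test (default 0.01).
#' @param censoring apply the censoring correction throughout.
#' @param threshold censoring threshold.
#' @param n_starts optimizer starts per fit.
#' @param correlations_by_ses also estimate twin correlations per SES
#'   group.
#' @return an \code{analysis_report} list: \code{descriptives},
#'   \code{twin_correlations}, \code{ladder} (model comparison table),
#'   \code{group_table} (means, unstandardized variances and standardized
#'   proportions per SES group), \code{sex_tests}, \code{pgs} (or
#'   \code{NULL}), and the underlying \code{fits}.
#' @export
run_pipeline <- function(data, alpha = 0.01, censoring = TRUE,
                         threshold = 550, n_starts = 2L,
                         correlations_by_ses = TRUE) {
  stopifnot(inherits(data, "twin_data"))
  G <- max(data$ses)
  sp <- function(...) twin_spec(..., censoring = censoring,
                                threshold = threshold)

  # --- descriptives ------------------------------------------------------
  desc <- do.call(rbind, lapply(seq_len(G), function(gg) {
    d <- data[data$ses == gg, , drop = FALSE]
    vals <- c(d$ea1, d$ea2)
    sexes <- c(d$sex1, d$sex2)
    cens <- c(d$cens1, d$cens2) %in% TRUE
    data.frame(ses = ses_labels[gg],
               n_mz = sum(d$zygosity == "MZ"),
               n_dz = sum(d$zygosity == "DZ"),
               mean_girls = mean(vals[sexes == "F"], na.rm = TRUE),
               mean_boys = mean(vals[sexes == "M"], na.rm = TRUE),
               censored_fraction = mean(cens[!is.na(vals)]),
               stringsAsFactors = FALSE)
  }))

  # --- twin correlations (censoring-corrected, saturated) ---------------
  cors <- list(
    MZ = twin_correlation(data, "MZ", censoring = censoring),
    DZ = twin_correlation(data, "DZ", censoring = censoring))
  if (correlations_by_ses) {
    cors$MZ_by_ses <- twin_correlation(data, "MZ", censoring = censoring,
                                       by_ses = TRUE)
    cors$DZ_by_ses <- twin_correlation(data, "DZ", censoring = censoring,
                                       by_ses = TRUE)
  }

  # --- model ladder ------------------------------------------------------
  fits <- list()
  ladder <- list()
  add_row <- function(name, fit, parent = NA_character_,
                      test = NULL) {
    ladder[[length(ladder) + 1L]] <<- data.frame(
      model = name, minus2ll = fit$minus2ll, n_free = fit$n_free,
      parent = parent,
      delta_minus2ll = if (is.null(test)) NA_real_ else test$delta_minus2ll,
      delta_df = if (is.null(test)) NA_integer_ else test$delta_df,
      p_value = if (is.null(test)) NA_real_ else test$p_value,
      stringsAsFactors = FALSE)
  }

  fits$ace_total <- fit_twin_model(data, sp(means = "shared",
                                            variances = "shared",
                                            sex = "shared"),
                                   n_starts = n_starts)
  add_row("ACE total sample", fits$ace_total)

  fits$ae_total <- fit_twin_model(data, sp(means = "shared",
                                           variances = "shared",
                                           include_c = FALSE,
                                           sex = "shared"),
                                  n_starts = n_starts)
  add_row("AE total sample (C = 0)", fits$ae_total, "ACE total sample",
          lrt(fits$ace_total, fits$ae_total))

  fits$means_ses <- fit_twin_model(data, sp(means = "by_ses",
                                            variances = "shared",
                                            sex = "by_ses"),
                                   n_starts = n_starts)
  add_row("SES-stratified means (ACE)", fits$means_ses)

  fits$means_ses_noc <- fit_twin_model(data, sp(means = "by_ses",
                                                variances = "shared",
                                                include_c = FALSE,
                                                sex = "by_ses"),
                                       n_starts = n_starts)
  add_row("SES means, C = 0", fits$means_ses_noc, "SES-stratified means (ACE)",
          lrt(fits$means_ses, fits$means_ses_noc))

  # per-group sex tests: all groups free, drop one group's sex at a time
  sex_tests <- lapply(seq_len(G), function(gg) {
    free <- rep(TRUE, G); free[gg] <- FALSE
    nofit <- fit_twin_model(data, sp(means = "by_ses", variances = "shared",
                                     sex = "by_ses", sex_free = free),
                            n_starts = n_starts)
    tst <- lrt(fits$means_ses, nofit)
    tst$label <- paste("sex effect,", ses_labels[gg], "SES")
    tst
  })
  names(sex_tests) <- ses_labels[seq_len(G)]

  fits$full_strat <- fit_twin_model(data, sp(means = "by_ses",
                                             variances = "by_ses",
                                             sex = "by_ses"),
                                    n_starts = n_starts)
  add_row("SES-stratified means + variances", fits$full_strat)
  mod_test <- lrt(fits$full_strat, fits$means_ses)
  add_row("variance moderation test", fits$means_ses,
          "SES-stratified means + variances", mod_test)

  est <- fits$full_strat$estimates
  std <- standardize_ace(est$a2, est$c2, est$e2)
  group_table <- data.frame(
    ses = ses_labels[seq_len(G)],
    mean_girls = est$intercept,
    mean_boys = est$intercept + est$beta_sex,
    phenotypic = est$total, a2 = est$a2, c2 = est$c2, e2 = est$e2,
    prop_a = std[, "a2"], prop_c = std[, "c2"], prop_e = std[, "e2"],
    stringsAsFactors = FALSE)

  # --- PGS stages --------------------------------------------------------
  pgs_section <- NULL
  has_pgs <- any(!is.na(data$pgs1) | !is.na(data$pgs2))
  if (has_pgs) {
    pdat <- standardize_pgs(data)
    dist <- pgs_by_ses_tests(pdat)
    fit_b <- ea_on_pgs_fit(pdat, slopes = "by_ses", n_starts = n_starts,
                           censoring = censoring, threshold = threshold)
    fit_shared_slope <- ea_on_pgs_fit(pdat, slopes = "shared",
                                      n_starts = n_starts,
                                      censoring = censoring,
                                      threshold = threshold)
    fit_shared_int <- ea_on_pgs_fit(pdat, slopes = "by_ses",
                                    intercepts = "shared",
                                    n_starts = n_starts,
                                    censoring = censoring,
                                    threshold = threshold)
    slope_test <- lrt(fit_b, fit_shared_slope)
    slope_test$label <- "PGS slope equality"
    int_test <- lrt(fit_b, fit_shared_int)
    int_test$label <- "intercept equality"
    dzr <- dz_pgs_correlation(pdat)
    wf <- within_family_test(pdat, censoring = censoring,
                             threshold = threshold)
    fits$ea_on_pgs <- fit_b
    fits$ea_on_pgs_shared_slope <- fit_shared_slope
    fits$ea_on_pgs_shared_intercept <- fit_shared_int
    pgs_section <- list(
      distribution = dist,
      slopes = fit_b$estimates$beta_pgs,
      intercepts = fit_b$estimates$intercept,
      slope_test = slope_test,
      intercept_test = int_test,
      dz_pgs_correlation = dzr,
      within_family = wf)
  } else {
    message("run_pipeline: no polygenic scores present; PGS stages skipped")
  }

  structure(list(
    descriptives = desc,
    twin_correlations = cors,
    ladder = do.call(rbind, ladder),
    group_table = group_table,
    sex_tests = sex_tests,
    variance_moderation = mod_test,
    c_after_ses = lrt(fits$means_ses, fits$means_ses_noc),
    pgs = pgs_section,
    alpha = alpha,
    fits = fits), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Gene-by-SES analysis report ==\n\nDescriptives:\n")
  print(transform(x$descriptives,
                  mean_girls = round(mean_girls, 1),
                  mean_boys = round(mean_boys, 1),
                  censored_fraction = round(censored_fraction, 3)))
  cat("\nTwin correlations (censoring-corrected):\n")
  cat(sprintf("  MZ: %.2f   DZ: %.2f\n", x$twin_correlations$MZ$r,
              x$twin_correlations$DZ$r))
  cat("\nModel ladder:\n")
  lad <- x$ladder
  lad$minus2ll <- round(lad$minus2ll, 1)
  lad$delta_minus2ll <- round(lad$delta_minus2ll, 1)
  lad$p_value <- signif(lad$p_value, 3)
  print(lad, row.names = FALSE)
  cat("\nPer-group estimates (stratified model):\n")
  print(cbind(x$group_table[1], round(x$group_table[-1], 2)),
        row.names = FALSE)
  cat("\nSex-effect tests by SES group:\n")
  for (t in x$sex_tests) print(t)
  if (!is.null(x$pgs)) {
    p <- x$pgs
    cat("\nPGS section:\n  group means: ",
        paste(round(p$distribution$stratified$mean, 2), collapse = ", "),
        "\n", sep = "")
    print(p$distribution$means_test)
    print(p$distribution$variances_test)
    cat(sprintf("  DZ PGS correlation: %.2f (%.0f%% CI %.2f-%.2f, n = %d)\n",
                p$dz_pgs_correlation$r, 100 * p$dz_pgs_correlation$level,
                p$dz_pgs_correlation$lower, p$dz_pgs_correlation$upper,
                p$dz_pgs_correlation$n_pairs))
    cat("  EA-on-PGS slopes: ",
        paste(round(p$slopes, 2), collapse = ", "), "\n", sep = "")
    print(p$slope_test)
    print(p$intercept_test)
    print(p$within_family)
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Machine-readable form of \code{\link{run_pipeline}}'s output (fits are
#' reduced to their estimates and fit statistics). Deterministic for a
#' fixed dataset: identical inputs give byte-identical JSON.
#'
#' @param report an \code{analysis_report}.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  strip_lrt <- function(t) list(delta_minus2ll = t$delta_minus2ll,
                                delta_df = t$delta_df, p_value = t$p_value)
  strip_fit <- function(f) list(minus2ll = f$minus2ll, n_free = f$n_free,
                                converged = f$converged,
                                estimates = f$estimates)
  x <- list(
    descriptives = report$descriptives,
    twin_correlations = list(MZ = report$twin_correlations$MZ,
                             DZ = report$twin_correlations$DZ),
    ladder = report$ladder,
    group_table = report$group_table,
    sex_tests = lapply(report$sex_tests, strip_lrt),
    variance_moderation = strip_lrt(report$variance_moderation),
    c_after_ses = strip_lrt(report$c_after_ses),
    alpha = report$alpha,
    fits = lapply(report$fits, strip_fit))
  if (!is.null(report$pgs)) {
    p <- report$pgs
    x$pgs <- list(
      group_means = p$distribution$stratified$mean,
      group_variances = p$distribution$stratified$variance,
      means_test = strip_lrt(p$distribution$means_test),
      variances_test = strip_lrt(p$distribution$variances_test),
      slopes = p$slopes, intercepts = p$intercepts,
      slope_test = strip_lrt(p$slope_test),
      intercept_test = strip_lrt(p$intercept_test),
      dz_pgs_correlation = p$dz_pgs_correlation[c("r", "lower", "upper",
                                                  "n_pairs")],
      within_family = list(mean_pgs_gap = p$within_family$mean_pgs_gap,
                           mean_ea_gap = p$within_family$mean_ea_gap,
                           lrt = strip_lrt(p$within_family$lrt),
                           n_pairs = p$within_family$n_pairs))
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "columns")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
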