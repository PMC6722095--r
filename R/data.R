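# SES group labels, lowest to highest (4-level parental classification)
ses_labels <- c("lowest", "low", "high", "highest")

#' Construct and validate a twin-pair dataset
#'
#' A \code{twin_data} object is a data frame with one row per twin pair:
#' \describe{
#'   \item{family_id}{opaque pair identifier}
#'   \item{zygosity}{\code{"MZ"} or \code{"DZ"}}
#'   \item{ses}{SES group, integer 1 (lowest) to 4 (highest)}
#'   \item{sex1, sex2}{\code{"F"} or \code{"M"} per twin}
#'   \item{ea1, ea2}{educational-achievement score (501--550) or \code{NA}}
#'   \item{cens1, cens2}{right-censoring flags; derived, never trusted: a
#'     stored score equal to the threshold is always treated as censored}
#'   \item{pgs1, pgs2}{standardized polygenic score or \code{NA} (optional)}
#' }
#'
#' Validation enforces the closed vocabularies, the score range, that MZ
#' co-twins have the same sex, and that no pair has both scores missing.
#' Any stored score equal to \code{threshold} has its censoring flag set.
#'
#' @param df a data frame with at least the columns above (\code{cens*} and
#'   \code{pgs*} optional).
#' @param threshold censoring threshold used to derive the flags.
#' @param floor_value lowest attainable score.
#' @return the validated data frame with class \code{twin_data}.
#' @export
as_twin_data <- function(df, threshold = 550, floor_value = 501) {
  req <- c("family_id", "zygosity", "ses", "sex1", "sex2", "ea1", "ea2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("twin data: missing column(s) ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("pgs1", "pgs2")) if (is.null(df[[col]])) df[[col]] <- NA_real_
  df$zygosity <- as.character(df$zygosity)
  df$sex1 <- as.character(df$sex1)
  df$sex2 <- as.character(df$sex2)
  df$ses <- as.integer(df$ses)
  df$ea1 <- as.numeric(df$ea1)
  df$ea2 <- as.numeric(df$ea2)

  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      rows <- which(cond)
      stop("twin data: ", what, " in row(s) ",
           paste(utils::head(rows, 5L), collapse = ", "),
           if (length(rows) > 5L) sprintf(" (and %d more)", length(rows) - 5L))
    }
  }
  bad_row(!df$zygosity %in% c("MZ", "DZ"), "unknown zygosity code")
  bad_row(is.na(df$ses) | !df$ses %in% 1:4, "SES group outside 1..4")
  bad_row(!df$sex1 %in% c("F", "M") | !df$sex2 %in% c("F", "M"),
          "unknown sex code")
  bad_row(df$zygosity == "MZ" & df$sex1 != df$sex2,
          "MZ pair with discordant sexes")
  for (side in 1:2) {
    ea <- df[[paste0("ea", side)]]
    bad_row(!is.na(ea) & (ea < floor_value | ea > threshold),
            sprintf("ea%d outside [%s, %s]", side, floor_value, threshold))
  }
  bad_row(is.na(df$ea1) & is.na(df$ea2), "both scores missing")
  # censoring flags are derived: stored threshold value <=> censored
  df$cens1 <- !is.na(df$ea1) & df$ea1 >= threshold
  df$cens2 <- !is.na(df$ea2) & df$ea2 >= threshold
  df$pgs1 <- as.numeric(df$pgs1)
  df$pgs2 <- as.numeric(df$pgs2)
  mzp <- df$zygosity == "MZ" & !is.na(df$pgs1) & !is.na(df$pgs2)
  if (any(mzp) && any(abs(df$pgs1[mzp] - df$pgs2[mzp]) > 1e-6))
    warning("twin data: MZ pairs with unequal polygenic scores; ",
            "MZ co-twins are genetically identical")
  class(df) <- c("twin_data", "data.frame")
  attr(df, "threshold") <- threshold
  attr(df, "floor_value") <- floor_value
  df
}

#' Read a twin-pair CSV
#'
#' Reads the package-standard comma-separated schema (columns
#' \code{family_id, zygosity, ses, sex1, sex2, ea1, ea2, pgs1, pgs2}; empty
#' fields are missing values; UTF-8; \code{.} decimal separator) and
#' validates it with \code{\link{as_twin_data}}. Scores stored at the
#' threshold are flagged censored on load.
#'
#' @param path file path.
#' @param threshold,floor_value passed to \code{\link{as_twin_data}}.
#' @return a \code{twin_data} data frame.
#' @export
read_twin_data <- function(path, threshold = 550, floor_value = 501) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(family_id = "character",
                                       zygosity = "character",
                                       sex1 = "character",
                                       sex2 = "character"),
                        na.strings = "")
  as_twin_data(df, threshold = threshold, floor_value = floor_value)
}

#' Write a twin-pair CSV
#'
#' Writes the package-standard schema (see \code{\link{read_twin_data}}).
#' Censoring flags are not persisted: by convention a stored score equal to
#' the threshold is censored. Latent truth columns from the simulator are
#' dropped.
#'
#' @param data a \code{twin_data} data frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_twin_data <- function(data, path) {
  cols <- c("family_id", "zygosity", "ses", "sex1", "sex2",
            "ea1", "ea2", "pgs1", "pgs2")
  out <- as.data.frame(data)[, cols]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.twin_data <- function(x, ...) {
  cat(sprintf("twin_data: %d pairs (%d MZ, %d DZ), SES groups %s\n",
              nrow(x), sum(x$zygosity == "MZ"), sum(x$zygosity == "DZ"),
              paste(sort(unique(x$ses)), collapse = ",")))
  cat(sprintf("  censored scores: %d; incomplete pairs: %d; PGS present: %d pairs\n",
              sum(x$cens1, na.rm = TRUE) + sum(x$cens2, na.rm = TRUE),
              sum(is.na(x$ea1) | is.na(x$ea2)),
              sum(!is.na(x$pgs1) | !is.na(x$pgs2))))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("  ... %d more pairs\n", nrow(x) - 4L))
  invisible(x)
}
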