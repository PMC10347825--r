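cohort_columns <- function() {
  c("ma", "bmi", "duration", "hcg", "em", "gsd", "ysd", "el", "ehr",
    "iuh", "outcome")
}

#' Write a cohort to CSV
#'
#' One header row with columns
#' `ma,bmi,duration,hcg,em,gsd,ysd,el,ehr,iuh,outcome`; missing optional
#' covariates are written as empty fields; `iuh` as `TRUE`/`FALSE`;
#' `outcome` as `ongoing`/`epl`.
#'
#' @param cohort A cohort `data.frame` (see
#'   [generate_group_conditional()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
cohort_to_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  for (col in missing_cols) cohort[[col]] <- NA
  utils::write.csv(cohort[, cohort_columns()], path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates every row: scoring measurements must be finite and
#' non-negative, `iuh` empty or logical, `outcome` empty or one of
#' `ongoing`/`epl`. Malformed cells raise an error naming the row and
#' column.
#'
#' @param path Path to a cohort CSV written by [cohort_to_csv()] (or
#'   following the same layout).
#' @return A cohort `data.frame`; zero rows if the file holds only the
#'   header.
#' @export
cohort_from_csv <- function(path) {
  if (!file.exists(path)) abort("cohort file '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols)) {
    abort("'%s' lacks column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  df <- df[, cohort_columns()]
  scoring <- c("ma", "em", "gsd", "ysd", "el", "ehr")
  optional_num <- c("bmi", "duration", "hcg")
  for (col in c(scoring, optional_num)) {
    v <- df[[col]]
    if (!is.numeric(v) && !is.logical(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      abort("row %d, column '%s': not a number ('%s')", bad, col, v[bad])
    }
    df[[col]] <- as.numeric(v)
  }
  for (col in scoring) {
    bad <- which(is.na(df[[col]]))[1]
    if (!is.na(bad)) abort("row %d, column '%s': missing scoring value", bad, col)
    bad <- which(df[[col]] < 0)[1]
    if (!is.na(bad)) {
      abort("row %d, column '%s': negative value (%g)", bad, col, df[[col]][bad])
    }
  }
  if (!is.logical(df$iuh)) {
    v <- toupper(trimws(as.character(df$iuh)))
    ok <- is.na(v) | v %in% c("TRUE", "FALSE")
    if (!all(ok)) {
      bad <- which(!ok)[1]
      abort("row %d, column 'iuh': expected TRUE/FALSE ('%s')", bad, df$iuh[bad])
    }
    df$iuh <- v == "TRUE"
  }
  if (nrow(df)) {
    v <- as.character(df$outcome)
    ok <- is.na(v) | v %in% c("ongoing", "epl")
    if (!all(ok)) {
      bad <- which(!ok)[1]
      abort("row %d, column 'outcome': expected ongoing/epl ('%s')", bad, v[bad])
    }
    df$outcome <- v
  } else {
    df$outcome <- character(0)
  }
  df
}
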