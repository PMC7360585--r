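#' Cohort table of per-sample statistics
#'
#' One row per (sample, panel): the metadata columns `sample_id`,
#' `instrument_id`, `center_id`, `acquisition_date`, `panel_id`,
#' `batch_id`, `group`, then feature columns named
#' `freq.<population>` (percent of leukocytes), `count.<population>`
#' (cells/uL) and `mfi.<population>.<marker>` (arithmetic mean, linear
#' scale). This is the CSV the MFI correction steps operate on: the
#' corrections rescale only the `mfi.*` columns, never frequencies or
#' counts.
#'
#' The attribute `corrections` records which corrections have been
#' applied (in order), enforcing the pipeline order batch-then-center.
#'
#' @param df data frame with the columns above.
#' @return a `cohort_table` (still a data frame).
#' @export
cohort_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) stop("a cohort table must contain at least one sample")
  need <- c("sample_id", "instrument_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("cohort table lacks required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(attr(df, "corrections"))) attr(df, "corrections") <- character(0)
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Feature column helpers
#' @param tab a [cohort_table()].
#' @return character vector of matching column names.
#' @export
mfi_columns <- function(tab) grep("^mfi\\.", names(tab), value = TRUE)

#' @rdname mfi_columns
#' @export
freq_columns <- function(tab) grep("^freq\\.", names(tab), value = TRUE)

#' @rdname mfi_columns
#' @export
count_columns <- function(tab) grep("^count\\.", names(tab), value = TRUE)

#' Read/write cohort tables as CSV
#'
#' Plain CSV with a header row; applied corrections are recorded in a
#' leading `# corrections:` comment line so provenance survives the round
#' trip.
#'
#' @param tab a [cohort_table()].
#' @param path CSV path.
#' @return the path invisibly / a [cohort_table()].
#' @export
write_cohort_table <- function(tab, path) {
  stopifnot(inherits(tab, "cohort_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# corrections: %s",
                     paste(attr(tab, "corrections"), collapse = ",")), con)
  utils::write.csv(as.data.frame(tab), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  first <- readLines(path, n = 1L)
  corrections <- character(0)
  if (startsWith(first, "# corrections:")) {
    val <- trimws(sub("^# corrections:", "", first))
    if (nzchar(val)) corrections <- strsplit(val, ",", fixed = TRUE)[[1L]]
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty cohort table CSV")
  if ("acquisition_date" %in% names(df)) {
    df$acquisition_date <- as.Date(df$acquisition_date)
  }
  attr(df, "corrections") <- corrections
  cohort_table(df)
}
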