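#' Assign antibody-lot/calibration batches from acquisition dates
#'
#' A batch is the combination of the antibody lot in use (lots are
#' half-open date periods: a date on a period boundary belongs to the
#' period starting that day) and the calibration epoch (the number of
#' recalibration dates on or before the acquisition date; a
#' recalibration starts a new epoch the same day). With three lots and
#' seven recalibrations this yields up to 21 distinct batches per
#' instrument.
#'
#' @param dates `Date` vector of per-sample acquisition dates (names are
#'   used in error messages).
#' @param lot_periods data frame with columns `lot_id`, `start`, `end`
#'   (`Date`; half-open `[start, end)`), non-overlapping and covering
#'   all `dates`.
#' @param calib_dates `Date` vector of recalibration dates (possibly
#'   empty).
#' @return character vector of batch ids, `"<lot>.e<epoch>"`.
#' @export
assign_batches <- function(dates, lot_periods,
                           calib_dates = as.Date(character(0))) {
  stopifnot(inherits(dates, "Date"),
            all(c("lot_id", "start", "end") %in% names(lot_periods)))
  ord <- order(lot_periods$start)
  lot_periods <- lot_periods[ord, ]
  if (any(lot_periods$end[-nrow(lot_periods)] > lot_periods$start[-1L])) {
    stop("lot periods overlap")
  }
  out <- character(length(dates))
  for (i in seq_along(dates)) {
    d <- dates[i]
    hit <- which(lot_periods$start <= d & d < lot_periods$end)
    if (length(hit) != 1L) {
      who <- if (!is.null(names(dates))) names(dates)[i] else as.character(i)
      stop(sprintf("batch assignment error: sample '%s' (%s) falls outside all lot periods",
                   who, format(d)))
    }
    epoch <- sum(calib_dates <= d)
    out[i] <- sprintf("%s.e%d", lot_periods$lot_id[hit], epoch)
  }
  out
}

#' Correction coefficients (batch or center scope)
#'
#' Multiplicative per-feature coefficients keyed by (instrument, batch)
#' for the antibody-batch correction, or by instrument for the
#' instrument-to-reference correction. The reference key's coefficients
#' are exactly 1.
#'
#' @param df data frame with key columns, `feature` and `coefficient`.
#' @param scope `"batch"` or `"center"`.
#' @param reference the reference key (first batch per instrument /
#'   reference instrument).
#' @return a `correction_coefficients` data frame.
#' @export
correction_coefficients <- function(df, scope = c("batch", "center"),
                                    reference) {
  scope <- match.arg(scope)
  if (any(!is.finite(df$coefficient) | df$coefficient <= 0)) {
    stop("all correction coefficients must be finite and positive")
  }
  structure(df, scope = scope, reference = reference,
            class = c("correction_coefficients", "data.frame"))
}

#' Write correction coefficients as CSV
#' @param coeffs a [correction_coefficients()] object.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_coefficients <- function(coeffs, path) {
  df <- as.data.frame(coeffs)
  df$scope <- attr(coeffs, "scope")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

sample_stat <- function(stat) {
  switch(stat, median = stats::median, mean = mean)
}

#' Antibody-batch correction coefficients within each instrument
#'
#' For every MFI feature and every batch of an instrument, the
#' coefficient is the median of the feature over the samples of the
#' instrument's first (earliest-starting) batch divided by the median
#' over the samples of that batch; the first batch's coefficient is 1.
#' Applying these coefficients aligns the per-batch medians of every
#' feature exactly (the median is multiplicative: `median(c*x) =
#' c*median(x)`).
#'
#' "MFI of all samples" is summarized by the median because the
#' correction's stated purpose is the alignment of median values; the
#' mean is available via `stat` for sensitivity analysis. Coefficients
#' are computed per (population, marker) feature, not pooled per
#' channel, since lot effects are antibody-specific.
#'
#' @param tab a [cohort_table()] with `batch_id` assigned.
#' @param instruments instruments to process (default: all present).
#' @param stat `"median"` or `"mean"`.
#' @return a [correction_coefficients()] with scope `"batch"`.
#' @export
batch_coefficients <- function(tab, instruments = NULL,
                               stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(inherits(tab, "cohort_table"))
  if (!"batch_id" %in% names(tab) || anyNA(tab$batch_id)) {
    stop("cohort table needs a complete batch_id column (see assign_batches)")
  }
  if (is.null(instruments)) instruments <- unique(tab$instrument_id)
  fn <- sample_stat(stat)
  feats <- mfi_columns(tab)
  rows <- list()
  refs <- character(0)
  for (ins in instruments) {
    sub <- tab[tab$instrument_id == ins, , drop = FALSE]
    if (nrow(sub) == 0L) stop(sprintf("no samples for instrument '%s'", ins))
    first_batch <- sub$batch_id[which.min(sub$acquisition_date)]
    refs[ins] <- first_batch
    ref_rows <- sub[sub$batch_id == first_batch, , drop = FALSE]
    for (b in unique(sub$batch_id)) {
      b_rows <- sub[sub$batch_id == b, , drop = FALSE]
      co <- vapply(feats, function(f) {
        num <- fn(ref_rows[[f]], na.rm = TRUE)
        den <- fn(b_rows[[f]], na.rm = TRUE)
        if (!is.finite(den) || den <= 0) {
          stop(sprintf("non-positive %s for feature %s in batch %s of %s",
                       stat, f, b, ins))
        }
        if (b == first_batch) 1 else num / den
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        instrument_id = ins, batch_id = b, feature = feats,
        coefficient = unname(co), stringsAsFactors = FALSE)
    }
  }
  correction_coefficients(do.call(rbind, rows), scope = "batch",
                          reference = refs)
}

#' Instrument-to-reference correction coefficients
#'
#' For every MFI feature, the coefficient of an instrument is the median
#' of the feature over the reference instrument's samples divided by the
#' median over that instrument's samples; the reference instrument's
#' coefficient is 1. After application the per-instrument medians of
#' every feature coincide exactly with the reference.
#'
#' The correction assumes every center measured the same case mix; when
#' a `group` column is present its composition per instrument is checked
#' with a chi-squared heterogeneity test and a warning is raised if the
#' mixes differ (p < 0.05), since the correction is biased otherwise.
#' The pipeline order is batch-then-center; calling this on a table
#' whose batch correction has not been applied is refused unless
#' `require_batch_corrected = FALSE`.
#'
#' @param tab a [cohort_table()].
#' @param reference_instrument id of the reference instrument.
#' @param stat `"median"` or `"mean"`.
#' @param require_batch_corrected enforce the pipeline order.
#' @return a [correction_coefficients()] with scope `"center"`.
#' @export
center_coefficients <- function(tab, reference_instrument,
                                stat = c("median", "mean"),
                                require_batch_corrected = TRUE) {
  stat <- match.arg(stat)
  stopifnot(inherits(tab, "cohort_table"))
  if (require_batch_corrected &&
      !"batch" %in% attr(tab, "corrections")) {
    stop("center correction refused before batch correction (pipeline order is batch then center); set require_batch_corrected = FALSE to override")
  }
  if (!reference_instrument %in% tab$instrument_id) {
    stop(sprintf("reference instrument '%s' has no samples", reference_instrument))
  }
  if ("group" %in% names(tab) && !anyNA(tab$group) &&
      length(unique(tab$group)) > 1L && length(unique(tab$instrument_id)) > 1L) {
    p <- suppressWarnings(
      stats::chisq.test(table(tab$instrument_id, tab$group))$p.value)
    if (is.finite(p) && p < 0.05) {
      warning(sprintf("disease-group composition differs between instruments (chi-squared p = %.3g); the instrument correction assumes a shared case mix and may be biased", p))
    }
  }
  fn <- sample_stat(stat)
  feats <- mfi_columns(tab)
  ref_rows <- tab[tab$instrument_id == reference_instrument, , drop = FALSE]
  rows <- lapply(unique(tab$instrument_id), function(ins) {
    i_rows <- tab[tab$instrument_id == ins, , drop = FALSE]
    co <- vapply(feats, function(f) {
      num <- fn(ref_rows[[f]], na.rm = TRUE)
      den <- fn(i_rows[[f]], na.rm = TRUE)
      if (!is.finite(den) || den <= 0) {
        stop(sprintf("non-positive %s for feature %s on instrument %s",
                     stat, f, ins))
      }
      if (ins == reference_instrument) 1 else num / den
    }, numeric(1))
    data.frame(instrument_id = ins, feature = feats,
               coefficient = unname(co), stringsAsFactors = FALSE)
  })
  correction_coefficients(do.call(rbind, rows), scope = "center",
                          reference = reference_instrument)
}

#' Apply correction coefficients to a cohort table
#'
#' Multiplies every `mfi.*` column of each sample by its key's
#' coefficient; frequencies and absolute counts are untouched
#' (bit-identical). The applied scope is appended to the table's
#' `corrections` attribute.
#'
#' @param tab a [cohort_table()].
#' @param coeffs a [correction_coefficients()] from
#'   [batch_coefficients()] or [center_coefficients()].
#' @return the corrected [cohort_table()].
#' @export
apply_coefficients <- function(tab, coeffs) {
  stopifnot(inherits(tab, "cohort_table"),
            inherits(coeffs, "correction_coefficients"))
  scope <- attr(coeffs, "scope")
  key_cols <- if (scope == "batch") c("instrument_id", "batch_id") else "instrument_id"
  tab_key <- do.call(paste, c(unclass(tab)[key_cols], sep = "\r"))
  co_key <- do.call(paste, c(unclass(coeffs)[key_cols], sep = "\r"))
  out <- tab
  for (f in unique(coeffs$feature)) {
    sub <- coeffs[coeffs$feature == f, , drop = FALSE]
    idx <- match(tab_key, co_key[coeffs$feature == f])
    if (anyNA(idx)) {
      bad <- unique(tab$sample_id[is.na(idx)])
      stop(sprintf("no %s coefficient for sample(s): %s", scope,
                   paste(utils::head(bad, 5L), collapse = ", ")))
    }
    out[[f]] <- out[[f]] * sub$coefficient[idx]
  }
  attr(out, "corrections") <- c(attr(tab, "corrections"), scope)
  out
}
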