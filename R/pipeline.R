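#' Pipeline configuration
#'
#' Bundles the declarative configuration the end-to-end workflow needs:
#' panel (channel order, thresholds, populations, reference bead
#' targets), channel map, spillover fallback, lot schedule, counting
#' bead concentration and the reference instrument. Defaults describe
#' the built-in panel 1.
#'
#' @param panel a [default_panel()]-shaped list.
#' @param channel_map a [channel_map()].
#' @param reference_peaks the frozen reference [peak_set()].
#' @param spillover fallback [spillover_matrix()] used when a file has
#'   no `$SPILLOVER` keyword (the keyword takes precedence).
#' @param lot_periods,calib_dates antibody-lot schedule for
#'   [assign_batches()].
#' @param reference_instrument instrument all others are corrected to.
#' @param beads_per_ul counting-bead concentration.
#' @param qc_limit daily-QC pass limit in percent.
#' @param date_fallback_days a sample acquired on a day without a bead
#'   file may borrow a transform at most this many days away (0 = exact
#'   match only).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(panel = default_panel("panel1"),
                            channel_map = default_channel_map("panel1"),
                            reference_peaks = panel$reference_peaks,
                            spillover = NULL,
                            lot_periods = NULL,
                            calib_dates = as.Date(character(0)),
                            reference_instrument = "instr01",
                            beads_per_ul = 100,
                            qc_limit = 5,
                            date_fallback_days = 0L) {
  structure(list(panel = panel, channel_map = channel_map,
                 reference_peaks = reference_peaks, spillover = spillover,
                 lot_periods = lot_periods, calib_dates = calib_dates,
                 reference_instrument = reference_instrument,
                 beads_per_ul = beads_per_ul, qc_limit = qc_limit,
                 date_fallback_days = as.integer(date_fallback_days)),
            class = "pipeline_config")
}

#' Run the harmonization workflow end to end
#'
#' Executes the fixed stage order on a cohort file tree: per
#' instrument-day bead QC and affine-transform fitting, then per sample
#' normalization, compensation, gating and statistics extraction, then
#' batch assignment, the antibody-batch correction, the
#' instrument-to-reference correction, and the harmonization
#' diagnostics. Per-file errors are collected and reported without
#' aborting the cohort; a sample whose day has no usable bead transform
#' is reported as failed while the rest proceed.
#'
#' @param input_dir directory containing `metadata.csv` (columns
#'   `file`, `kind` = `"beads"`/`"sample"`, `sample_id`,
#'   `instrument_id`, `center_id`, `date`, `panel_id`, `group`) and the
#'   FCS files it references, as produced by [simulate_cohort()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for CSV/JSON outputs (cohort
#'   tables, coefficients, QC report, failures).
#' @return list with `table_raw`, `table_batch_corrected`,
#'   `table_corrected`, `batch_coeffs`, `center_coeffs`, `qc`,
#'   `transforms`, `failures`, `metrics`.
#' @export
run_pipeline <- function(input_dir, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  meta_path <- file.path(input_dir, "metadata.csv")
  if (!file.exists(meta_path)) stop(sprintf("no metadata.csv in %s", input_dir))
  manifest <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  manifest$date <- as.Date(manifest$date)
  failures <- list()
  fail <- function(file, stage, message) {
    failures[[length(failures) + 1L]] <<- data.frame(
      file = file, stage = stage, message = conditionMessage(message),
      stringsAsFactors = FALSE)
  }
  # stage: bead QC + transforms per (instrument, date). The daily QC
  # deviation is judged against the instrument's *internal* reference
  # (its first bead acquisition), while the normalization transform is
  # always fitted against the frozen cross-center reference targets.
  transforms <- list()
  qc_reports <- list()
  internal_refs <- list()
  beads <- manifest[manifest$kind == "beads", , drop = FALSE]
  beads <- beads[order(beads$instrument_id, beads$date), , drop = FALSE]
  for (i in seq_len(nrow(beads))) {
    row <- beads[i, ]
    key <- paste(row$instrument_id, format(row$date))
    tryCatch({
      em <- read_fcs(file.path(input_dir, row$file))
      em <- standardize_channels(em, config$channel_map)
      em$meta$instrument_id <- row$instrument_id
      em$meta$acquisition_date <- row$date
      ps <- detect_peaks(em)
      if (is.null(internal_refs[[row$instrument_id]])) {
        internal_refs[[row$instrument_id]] <- ps
      }
      qc_reports[[key]] <- qc_deviation(ps, internal_refs[[row$instrument_id]],
                                        limit = config$qc_limit)
      transforms[[key]] <- fit_affine(ps, config$reference_peaks)
    }, error = function(e) fail(row$file, "bead_qc", e))
  }
  find_transform <- function(instrument, date) {
    key <- paste(instrument, format(date))
    if (!is.null(transforms[[key]])) return(transforms[[key]])
    if (config$date_fallback_days > 0L) {
      for (off in seq_len(config$date_fallback_days)) {
        for (d in c(date - off, date + off)) {
          key <- paste(instrument, format(as.Date(d, origin = "1970-01-01")))
          if (!is.null(transforms[[key]])) return(transforms[[key]])
        }
      }
    }
    NULL
  }
  # stage: per-sample normalize -> compensate -> gate -> extract
  samples <- manifest[manifest$kind == "sample", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    row <- samples[i, ]
    tryCatch({
      em <- read_fcs(file.path(input_dir, row$file))
      em <- standardize_channels(em, config$channel_map)
      em$meta$instrument_id <- row$instrument_id
      em$meta$center_id <- row$center_id
      em$meta$acquisition_date <- row$date
      em$meta$sample_id <- row$sample_id
      tr <- find_transform(row$instrument_id, row$date)
      if (is.null(tr)) {
        stop(sprintf("no bead transform for instrument %s on %s",
                     row$instrument_id, format(row$date)))
      }
      em <- apply_affine(em, tr)
      em <- apply_compensation(em, S = if (is.null(em$keywords[["$SPILLOVER"]]))
        config$spillover else NULL)
      labels <- gate_events(em, config$panel$populations,
                            config$panel$thresholds)
      st <- population_stats(em, labels, config$panel$populations,
                             beads_per_volume = config$beads_per_ul)
      rows[[length(rows) + 1L]] <- cohort_row(st, em$meta, group = row$group)
    }, error = function(e) fail(row$file, "sample", e))
  }
  if (!length(rows)) stop("no sample produced statistics; all files failed")
  tab <- cohort_table(do.call(rbind, rows))
  # stage: batch + center corrections on the extracted table
  if (!is.null(config$lot_periods)) {
    tab$batch_id <- assign_batches(
      stats::setNames(tab$acquisition_date, tab$sample_id),
      config$lot_periods, config$calib_dates)
  } else {
    tab$batch_id <- "lot1.e0"
  }
  bc <- batch_coefficients(tab)
  tab_batch <- apply_coefficients(tab, bc)
  cc <- suppressWarnings(
    center_coefficients(tab_batch, config$reference_instrument))
  tab_corr <- apply_coefficients(tab_batch, cc)
  # stage: diagnostics
  metrics <- list(
    median_equality_before = median_equality_test(tab),
    median_equality_after = median_equality_test(tab_corr)
  )
  n_centers <- length(unique(tab$center_id))
  if (n_centers >= 2L && all(table(tab$center_id) >= 3L)) {
    metrics$pca_mfi_before <- suppressWarnings(center_effect_pca(tab, "mfi"))
    metrics$pca_mfi_after <- suppressWarnings(center_effect_pca(tab_corr, "mfi"))
    metrics$pca_freq <- suppressWarnings(center_effect_pca(tab, "freq"))
  }
  failures_df <- if (length(failures)) do.call(rbind, failures) else
    data.frame(file = character(0), stage = character(0), message = character(0))
  out <- list(table_raw = tab, table_batch_corrected = tab_batch,
              table_corrected = tab_corr, batch_coeffs = bc,
              center_coeffs = cc, qc = qc_reports, transforms = transforms,
              failures = failures_df, metrics = metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_table(tab, file.path(out_dir, "cohort_raw.csv"))
    write_cohort_table(tab_corr, file.path(out_dir, "cohort_corrected.csv"))
    write_coefficients(bc, file.path(out_dir, "coefficients_batch.csv"))
    write_coefficients(cc, file.path(out_dir, "coefficients_center.csv"))
    utils::write.csv(failures_df, file.path(out_dir, "failures.csv"),
                     row.names = FALSE)
    qc_df <- do.call(rbind, lapply(names(qc_reports), function(k) {
      r <- qc_reports[[k]]
      data.frame(key = k, max_deviation = max(r$deviation), pass = r$pass)
    }))
    if (!is.null(qc_df)) {
      utils::write.csv(qc_df, file.path(out_dir, "qc_report.csv"),
                       row.names = FALSE)
    }
  }
  out
}
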