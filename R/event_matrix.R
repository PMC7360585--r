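#' Event-level flow cytometry data
#'
#' An `event_matrix` holds one acquisition: a numeric matrix of events by
#' channels on the linear intensity scale, together with the acquisition
#' metadata that the harmonization pipeline keys on (instrument, center,
#' date, panel, sample) and the raw FCS keywords of the file it came from.
#' Log-amplified on-disk values are linearized at read time, so all
#' computation in this package happens on the linear scale; display
#' transforms are a plotting concern only.
#'
#' @param values numeric matrix, events in rows, channels in columns.
#'   Raw intensities are non-negative; compensated values may be negative.
#' @param channel_names character vector of unique channel names, one per
#'   column. Defaults to `colnames(values)`.
#' @param scatter logical vector flagging non-fluorescence channels
#'   (forward/side scatter, time). Guessed from the names when `NULL`.
#' @param meta named list of acquisition metadata. Recognized entries:
#'   `instrument_id`, `center_id`, `acquisition_date` (a `Date`),
#'   `panel_id` (`"panel1"`, `"panel2"` or `"beads"`), `sample_id`,
#'   `vendor` (`"BC"` or `"BD"`), and the processing flags `normalized`
#'   and `compensated`.
#' @param keywords named list of FCS keyword/value pairs (kept verbatim so
#'   e.g. a `$SPILLOVER` keyword survives the round trip).
#' @return an object of class `event_matrix`.
#' @export
event_matrix <- function(values, channel_names = colnames(values),
                         scatter = NULL, meta = list(), keywords = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(channel_names)) {
    stop("channel_names must be given when `values` has no column names")
  }
  channel_names <- as.character(channel_names)
  if (ncol(values) != length(channel_names)) {
    stop("length(channel_names) must equal ncol(values)")
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique")
  }
  if (nrow(values) < 1L) {
    stop("an event_matrix must contain at least one event")
  }
  if (is.null(scatter)) scatter <- guess_scatter(channel_names)
  stopifnot(is.logical(scatter), length(scatter) == length(channel_names))
  defaults <- list(
    instrument_id = NA_character_, center_id = NA_character_,
    acquisition_date = as.Date(NA), panel_id = NA_character_,
    sample_id = NA_character_, vendor = NA_character_,
    normalized = FALSE, compensated = FALSE
  )
  meta <- utils::modifyList(defaults, meta)
  colnames(values) <- channel_names
  structure(
    list(values = values, channels = channel_names, scatter = scatter,
         meta = meta, keywords = keywords),
    class = "event_matrix"
  )
}

# Scatter/time channels by naming convention: BC "FS INT"/"SS INT",
# BD "FSC-A"/"SSC-A", canonical "FSC"/"SSC", plus TIME.
guess_scatter <- function(channel_names) {
  grepl("^(FS|SS)([ C-]|$)|^TIME", toupper(channel_names))
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> %d events x %d channels\n",
              nrow(x$values), length(x$channels)))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  scat <- x$channels[x$scatter]
  if (length(scat)) cat("  scatter: ", paste(scat, collapse = ", "), "\n")
  m <- x$meta
  cat(sprintf("  sample=%s instrument=%s center=%s panel=%s date=%s\n",
              m$sample_id, m$instrument_id, m$center_id, m$panel_id,
              format(m$acquisition_date)))
  cat(sprintf("  normalized=%s compensated=%s\n", m$normalized, m$compensated))
  invisible(x)
}

#' Number of events / channels in an event matrix
#' @param em an `event_matrix`.
#' @return integer count.
#' @export
n_events <- function(em) nrow(em$values)

#' @rdname n_events
#' @export
n_channels <- function(em) length(em$channels)

#' Names of the fluorescence (non-scatter) channels
#' @param em an `event_matrix`.
#' @return character vector.
#' @export
fluorescence_channels <- function(em) em$channels[!em$scatter]

# Single-channel accessor used throughout; errors on unknown channels so
# typos surface early.
channel_values <- function(em, channel) {
  idx <- match(channel, em$channels)
  if (is.na(idx)) stop(sprintf("channel '%s' not present", channel))
  em$values[, idx]
}
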