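#' Ordered bead peak MFIs per channel
#'
#' A `peak_set` stores, for every fluorescence channel of a bead
#' acquisition, the mean fluorescence intensities of the 8 rainbow-bead
#' peaks in ascending order (linear scale). One peak set per study is
#' frozen as the reference; every later acquisition is matched to it peak
#' by peak by rank (gain shifts preserve order, so rank matching is the
#' robust choice).
#'
#' @param peaks numeric matrix, `n_peaks` rows x channels (ascending
#'   within each column, all positive).
#' @param n_events_used integer vector, events contributing per channel.
#' @param is_reference logical flag.
#' @param instrument_id,date provenance.
#' @return a `peak_set`.
#' @export
peak_set <- function(peaks, n_events_used = rep(NA_integer_, ncol(peaks)),
                     is_reference = FALSE, instrument_id = NA_character_,
                     date = as.Date(NA)) {
  peaks <- as.matrix(peaks)
  if (is.null(colnames(peaks))) stop("peak matrix must have channel column names")
  if (any(peaks <= 0)) stop("peak MFIs must be positive")
  if (any(apply(peaks, 2L, function(x) any(diff(x) <= 0)))) {
    stop("peak MFIs must be strictly increasing within each channel")
  }
  structure(
    list(peaks = peaks, n_events_used = n_events_used,
         is_reference = is_reference, instrument_id = instrument_id,
         date = date),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks x %d channels (%s%s, %s)\n",
              nrow(x$peaks), ncol(x$peaks),
              if (isTRUE(x$is_reference)) "reference, " else "",
              x$instrument_id, format(x$date)))
  print(round(x$peaks, 1))
  invisible(x)
}

#' Extract rainbow bead peak MFIs from a bead acquisition
#'
#' Events are first debris-filtered with a forward-scatter gate, then
#' each fluorescence channel is partitioned into `n_peaks` clusters by
#' one-dimensional k-means on log10 intensity with quantile-spaced
#' initialization (deterministic; the peaks are well-separated log-normal
#' modes, so no random restarts are needed). The peak MFI is the
#' arithmetic mean of the linear intensities of the cluster members
#' (median available via `stat`), returned ascending.
#'
#' A channel errors when the clusters are not resolvable: any cluster
#' holding fewer than `min_occupancy` of the events, or two cluster
#' centers closer than `min_separation` decades (the signature of a
#' merged or split peak).
#'
#' @param em bead-acquisition [event_matrix()] with at least
#'   `50 * n_peaks` events.
#' @param n_peaks number of bead peaks (8 for rainbow beads).
#' @param stat peak statistic, `"mean"` (default) or `"median"`.
#' @param debris_fsc_min linear FSC below which an event is debris.
#' @param max_debris_frac if the scatter gate removes more than this
#'   fraction of events the file is flagged debris-contaminated (attribute
#'   `debris_contaminated` on the result, plus a warning).
#' @param min_occupancy minimum cluster share of gated events.
#' @param min_separation minimum distance between adjacent cluster
#'   centers, in log10 units.
#' @return a [peak_set()].
#' @export
detect_peaks <- function(em, n_peaks = 8L, stat = c("mean", "median"),
                         debris_fsc_min = 1e4, max_debris_frac = 0.5,
                         min_occupancy = 0.01, min_separation = 0.1) {
  stat <- match.arg(stat)
  stopifnot(inherits(em, "event_matrix"))
  if (n_events(em) < 50L * n_peaks) {
    stop(sprintf("bead acquisition too small: %d events for %d peaks",
                 n_events(em), n_peaks))
  }
  keep <- rep(TRUE, n_events(em))
  fsc_name <- em$channels[em$scatter & grepl("^FS", toupper(em$channels))][1L]
  debris_contaminated <- FALSE
  if (!is.na(fsc_name)) {
    keep <- channel_values(em, fsc_name) >= debris_fsc_min
    removed <- 1 - mean(keep)
    if (removed > max_debris_frac) {
      debris_contaminated <- TRUE
      warning(sprintf("debris-contaminated bead file: scatter gate removed %.0f%% of events",
                      100 * removed))
    }
  }
  fluo <- fluorescence_channels(em)
  if (!length(fluo)) stop("bead acquisition has no fluorescence channels")
  peaks <- matrix(NA_real_, n_peaks, length(fluo),
                  dimnames = list(NULL, fluo))
  for (ch in fluo) {
    x <- channel_values(em, ch)[keep]
    x <- x[x > 0]
    if (length(x) < 50L * n_peaks) {
      stop(sprintf("peak-detection error in channel %s: too few positive events", ch))
    }
    lx <- log10(x)
    centers <- stats::quantile(lx, probs = (seq_len(n_peaks) - 0.5) / n_peaks,
                               names = FALSE)
    if (anyDuplicated(centers)) {
      stop(sprintf("peak-detection error in channel %s: degenerate intensity distribution", ch))
    }
    km <- suppressWarnings(
      stats::kmeans(lx, centers = matrix(centers, ncol = 1L), iter.max = 100L)
    )
    occupancy <- tabulate(km$cluster, nbins = n_peaks) / length(lx)
    if (any(occupancy < min_occupancy)) {
      stop(sprintf("peak-detection error in channel %s: fewer than %d resolvable peaks (cluster occupancy below %.1f%%)",
                   ch, n_peaks, 100 * min_occupancy))
    }
    ord <- order(km$centers[, 1L])
    if (any(diff(sort(km$centers[, 1L])) < min_separation)) {
      stop(sprintf("peak-detection error in channel %s: fewer than %d resolvable peaks (adjacent peaks closer than %.2f decades)",
                   ch, n_peaks, min_separation))
    }
    stat_fun <- if (stat == "mean") mean else stats::median
    mfis <- vapply(ord, function(k) stat_fun(x[km$cluster == k]), numeric(1))
    peaks[, ch] <- mfis
  }
  ps <- peak_set(peaks, n_events_used = rep(sum(keep), length(fluo)),
                 instrument_id = em$meta$instrument_id,
                 date = em$meta$acquisition_date)
  attr(ps, "debris_contaminated") <- debris_contaminated
  ps
}

#' Daily-QC deviation of observed bead peaks from the reference
#'
#' Per-peak percent deviation `100 * |obs - ref| / ref`, matched by rank.
#' The acquisition passes when every deviation is below `limit` (5% by
#' default: the daily-QC acceptance rule for every fluorochrome's peaks).
#'
#' @param obs,ref [peak_set()]s sharing channels and peak count.
#' @param limit pass threshold in percent.
#' @return a `qc_report`: list with `deviation` (matrix, percent),
#'   `pass`, `limit`.
#' @export
qc_deviation <- function(obs, ref, limit = 5) {
  stopifnot(inherits(obs, "peak_set"), inherits(ref, "peak_set"))
  if (nrow(obs$peaks) != nrow(ref$peaks)) {
    stop("observed and reference peak sets have different peak counts")
  }
  if (!setequal(colnames(obs$peaks), colnames(ref$peaks))) {
    stop(sprintf("channel mismatch between observed (%s) and reference (%s)",
                 paste(colnames(obs$peaks), collapse = ","),
                 paste(colnames(ref$peaks), collapse = ",")))
  }
  refm <- ref$peaks[, colnames(obs$peaks), drop = FALSE]
  deviation <- 100 * abs(obs$peaks - refm) / refm
  structure(list(deviation = deviation, pass = all(deviation < limit),
                 limit = limit, instrument_id = obs$instrument_id,
                 date = obs$date),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s (max deviation %.2f%%, limit %g%%)\n",
              if (x$pass) "PASS" else "FAIL", max(x$deviation), x$limit))
  invisible(x)
}

#' Read/write peak sets as CSV
#'
#' Long CSV with columns channel, peak, mfi, n_events_used,
#' instrument_id, date, is_reference — the on-disk store for the frozen
#' reference targets and per-day bead results.
#'
#' @param ps a [peak_set()].
#' @param path CSV path.
#' @return `write_peak_set` the path invisibly; `read_peak_set` a
#'   [peak_set()].
#' @export
write_peak_set <- function(ps, path) {
  stopifnot(inherits(ps, "peak_set"))
  chans <- colnames(ps$peaks)
  df <- data.frame(
    channel = rep(chans, each = nrow(ps$peaks)),
    peak = rep(seq_len(nrow(ps$peaks)), length(chans)),
    mfi = as.vector(ps$peaks),
    n_events_used = rep(ps$n_events_used, each = nrow(ps$peaks)),
    instrument_id = ps$instrument_id,
    date = format(ps$date),
    is_reference = ps$is_reference
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_set
#' @export
read_peak_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  chans <- unique(df$channel)
  n_peaks <- max(df$peak)
  m <- matrix(NA_real_, n_peaks, length(chans), dimnames = list(NULL, chans))
  for (ch in chans) {
    sub <- df[df$channel == ch, ]
    m[sub$peak, ch] <- sub$mfi
  }
  peak_set(m,
           n_events_used = vapply(chans, function(ch)
             as.integer(df$n_events_used[df$channel == ch][1L]), integer(1)),
           is_reference = isTRUE(df$is_reference[1L]),
           instrument_id = as.character(df$instrument_id[1L]),
           date = as.Date(df$date[1L]))
}
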