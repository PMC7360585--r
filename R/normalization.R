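#' Fit per-channel affine normalization from bead peaks
#'
#' For every channel an ordinary least-squares line maps the observed
#' peak MFIs onto the reference peak MFIs:
#' `corrected = alpha * observed + beta`, minimizing
#' `sum_k (alpha * obs_k + beta - ref_k)^2` over the 8 rank-matched peak
#' pairs. Fitting in the observed-to-reference direction means the
#' transform can be applied directly to sample events acquired the same
#' day on the same instrument.
#'
#' Because the 8 peaks span almost three decades, the default regression
#' is weighted by `1/ref^2`, i.e. it minimizes *relative* residuals:
#' with unweighted least squares the bright peaks' sampling noise is
#' free to push the intercept by tens of intensity units, which wrecks
#' the dimmest peak's correction while barely moving the loss. Relative
#' weighting corrects every peak to within its own sampling error. The
#' unweighted fit remains available via `weights = "none"`.
#'
#' A fit is rejected (error, not silently accepted) when `alpha <= 0` or
#' R-squared falls below `min_r_squared` — both signal a corrupted bead
#' run rather than ordinary drift.
#'
#' @param observed [peak_set()] from the day's bead acquisition.
#' @param reference the frozen reference [peak_set()].
#' @param weights `"relative"` (default, weight `1/ref^2`),
#'   `"inverse_reference"` (weight `1/ref`), or `"none"` (ordinary
#'   unweighted least squares).
#' @param min_r_squared fit-quality floor.
#' @return an `affine_transform`: data frame with columns `channel`,
#'   `alpha`, `beta`, `r_squared`, `max_residual_pct`, carrying the bead
#'   provenance as attributes.
#' @export
fit_affine <- function(observed, reference,
                       weights = c("relative", "inverse_reference", "none"),
                       min_r_squared = 0.99) {
  weights <- match.arg(weights)
  stopifnot(inherits(observed, "peak_set"), inherits(reference, "peak_set"))
  chans <- colnames(observed$peaks)
  if (!all(chans %in% colnames(reference$peaks))) {
    stop("reference peak set lacks channels present in the observed set")
  }
  if (nrow(observed$peaks) != nrow(reference$peaks)) {
    stop("observed and reference peak sets have different peak counts")
  }
  rows <- lapply(chans, function(ch) {
    obs <- observed$peaks[, ch]
    ref <- reference$peaks[, ch]
    w <- switch(weights,
                relative = 1 / ref^2,
                inverse_reference = 1 / ref,
                none = rep(1, length(ref)))
    fit <- stats::lm(ref ~ obs, weights = w)
    alpha <- unname(stats::coef(fit)[2L])
    beta <- unname(stats::coef(fit)[1L])
    res <- stats::residuals(fit)
    sst <- sum(w * (ref - stats::weighted.mean(ref, w))^2)
    r2 <- 1 - sum(w * res^2) / sst
    if (!is.finite(alpha) || alpha <= 0) {
      stop(sprintf("fit-quality error in channel %s: alpha = %.4g is not positive", ch, alpha))
    }
    if (r2 < min_r_squared) {
      stop(sprintf("fit-quality error in channel %s: R^2 = %.4f < %.4f", ch, r2, min_r_squared))
    }
    data.frame(channel = ch, alpha = alpha, beta = beta, r_squared = r2,
               max_residual_pct = 100 * max(abs(res) / ref),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("affine_transform", "data.frame"),
            instrument_id = observed$instrument_id, date = observed$date)
}

#' Apply a fitted affine transform to event data
#'
#' Every fluorescence intensity `x` becomes `alpha * x + beta` for its
#' channel; scatter channels are left unchanged (the daily bead QC tracks
#' fluorescence gain, not scatter). Negative corrected values (possible
#' when `beta < 0`) are kept rather than clipped: downstream statistics
#' are means and medians and clipping would bias them.
#'
#' @param em an [event_matrix()].
#' @param transform an `affine_transform` from [fit_affine()] covering
#'   every fluorescence channel of `em`.
#' @return the normalized [event_matrix()]; event count and order are
#'   unchanged and `meta$normalized` is set.
#' @export
apply_affine <- function(em, transform) {
  stopifnot(inherits(em, "event_matrix"), inherits(transform, "affine_transform"))
  fluo <- fluorescence_channels(em)
  missing <- setdiff(fluo, transform$channel)
  if (length(missing)) {
    stop(sprintf("no affine transform for channel(s): %s",
                 paste(missing, collapse = ", ")))
  }
  values <- em$values
  for (ch in fluo) {
    row <- transform[transform$channel == ch, ]
    values[, ch] <- row$alpha * values[, ch] + row$beta
  }
  out <- em
  out$values <- values
  out$meta$normalized <- TRUE
  out
}

#' Serialize affine transforms as JSON
#'
#' The per-channel alpha/beta/R-squared log written next to each
#' normalized file, so every correction is auditable.
#'
#' @param transform an `affine_transform`.
#' @param path JSON path.
#' @return the path (write) / an `affine_transform` (read).
#' @export
write_affine <- function(transform, path) {
  stopifnot(inherits(transform, "affine_transform"))
  payload <- list(
    instrument_id = attr(transform, "instrument_id"),
    date = format(attr(transform, "date")),
    channels = as.data.frame(transform)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(payload$channels,
            class = c("affine_transform", "data.frame"),
            instrument_id = payload$instrument_id,
            date = as.Date(payload$date))
}
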