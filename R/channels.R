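#' Detector-to-marker channel map
#'
#' Vendors name detectors differently ("FL1 INT" on Beckman Coulter,
#' "FITC-A" on BD); downstream code wants marker names. A channel map
#' pairs a matching pattern per canonical channel with the panel's
#' canonical order. Patterns are matched case-insensitively against the
#' whole detector name; the canonical name itself always matches, which
#' makes [standardize_channels()] idempotent.
#'
#' @param canonical character vector of canonical channel names, in
#'   canonical panel order.
#' @param pattern character vector of regular expressions, one per
#'   canonical name (anchored internally).
#' @param scatter logical vector flagging scatter/time channels.
#' @param panel_id panel identifier.
#' @return a `channel_map` data frame.
#' @export
channel_map <- function(canonical, pattern, scatter, panel_id) {
  stopifnot(length(canonical) == length(pattern),
            length(canonical) == length(scatter))
  if (anyDuplicated(canonical)) {
    stop("every canonical name may appear at most once per panel")
  }
  structure(
    data.frame(canonical = canonical, pattern = pattern, scatter = scatter,
               stringsAsFactors = FALSE),
    panel_id = panel_id, class = c("channel_map", "data.frame")
  )
}

#' Built-in channel maps for the two panels
#'
#' Covers the Beckman Coulter dialect (`FS INT`, `SS INT`, `FL1 INT` ...)
#' and the BD dye-name dialect (`FSC-A`, `SSC-A`, `FITC-A` ...), mapping
#' both onto the same canonical marker columns.
#'
#' @param panel_id `"panel1"` or `"panel2"`.
#' @return a [channel_map()].
#' @export
default_channel_map <- function(panel_id = c("panel1", "panel2")) {
  panel_id <- match.arg(panel_id)
  pan <- default_panel(panel_id)
  markers <- pan$markers
  bc <- sprintf("FL%d INT", seq_along(markers))
  bd <- c("FITC-A", "PE-A", "PerCP-Cy5-5-A", "PE-Cy7-A", "APC-A",
          "Alexa Fluor 700-A", "APC-Cy7-A", "Pacific Blue-A")[seq_along(markers)]
  canonical <- pan$channels
  # first alternative is the BC detector name, second the BD name, then
  # the canonical name itself (idempotence)
  pattern <- c(
    "FS INT|FSC-A|FSC|FS PEAK",
    "SS INT|SSC-A|SSC|SS PEAK",
    sprintf("%s|%s|%s", gsub("([().])", "\\\\\\1", bc),
            gsub("([().])", "\\\\\\1", bd),
            gsub("([().-])", "\\\\\\1", markers))
  )
  channel_map(canonical, pattern, pan$scatter, panel_id)
}

#' Rename and reorder channels to a panel's canonical layout
#'
#' Every channel of `em` must match exactly one map entry; channels are
#' renamed to the canonical names and the value columns permuted into the
#' canonical order (channels of the panel absent from the file are simply
#' not present). Unmatched fluorescence detectors are reported by name in
#' the error, so a mislabeled file can be fixed rather than excluded.
#'
#' @param em an [event_matrix()].
#' @param map a [channel_map()].
#' @return the standardized [event_matrix()]; values are bit-identical,
#'   only names/order change. Idempotent.
#' @export
standardize_channels <- function(em, map) {
  stopifnot(inherits(em, "event_matrix"), inherits(map, "channel_map"))
  anchored <- sprintf("^(%s)$", map$pattern)
  hit <- matrix(FALSE, length(em$channels), nrow(map))
  for (j in seq_len(nrow(map))) {
    hit[, j] <- grepl(anchored[j], em$channels, ignore.case = TRUE)
  }
  n_hits <- rowSums(hit)
  if (any(n_hits > 1L)) {
    stop(sprintf("channels match more than one map entry: %s",
                 paste(em$channels[n_hits > 1L], collapse = ", ")))
  }
  if (any(n_hits == 0L)) {
    bad <- em$channels[n_hits == 0L]
    stop(sprintf("mapping error: unmatched detector name(s): %s",
                 paste(bad, collapse = ", ")))
  }
  idx <- apply(hit, 1L, which)            # map row per em channel
  if (anyDuplicated(idx)) {
    stop(sprintf("two detectors map to the same canonical channel: %s",
                 paste(map$canonical[idx[duplicated(idx)]], collapse = ", ")))
  }
  ord <- order(idx)                        # canonical panel order
  values <- em$values[, ord, drop = FALSE]
  canonical <- map$canonical[idx[ord]]
  colnames(values) <- canonical
  meta <- em$meta
  if (is.na(meta$panel_id)) meta$panel_id <- attr(map, "panel_id")
  event_matrix(values, channel_names = canonical,
               scatter = map$scatter[idx[ord]],
               meta = meta, keywords = em$keywords)
}
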