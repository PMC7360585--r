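#' Read an FCS or LMD flow cytometry file
#'
#' Supports FCS 2.0, 3.0 and 3.1 list-mode files with integer, float or
#' double storage, and Beckman Coulter LMD files that concatenate two
#' datasets (an FCS 2.0 segment followed by an FCS 3.0 segment). For
#' multi-dataset files the last dataset is returned by default: on Beckman
#' instruments that is the FCS 3.0 segment carrying the full-resolution
#' data.
#'
#' Log-amplified stored values are linearized at read time using the
#' `$PnE`/`$PnR` keywords: a stored value `v` with `$PnE = "d,f"` and range
#' `r` becomes `f * 10^(d*v/r)` (with `f = 0` treated as 1 per the FCS
#' convention), so downstream code always sees the linear scale.
#'
#' @param path path to an FCS or LMD file.
#' @param dataset which dataset to return from a multi-dataset file:
#'   `"last"` (default), `"first"`, or `"all"` for a list of all datasets.
#' @return an [event_matrix()] (or a list of them for `dataset = "all"`).
#'   Vendor (`"BC"`/`"BD"`) is inferred from the `$CYT` keyword and the
#'   LMD dual-dataset layout; acquisition date is parsed from `$DATE`.
#' @export
read_fcs <- function(path, dataset = c("last", "first", "all")) {
  dataset <- match.arg(dataset)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 58L) stop(sprintf("format error: '%s' is too short to hold an FCS header", path))
  datasets <- list()
  base <- 0L
  n_seg <- 0L
  repeat {
    ds <- parse_fcs_dataset(raw, base, path)
    datasets[[length(datasets) + 1L]] <- ds
    n_seg <- n_seg + 1L
    if (is.na(ds$nextdata) || ds$nextdata <= 0L) break
    base <- base + ds$nextdata
    if (base + 58L > length(raw)) {
      stop(sprintf("format error: $NEXTDATA points past end of file in '%s'", path))
    }
    if (n_seg > 16L) stop("format error: too many chained datasets")
  }
  ems <- lapply(datasets, function(ds) dataset_to_event_matrix(ds, n_seg))
  switch(dataset,
         last = ems[[length(ems)]],
         first = ems[[1L]],
         all = ems)
}

# Parse one dataset starting at byte offset `base` (0-based). Header
# segment offsets are interpreted relative to the dataset start, which is
# the convention this package also writes and matches how chained LMD
# segments are laid out.
parse_fcs_dataset <- function(raw, base, path) {
  hdr <- rawToChar(raw[(base + 1L):(base + 58L)])
  version <- substr(hdr, 1L, 6L)
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1")) {
    stop(sprintf("format error: '%s' does not begin with a valid FCS header (got '%s')",
                 path, version))
  }
  off <- function(i) {
    s <- trimws(substr(hdr, 11L + (i - 1L) * 8L, 10L + i * 8L))
    if (s == "") return(NA_integer_)
    as.integer(s)
  }
  text_beg <- off(1L); text_end <- off(2L)
  data_beg <- off(3L); data_end <- off(4L)
  if (is.na(text_beg) || is.na(text_end) || text_end <= text_beg) {
    stop(sprintf("format error: invalid TEXT segment offsets in '%s'", path))
  }
  text <- rawToChar(raw[(base + text_beg + 1L):(base + text_end + 1L)])
  kw <- parse_fcs_text(text)
  need <- function(name) {
    v <- kw[[name]]
    if (is.null(v)) stop(sprintf("metadata error: '%s' is missing required keyword %s", path, name))
    v
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  if (is.na(n_tot) || n_tot < 1L) {
    stop(sprintf("empty-file error: '%s' contains no events ($TOT = %s)", path, kw[["$TOT"]]))
  }
  pnn <- character(n_par)
  for (i in seq_len(n_par)) pnn[i] <- need(sprintf("$P%dN", i))
  datatype <- need("$DATATYPE")
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2", "1")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop(sprintf("format error: unsupported $BYTEORD '%s'", byteord))
  if (!identical(need("$MODE"), "L")) {
    stop(sprintf("format error: only list mode ($MODE=L) is supported, got '%s'", kw[["$MODE"]]))
  }
  if (is.na(data_beg) || data_beg == 0L) data_beg <- as.integer(need("$BEGINDATA"))
  if (is.na(data_end) || data_end == 0L) data_end <- as.integer(need("$ENDDATA"))
  n_values <- n_par * n_tot
  data_raw <- raw[(base + data_beg + 1L):(base + data_end + 1L)]
  values <- read_fcs_data(data_raw, datatype, kw, n_par, n_values, endian, path)
  mat <- matrix(values, ncol = n_par, byrow = TRUE)
  # linearize log-amplified parameters
  for (i in seq_len(n_par)) {
    pne <- kw[[sprintf("$P%dE", i)]]
    if (is.null(pne)) next
    df <- suppressWarnings(as.numeric(strsplit(pne, ",", fixed = TRUE)[[1L]]))
    if (length(df) != 2L || anyNA(df)) next
    if (df[1L] > 0) {
      r <- as.numeric(kw[[sprintf("$P%dR", i)]])
      f2 <- if (df[2L] == 0) 1 else df[2L]
      mat[, i] <- f2 * 10^(df[1L] * mat[, i] / r)
    }
  }
  nextdata <- suppressWarnings(as.integer(kw[["$NEXTDATA"]]))
  list(version = version, keywords = kw, values = mat, channels = pnn,
       nextdata = if (length(nextdata)) nextdata else NA_integer_)
}

read_fcs_data <- function(data_raw, datatype, kw, n_par, n_values, endian, path) {
  if (datatype == "F") {
    readBin(data_raw, "numeric", n = n_values, size = 4L, endian = endian)
  } else if (datatype == "D") {
    readBin(data_raw, "numeric", n = n_values, size = 8L, endian = endian)
  } else if (datatype == "I") {
    bits <- unique(vapply(seq_len(n_par), function(i) {
      b <- kw[[sprintf("$P%dB", i)]]
      if (is.null(b)) stop(sprintf("metadata error: '%s' is missing $P%dB", path, i))
      as.integer(b)
    }, integer(1)))
    if (length(bits) != 1L || !bits %in% c(8L, 16L, 32L)) {
      stop("format error: integer data requires uniform $PnB of 8, 16 or 32 bits")
    }
    size <- bits / 8L
    if (size == 4L) {
      as.numeric(readBin(data_raw, "integer", n = n_values, size = 4L, endian = endian))
    } else {
      as.numeric(readBin(data_raw, "integer", n = n_values, size = size,
                         signed = FALSE, endian = endian))
    }
  } else {
    stop(sprintf("format error: unsupported $DATATYPE '%s'", datatype))
  }
}

parse_fcs_text <- function(text) {
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1L, length(parts), by = 2L)]))
  vals <- parts[seq(2L, length(parts), by = 2L)]
  stats::setNames(as.list(vals), keys)
}

dataset_to_event_matrix <- function(ds, n_segments) {
  kw <- ds$keywords
  cyt <- kw[["$CYT"]]
  vendor <- NA_character_
  if (!is.null(cyt)) {
    if (grepl("navios|gallios|cytomics|cytoflex", cyt, ignore.case = TRUE)) {
      vendor <- "BC"
    } else if (grepl("canto|fortessa|verse|aria|lsr|facs", cyt, ignore.case = TRUE)) {
      vendor <- "BD"
    }
  }
  if (is.na(vendor) && n_segments > 1L) vendor <- "BC"
  meta <- list(
    instrument_id = kw[["INSTRUMENT_ID"]] %||% NA_character_,
    center_id = kw[["CENTER_ID"]] %||% NA_character_,
    acquisition_date = if (is.null(kw[["$DATE"]])) as.Date(NA) else parse_fcs_date(kw[["$DATE"]]),
    panel_id = kw[["PANEL_ID"]] %||% NA_character_,
    sample_id = kw[["SAMPLE_ID"]] %||% NA_character_,
    vendor = vendor,
    normalized = identical(kw[["NORMALIZED"]], "TRUE"),
    compensated = identical(kw[["COMPENSATED"]], "TRUE")
  )
  event_matrix(ds$values, channel_names = ds$channels, meta = meta,
               keywords = kw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FCS $DATE is dd-mmm-yyyy with an English month abbreviation; ISO dates
# are also accepted. Anything else errors rather than being guessed.
parse_fcs_date <- function(s) {
  s <- trimws(s)
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", s)) return(as.Date(s))
  m <- regmatches(s, regexec("^(\\d{1,2})-([A-Za-z]{3})-(\\d{4})$", s))[[1L]]
  if (length(m) == 4L) {
    mon <- match(toupper(m[3L]), toupper(month.abb))
    if (!is.na(mon)) {
      return(as.Date(sprintf("%s-%02d-%02d", m[4L], mon, as.integer(m[2L]))))
    }
  }
  stop(sprintf("ambiguous or unparseable acquisition date: '%s'", s))
}

format_fcs_date <- function(d) {
  sprintf("%02d-%s-%04d", as.integer(format(d, "%d")),
          toupper(month.abb[as.integer(format(d, "%m"))]),
          as.integer(format(d, "%Y")))
}

#' Write an event matrix to an FCS file
#'
#' Writes list-mode FCS with single-precision float storage by default.
#' Acquisition metadata is stored in keywords (`$DATE`, `$CYT`,
#' `INSTRUMENT_ID`, `CENTER_ID`, `PANEL_ID`, `SAMPLE_ID`, processing
#' flags) so that `read_fcs(write_fcs(em))` round-trips values, channel
#' names and metadata within float32 storage precision.
#'
#' Integer storage with a log amplification keyword (`datatype = "I"` plus
#' `pne`/`pnr`) is supported so legacy log-amplified files can be produced
#' for testing the reader's linearization; in that mode `em$values` are
#' taken as the stored (already amplified) channel values.
#'
#' @param em an [event_matrix()].
#' @param path output path.
#' @param version FCS version string for the header: `"3.1"`, `"3.0"` or
#'   `"2.0"`.
#' @param datatype `"F"` (float32, default) or `"I"` (unsigned integer).
#' @param pne,pnr per-file `$PnE` amplification string and `$PnR` range
#'   applied to every parameter when `datatype = "I"`.
#' @param pnb bits per integer parameter (`datatype = "I"` only).
#' @return the path, invisibly.
#' @export
write_fcs <- function(em, path, version = c("3.1", "3.0", "2.0"),
                      datatype = c("F", "I"), pne = "0,0", pnr = NULL,
                      pnb = 32L) {
  version <- match.arg(version)
  datatype <- match.arg(datatype)
  seg <- build_fcs_dataset(em, version, datatype, pne, pnr, pnb, nextdata = 0L)
  writeBin(seg, path)
  invisible(path)
}

#' Write a dual-dataset LMD-style file
#'
#' Emulates the Beckman Coulter LMD layout: an FCS 2.0 dataset chained via
#' `$NEXTDATA` to an FCS 3.0 dataset in the same file. [read_fcs()]
#' returns the last (FCS 3.0) dataset from such files.
#'
#' @param em_fcs2,em_fcs3 the [event_matrix()] objects for the two
#'   segments.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_lmd <- function(em_fcs2, em_fcs3, path) {
  # fixed-width offsets keep segment length independent of the value
  seg1 <- build_fcs_dataset(em_fcs2, "2.0", "F", "0,0", NULL, 32L, nextdata = 0L)
  seg1 <- build_fcs_dataset(em_fcs2, "2.0", "F", "0,0", NULL, 32L,
                            nextdata = length(seg1))
  seg2 <- build_fcs_dataset(em_fcs3, "3.0", "F", "0,0", NULL, 32L, nextdata = 0L)
  writeBin(c(seg1, seg2), path)
  invisible(path)
}

build_fcs_dataset <- function(em, version, datatype, pne, pnr, pnb, nextdata) {
  stopifnot(inherits(em, "event_matrix"))
  v <- em$values
  n_par <- ncol(v)
  n_tot <- nrow(v)
  size <- if (datatype == "F") 4L else as.integer(pnb) %/% 8L
  n_bytes <- n_par * n_tot * size
  kw <- list()
  kw[["$BEGINANALYSIS"]] <- "0"; kw[["$ENDANALYSIS"]] <- "0"
  kw[["$BEGINSTEXT"]] <- "0"; kw[["$ENDSTEXT"]] <- "0"
  kw[["$BEGINDATA"]] <- sprintf("%08d", 0L)  # patched below
  kw[["$ENDDATA"]] <- sprintf("%08d", 0L)
  kw[["$NEXTDATA"]] <- sprintf("%08d", nextdata)
  kw[["$BYTEORD"]] <- "1,2,3,4"
  kw[["$DATATYPE"]] <- datatype
  kw[["$MODE"]] <- "L"
  kw[["$PAR"]] <- as.character(n_par)
  kw[["$TOT"]] <- as.character(n_tot)
  for (i in seq_len(n_par)) {
    kw[[sprintf("$P%dN", i)]] <- em$channels[i]
    kw[[sprintf("$P%dB", i)]] <- as.character(if (datatype == "F") 32L else as.integer(pnb))
    kw[[sprintf("$P%dE", i)]] <- if (datatype == "F") "0,0" else pne
    kw[[sprintf("$P%dR", i)]] <- as.character(
      if (!is.null(pnr)) pnr else max(1024, ceiling(max(v[, i], 1))))
  }
  m <- em$meta
  if (!is.na(m$acquisition_date)) kw[["$DATE"]] <- format_fcs_date(m$acquisition_date)
  cyt <- em$keywords[["$CYT"]]
  if (is.null(cyt) && !is.na(m$vendor)) {
    cyt <- if (m$vendor == "BC") "Navios" else "LSRFortessa"
  }
  if (!is.null(cyt)) kw[["$CYT"]] <- cyt
  if (!is.na(m$instrument_id)) kw[["INSTRUMENT_ID"]] <- m$instrument_id
  if (!is.na(m$center_id)) kw[["CENTER_ID"]] <- m$center_id
  if (!is.na(m$panel_id)) kw[["PANEL_ID"]] <- m$panel_id
  if (!is.na(m$sample_id)) kw[["SAMPLE_ID"]] <- m$sample_id
  kw[["NORMALIZED"]] <- as.character(isTRUE(m$normalized))
  kw[["COMPENSATED"]] <- as.character(isTRUE(m$compensated))
  if (!is.null(em$keywords[["$SPILLOVER"]])) {
    kw[["$SPILLOVER"]] <- em$keywords[["$SPILLOVER"]]
  }
  delim <- "/"
  if (any(grepl(delim, unlist(kw), fixed = TRUE))) {
    stop("keyword values may not contain the TEXT delimiter '/'")
  }
  render_text <- function(kw) {
    paste0(delim, paste0(names(kw), delim, unlist(kw), delim, collapse = ""))
  }
  text <- render_text(kw)
  text_beg <- 58L
  text_end <- text_beg + nchar(text) - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + n_bytes - 1L
  if (data_end > 99999999) stop("dataset too large for 8-digit FCS header offsets")
  kw[["$BEGINDATA"]] <- sprintf("%08d", data_beg)
  kw[["$ENDDATA"]] <- sprintf("%08d", data_end)
  text <- render_text(kw)
  stopifnot(nchar(text) == text_end - text_beg + 1L)
  header <- sprintf("FCS%s    %8d%8d%8d%8d%8d%8d", version,
                    text_beg, text_end, data_beg, data_end, 0L, 0L)
  stopifnot(nchar(header) == 58L)
  flat <- as.vector(t(v))
  data_raw <- if (datatype == "F") {
    writeBin(flat, raw(), size = 4L, endian = "little")
  } else {
    writeBin(as.integer(round(flat)), raw(), size = as.integer(pnb) / 8L,
             endian = "little")
  }
  stopifnot(length(data_raw) == n_bytes)
  c(charToRaw(header), charToRaw(text), data_raw)
}
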