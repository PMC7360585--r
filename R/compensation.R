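#' Spillover matrix
#'
#' Square matrix over the fluorescence channels; entry (i, j) is the
#' fraction of channel-i signal detected in channel j. Diagonal must be
#' 1, off-diagonals in [0, 1). Compensation multiplies event rows by the
#' inverse: `compensated = observed %*% solve(S)`.
#'
#' @param m square numeric matrix.
#' @param channels channel order (defaults to `colnames(m)`).
#' @return a validated `spillover_matrix`.
#' @export
spillover_matrix <- function(m, channels = colnames(m)) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("spillover matrix must be square")
  if (is.null(channels)) stop("spillover matrix needs channel names")
  if (any(abs(diag(m) - 1) > 1e-12)) stop("spillover diagonal must be 1")
  off <- m[row(m) != col(m)]
  if (any(off < 0 | off >= 1)) stop("off-diagonal spillover must be in [0, 1)")
  dimnames(m) <- list(channels, channels)
  structure(m, class = c("spillover_matrix", "matrix", "array"))
}

#' Parse / format the FCS $SPILLOVER keyword
#'
#' Comma-separated FCS 3.1 convention: `n, name1..namen, v11..vnn`
#' (row-major).
#'
#' @param s keyword string.
#' @return a [spillover_matrix()].
#' @export
parse_spillover <- function(s) {
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
  n <- as.integer(parts[1L])
  if (is.na(n) || length(parts) != 1L + n + n * n) {
    stop("malformed $SPILLOVER keyword")
  }
  channels <- parts[2L:(1L + n)]
  vals <- as.numeric(parts[(2L + n):length(parts)])
  spillover_matrix(matrix(vals, n, n, byrow = TRUE,
                          dimnames = list(channels, channels)))
}

#' @rdname parse_spillover
#' @param S a [spillover_matrix()].
#' @export
format_spillover <- function(S) {
  paste(c(ncol(S), colnames(S), format(t(S), trim = TRUE, digits = 15)),
        collapse = ",")
}

#' Apply spillover compensation to event data
#'
#' Row-vector convention: `compensated = observed %*% solve(S)` on the
#' fluorescence channels; scatter is untouched. When `S` is omitted it is
#' taken from the file's `$SPILLOVER` keyword (keyword takes precedence
#' over configuration by design, since it travels with the acquisition).
#'
#' @param em an [event_matrix()].
#' @param S a [spillover_matrix()] whose channels match `em`'s
#'   fluorescence channels (any order; reordered internally), or `NULL`
#'   to read the `$SPILLOVER` keyword.
#' @param max_condition reject matrices with 2-norm condition number
#'   above this (ill-conditioned compensation amplifies noise).
#' @return the compensated [event_matrix()], `meta$compensated` set.
#' @export
apply_compensation <- function(em, S = NULL, max_condition = 1e6) {
  stopifnot(inherits(em, "event_matrix"))
  if (is.null(S)) {
    kwd <- em$keywords[["$SPILLOVER"]]
    if (is.null(kwd)) stop("no spillover matrix given and no $SPILLOVER keyword present")
    S <- parse_spillover(kwd)
  }
  fluo <- fluorescence_channels(em)
  if (!setequal(colnames(S), fluo)) {
    stop(sprintf("spillover channels (%s) do not match fluorescence channels (%s)",
                 paste(colnames(S), collapse = ","), paste(fluo, collapse = ",")))
  }
  S <- S[fluo, fluo]
  cn <- kappa(S, exact = TRUE)
  if (!is.finite(cn) || cn > max_condition) {
    stop(sprintf("spillover matrix is singular or ill-conditioned (condition number %.3g)", cn))
  }
  values <- em$values
  values[, fluo] <- values[, fluo, drop = FALSE] %*% solve(S)
  out <- em
  out$values <- values
  out$meta$compensated <- TRUE
  out
}

#' Residual-spill diagnostic after compensation
#'
#' Quantifies what an operator judges visually when verifying a
#' compensation matrix: whether events bright in a primary channel drag
#' the secondary channel with them. Returns the slope of the secondary
#' medians against the primary medians between the bright (masked) and
#' dim (unmasked) groups; adequate compensation gives a slope near zero,
#' a positive slope means under-compensation by about that fraction.
#'
#' The 0.01 flag threshold used by the pipeline is a repository
#' convention, not a published criterion.
#'
#' @param em compensated [event_matrix()].
#' @param primary,secondary channel names.
#' @param positives logical event mask selecting events bright in the
#'   primary channel.
#' @param min_positives below this many masked events the result is
#'   inconclusive (flag, not an error).
#' @return list with `slope`, `conclusive`, `n_bright`, `n_dim`.
#' @export
residual_spill <- function(em, primary, secondary, positives,
                           min_positives = 50L) {
  stopifnot(inherits(em, "event_matrix"), is.logical(positives),
            length(positives) == n_events(em))
  n_bright <- sum(positives)
  n_dim <- sum(!positives)
  if (n_bright < min_positives || n_dim < min_positives) {
    return(list(slope = NA_real_, conclusive = FALSE,
                n_bright = n_bright, n_dim = n_dim))
  }
  p <- channel_values(em, primary)
  s <- channel_values(em, secondary)
  dp <- stats::median(p[positives]) - stats::median(p[!positives])
  ds <- stats::median(s[positives]) - stats::median(s[!positives])
  list(slope = ds / dp, conclusive = TRUE,
       n_bright = n_bright, n_dim = n_dim)
}
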