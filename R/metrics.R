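#' Coefficient of variation (percent)
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation —
#' the harmonization quality metric used throughout: between corrected
#' and reference bead peaks, between re-acquisitions of a sample, and
#' between instruments. Scale-invariant: `cv(c*x) = cv(x)` for `c > 0`.
#'
#' @param values numeric vector of positives, length at least 2.
#' @return CV in percent.
#' @export
cv <- function(values) {
  if (length(values) < 2L) stop("cv requires at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("cv requires a positive mean")
  100 * stats::sd(values) / m
}

#' Center-effect diagnostic by principal component analysis
#'
#' Standardizes (z-scores) the chosen feature block, decomposes it by
#' PCA (SVD via `prcomp`), and summarizes how strongly centers separate
#' in the first two components: the separability score is the
#' between-center share of the total variance of the PC1-2 scores
#' (0 = centers indistinguishable, 1 = perfectly separated). Signs are
#' fixed by making each component's largest-magnitude loading positive,
#' so the decomposition is deterministic.
#'
#' @param tab a [cohort_table()] with at least 2 centers of at least 3
#'   samples each.
#' @param features `"mfi"` or `"freq"`: which feature block to analyze.
#' @param group_col grouping column (default `"center_id"`).
#' @return list with `scores` (n x 2), `explained_variance` (fraction
#'   per component), `separability`, `groups`, `dropped` (constant
#'   features removed, with a warning).
#' @export
center_effect_pca <- function(tab, features = c("mfi", "freq"),
                              group_col = "center_id") {
  features <- match.arg(features)
  stopifnot(inherits(tab, "cohort_table"))
  groups <- as.character(tab[[group_col]])
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 3L)) {
    stop("center-effect PCA needs at least 2 centers with at least 3 samples each")
  }
  cols <- if (features == "mfi") mfi_columns(tab) else freq_columns(tab)
  x <- as.matrix(as.data.frame(tab)[, cols, drop = FALSE])
  keep <- apply(x, 2L, function(col) stats::sd(col, na.rm = TRUE) > 0) &
    colSums(is.na(x)) == 0L
  dropped <- cols[!keep]
  if (length(dropped)) {
    warning(sprintf("dropping constant or incomplete feature(s): %s",
                    paste(utils::head(dropped, 5L), collapse = ", ")))
  }
  x <- scale(x[, keep, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- pc$x[, 1:2, drop = FALSE]
  centered <- scale(scores, scale = FALSE)
  ss_total <- sum(centered^2)
  grand <- colMeans(scores)
  ss_between <- sum(vapply(names(sizes), function(g) {
    mu <- colMeans(scores[groups == g, , drop = FALSE])
    sizes[[g]] * sum((mu - grand)^2)
  }, numeric(1)))
  list(scores = scores,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2),
       separability = if (ss_total > 0) ss_between / ss_total else 0,
       groups = groups, dropped = dropped)
}

#' Median-equality test across instruments
#'
#' After the instrument correction the per-instrument medians of every
#' marker should be statistically indistinguishable; this is checked per
#' feature with a Kruskal-Wallis test across instruments (the aligned
#' statistic is a median, so a rank test is the natural choice; the
#' specific test is a package convention).
#'
#' @param tab a [cohort_table()].
#' @param columns feature columns to test (default: all `mfi.*`).
#' @param group_col grouping column (default `"instrument_id"`).
#' @param min_per_group features are only tested when at least 2 groups
#'   have at least this many non-missing samples; otherwise the feature
#'   is flagged not-computed.
#' @return data frame with `feature`, `p_value`, `computed`.
#' @export
median_equality_test <- function(tab, columns = NULL,
                                 group_col = "instrument_id",
                                 min_per_group = 3L) {
  stopifnot(inherits(tab, "cohort_table"))
  if (is.null(columns)) columns <- mfi_columns(tab)
  groups <- factor(tab[[group_col]])
  rows <- lapply(columns, function(f) {
    x <- tab[[f]]
    ok <- !is.na(x)
    n_ok <- table(groups[ok])
    if (sum(n_ok >= min_per_group) < 2L) {
      return(data.frame(feature = f, p_value = NA_real_, computed = FALSE))
    }
    p <- stats::kruskal.test(x[ok], droplevels(groups[ok]))$p.value
    data.frame(feature = f, p_value = p, computed = TRUE)
  })
  do.call(rbind, rows)
}
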