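# Percentile Winsorization for per-core staining-feature alignment.
#
# Multiplexed cores imaged on one slide can differ strongly in intensity
# (fixation, antibody binding), which shifts whole feature distributions
# between cores. Clamping each feature to its own core's [P10, P90] and
# rescaling that interval to [0, 1] removes any positive affine shift
# between cores exactly, because percentiles are affine-equivariant.

#' Winsorize a numeric vector to percentile bounds
#'
#' Computes the `p_low`-th and `p_high`-th percentiles (linear interpolation
#' between order statistics, [stats::quantile()] type 7) over the
#' non-missing values, clamps every value into that interval, and, when
#' `rescale = TRUE` (default), maps it affinely so the lower percentile
#' becomes 0 and the upper 1. Missing values pass through unchanged;
#' output order matches input order.
#'
#' With `rescale = FALSE` this is textbook Winsorization (pure clamping).
#' Rescaling is the default because clamping alone cannot align feature
#' spaces that differ by an affine intensity shift.
#'
#' @param x Numeric vector with at least 2 non-missing values.
#' @param p_low,p_high Percentile ranks, `0 <= p_low < p_high <= 100`
#'   (defaults 10 and 90).
#' @param rescale Map `[P_low, P_high]` to `[0, 1]` after clamping?
#' @return Numeric vector of the same length. If the two percentiles
#'   coincide (constant feature) all non-missing values become 0, with a
#'   warning.
#' @examples
#' winsorize(0:100)[c(1, 51, 101)]  # 0, 0.5, 1
#' @export
winsorize <- function(x, p_low = 10, p_high = 90, rescale = TRUE) {
  if (!is.numeric(p_low) || !is.numeric(p_high) ||
      length(p_low) != 1L || length(p_high) != 1L ||
      !(p_low >= 0 && p_low < p_high && p_high <= 100))
    stop_validation("need 0 <= p_low < p_high <= 100")
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop_validation("winsorize() needs at least 2 non-missing values")
  q <- stats::quantile(x[ok], probs = c(p_low, p_high) / 100, names = FALSE, type = 7)
  if (q[1] == q[2]) {
    warning("constant feature within [P_low, P_high]; all values set to 0")
    x[ok] <- 0
    return(x)
  }
  v <- pmin(pmax(x[ok], q[1]), q[2])
  if (rescale) v <- (v - q[1]) / (q[2] - q[1])
  x[ok] <- v
  x
}

feature_columns <- function(features, id_col, sample_col) {
  fc <- setdiff(names(features), c(id_col, sample_col))
  fc <- fc[vapply(features[fc], is.numeric, logical(1))]
  if (length(fc) == 0L) stop_validation("no numeric feature columns found")
  fc
}

#' Normalize a feature table by per-sample Winsorization
#'
#' Applies [winsorize()] independently to every numeric feature column and,
#' when `per_sample = TRUE` (default), independently within every
#' `sample`/core group, so each core is anchored to its own percentiles -
#' this is what aligns cores whose intensities differ by an affine shift.
#' Row order and table shape are preserved; missing values stay missing.
#' Sample groups with fewer than 2 rows pass through unchanged with a
#' warning.
#'
#' @param features A data frame with an id column, a sample column and one
#'   or more numeric feature columns (see [read_feature_table()]).
#' @inheritParams winsorize
#' @param per_sample Winsorize within each sample separately (default) or
#'   globally over the whole table.
#' @param id_col,sample_col Column names (defaults `"id"`, `"sample"`).
#' @return The normalized table, same dimensions and order.
#' @export
normalize_features <- function(features, p_low = 10, p_high = 90, rescale = TRUE,
                               per_sample = TRUE, id_col = "id", sample_col = "sample") {
  if (!is.data.frame(features)) stop_validation("'features' must be a data.frame")
  if (per_sample && !sample_col %in% names(features))
    stop_format("missing required column(s): %s", sample_col)
  fc <- feature_columns(features, id_col, sample_col)
  groups <- if (per_sample) split(seq_len(nrow(features)), features[[sample_col]])
            else list(seq_len(nrow(features)))
  out <- features
  for (idx in groups) {
    if (length(idx) < 2L) {
      warning(sprintf("sample group with %d row(s) passed through unnormalized", length(idx)))
      next
    }
    for (f in fc) out[[f]][idx] <- winsorize(features[[f]][idx], p_low, p_high, rescale)
  }
  out
}

# Two-sample Kolmogorov-Smirnov distance; ties are fine for the statistic.
ks_stat <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}

#' Quantify feature-space alignment between two cores
#'
#' Replaces the visual check of an embedding viewer with numbers: for each
#' feature, the two-sample Kolmogorov-Smirnov statistic between the two
#' sample groups before and after normalization. A statistic near 0 means
#' the two cores' feature distributions coincide; 1 means disjoint support.
#'
#' @param before,after Feature tables with identical shape and exactly two
#'   sample groups (e.g. the input and output of [normalize_features()]).
#' @inheritParams normalize_features
#' @return A data frame with columns `feature`, `ks_before`, `ks_after`,
#'   `improved`, plus attribute `fraction_improved`.
#' @export
alignment_report <- function(before, after, id_col = "id", sample_col = "sample") {
  for (tb in list(before, after))
    if (!is.data.frame(tb) || !sample_col %in% names(tb))
      stop_validation("alignment_report() needs data frames with a '%s' column", sample_col)
  if (!identical(dim(before), dim(after)))
    stop_validation("'before' and 'after' must have identical shape")
  samples <- unique(before[[sample_col]])
  if (length(samples) != 2L)
    stop_validation("alignment_report() requires exactly 2 sample groups, found %d",
                    length(samples))
  fc <- feature_columns(before, id_col, sample_col)
  g1 <- before[[sample_col]] == samples[1]
  res <- data.frame(
    feature = fc,
    ks_before = vapply(fc, function(f) ks_stat(before[[f]][g1], before[[f]][!g1]), 0),
    ks_after = vapply(fc, function(f) ks_stat(after[[f]][g1], after[[f]][!g1]), 0),
    row.names = NULL)
  res$improved <- res$ks_after < res$ks_before
  structure(res, fraction_improved = mean(res$improved))
}
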