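# Preprocessing of continuous expression matrices -- outlier winsorization,
# quantile normalization, gene standardization -- plus the RNA-seq count
# filter. Counts are never quantile-normalized: the count filter is the only
# count-space step.

#' Winsorize per-sample outliers
#'
#' Per sample (column), values below the `winsor_low` or above the
#' `winsor_high` empirical quantile (linear-interpolation, type 7) are clamped
#' to those quantiles. Bounds `(0, 1)` leave the matrix unchanged.
#'
#' @param mat continuous genes x samples matrix.
#' @param winsor_low,winsor_high quantile bounds, `0 <= low < high <= 1`.
#' @return matrix of the same dimensions.
#' @export
winsorize_outliers <- function(mat, winsor_low = 0.01, winsor_high = 0.99) {
  check_expression_matrix(mat)
  if (!(winsor_low >= 0 && winsor_low < winsor_high && winsor_high <= 1)) {
    param_error("need 0 <= winsor_low < winsor_high <= 1")
  }
  out <- apply(mat, 2, function(x) {
    q <- quantile(x, c(winsor_low, winsor_high), type = 7, names = FALSE)
    pmin(pmax(x, q[1]), q[2])
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Quantile-normalize a matrix so all columns share one distribution
#'
#' Every column's sorted values become the across-column mean of order
#' statistics (the reference distribution). Ties within a column receive the
#' mean of the reference values they span, so tied inputs stay tied. The
#' operation is idempotent. A single-column matrix is returned unchanged with
#' a warning.
#'
#' @param mat continuous genes x samples matrix.
#' @return normalized matrix, same dimensions and dimnames.
#' @export
quantile_normalize <- function(mat) {
  check_expression_matrix(mat)
  if (ncol(mat) < 2) {
    warning("quantile_normalize: single-sample matrix left unchanged")
    return(mat)
  }
  sorted <- apply(mat, 2, sort)
  ref <- rowMeans(sorted)
  cs <- c(0, cumsum(ref))
  out <- apply(mat, 2, function(x) {
    # a run of tied values spans ranks [r_min, r_max]; each member receives
    # the mean of the reference values over that whole span
    r_min <- rank(x, ties.method = "min")
    r_max <- rank(x, ties.method = "max")
    (cs[r_max + 1] - cs[r_min]) / (r_max - r_min + 1)
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Standardize each gene row to mean 0, sample SD 1
#'
#' Zero-variance rows are mapped to all zeros rather than dividing by zero.
#'
#' @param mat continuous genes x samples matrix.
#' @return standardized matrix.
#' @export
standardize_genes <- function(mat) {
  check_expression_matrix(mat)
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  out <- (mat - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  dimnames(out) <- dimnames(mat)
  out
}

#' Filter lowly-expressed genes from a count matrix
#'
#' Retains exactly the genes with at least `min_count` counts in at least
#' `min_samples` samples (both boundaries inclusive); row order is preserved.
#'
#' @param count_matrix non-negative integer genes x samples matrix.
#' @param min_count minimal count (default 5).
#' @param min_samples minimal number of samples reaching it (default 8).
#' @return the retained submatrix, with attribute `removed_genes`.
#' @export
filter_low_counts <- function(count_matrix, min_count = 5, min_samples = 8) {
  check_expression_matrix(count_matrix, "count_matrix")
  if (any(count_matrix < 0) || any(count_matrix != round(count_matrix))) {
    param_error("count_matrix must contain non-negative integers")
  }
  if (min_samples > ncol(count_matrix)) {
    param_error("min_samples exceeds the number of samples")
  }
  keep <- rowSums(count_matrix >= min_count) >= min_samples
  out <- count_matrix[keep, , drop = FALSE]
  attr(out, "removed_genes") <- rownames(count_matrix)[!keep]
  log_msg("filter_low_counts: kept %d / %d genes", sum(keep), length(keep))
  out
}

#' Run the full continuous-matrix preprocessing chain
#'
#' Winsorize per-sample outliers, quantile-normalize across samples, then
#' standardize each gene, in that fixed order.
#'
#' @param mat continuous genes x samples matrix.
#' @param winsor_low,winsor_high winsorization bounds (see
#'   [winsorize_outliers()]); `NULL` skips the step.
#' @param quantile_norm,standardize logical switches for the two later steps.
#' @return preprocessed matrix.
#' @export
preprocess_matrix <- function(mat, winsor_low = 0.01, winsor_high = 0.99,
                              quantile_norm = TRUE, standardize = TRUE) {
  if (!is.null(winsor_low)) {
    mat <- winsorize_outliers(mat, winsor_low, winsor_high)
  }
  if (quantile_norm) mat <- quantile_normalize(mat)
  if (standardize) mat <- standardize_genes(mat)
  mat
}
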