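#' Log2-transform an expression matrix
#'
#' @param x An [expression_matrix()] of raw intensities.
#' @param offset Non-negative constant added before taking logs. The default
#'   of 0 errors on non-positive intensities rather than silently producing
#'   non-finite values; pass e.g. `offset = 1` for count-like data.
#' @return An [expression_matrix()] of log2 intensities.
#' @export
log2_transform <- function(x, offset = 0) {
  stopifnot(inherits(x, "expression_matrix"))
  if (offset < 0) stop("`offset` must be >= 0")
  v <- x$values + offset
  if (any(v <= 0))
    stop("matrix contains values <= 0 after adding offset ", offset,
         "; supply a positive `offset`")
  expression_matrix(log2(v), pairs = x$pairs)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the common reference distribution: the
#' row-wise mean of the per-column sorted values. After normalization all
#' columns have identical sorted values; tied entries within a column
#' receive the mean of the reference values at their tied positions. Gene
#' order is preserved and the operation is idempotent. Normalization is
#' delegated to [limma::normalizeQuantiles()], whose tie convention matches
#' this contract.
#'
#' @param x An [expression_matrix()] with at least 2 samples; a single
#'   sample is returned unchanged with a warning.
#' @return The normalized [expression_matrix()].
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (ncol(x$values) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(x)
  }
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  expression_matrix(v, pairs = x$pairs)
}

#' Filter genes by signal-to-noise ratio
#'
#' Keeps genes whose best (maximum) SNR across samples satisfies the keep
#' rule. The conventional reading of "robustly expressed" retains genes with
#' SNR at or above the threshold (`"at_least_threshold"`, the default); the
#' inverted rule `"below_threshold"` is provided for data processed under
#' the opposite convention. Retained genes keep their original order.
#'
#' @param x An [expression_matrix()] of raw (linear-scale) intensities.
#' @param noise Positive per-sample noise estimates, one per column (a named
#'   vector is matched to sample names).
#' @param threshold Positive SNR threshold (default 2).
#' @param keep `"at_least_threshold"` keeps genes with max SNR >= threshold;
#'   `"below_threshold"` keeps genes with max SNR < threshold.
#' @return The filtered [expression_matrix()].
#' @export
snr_filter <- function(x, noise, threshold = 2,
                       keep = c("at_least_threshold", "below_threshold")) {
  stopifnot(inherits(x, "expression_matrix"))
  keep <- match.arg(keep)
  if (threshold <= 0) stop("`threshold` must be > 0")
  sid <- colnames(x$values)
  if (!is.null(names(noise))) {
    if (!all(sid %in% names(noise)))
      stop("`noise` is missing samples: ",
           paste(setdiff(sid, names(noise)), collapse = ", "))
    noise <- noise[sid]
  }
  if (length(noise) != ncol(x$values))
    stop("`noise` must supply one value per sample")
  if (any(!is.finite(noise)) || any(noise <= 0))
    stop("`noise` values must be positive and finite")
  snr <- sweep(x$values, 2, noise, "/")
  best <- apply(snr, 1, max)
  sel <- if (keep == "at_least_threshold") best >= threshold else best < threshold
  expression_matrix(x$values[sel, , drop = FALSE], pairs = x$pairs)
}
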