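#' Log2-transform a linear-scale matrix
#'
#' `v -> log2(v + offset)`. Refuses matrices already flagged as log scale
#' and matrices containing negative values.
#'
#' @param x an `ExpressionMatrix` on the linear scale.
#' @param offset nonnegative pseudo-count added before the log (default 1).
#' @return the transformed `ExpressionMatrix` with `log_scale = TRUE`.
#' @export
log2_transform <- function(x, offset = 1) {
  if (is_log_scale(x)) {
    stop("matrix is already on the log2 scale", call. = FALSE)
  }
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0) {
    stop("`offset` must be a single nonnegative number", call. = FALSE)
  }
  if (any(unclass(x) < 0)) {
    stop("negative values cannot be log-transformed", call. = FALSE)
  }
  expression_matrix(log2(unclass(x) + offset), rownames(x), colnames(x),
                    log_scale = TRUE)
}

#' Quantile-normalize samples
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' mean across samples of the column-sorted values. Ties within a sample
#' receive the mean of the normalized values they span, so the map is
#' deterministic, rank-preserving for tie-free data, and idempotent.
#' (limma's `normalizeQuantiles` interpolates at the average rank, which
#' differs for ties spanning more than two ranks, so the rule is
#' implemented here directly.)
#'
#' @param x an `ExpressionMatrix` with at least 2 samples.
#' @return the normalized `ExpressionMatrix`.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2L) {
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  }
  expression_matrix(quantile_normalize_ref(unclass(x)),
                    rownames(x), colnames(x), log_scale = is_log_scale(x))
}

# Target distribution = row means of the column-sorted matrix; tied input
# values get the mean target value over the ranks they occupy.
quantile_normalize_ref <- function(v) {
  target <- rowMeans(apply(v, 2L, sort))
  out <- v
  for (j in seq_len(ncol(v))) {
    o <- order(v[, j])
    out[o, j] <- stats::ave(target, match(v[o, j], unique(v[o, j])),
                            FUN = mean)
  }
  out
}
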