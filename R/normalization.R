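#' Log2-transform an intensity matrix
#'
#' @param X an `IntensityMatrix` on the linear scale; all present values must
#'   be strictly positive (zeros are expected to have been converted to
#'   missing at read time).
#' @return the matrix on the log2 scale; missing cells stay missing.
#' @export
to_log2 <- function(X) {
  stopifnot(inherits(X, "IntensityMatrix"))
  if (X$scale != "linear") stop("matrix is already on the log2 scale")
  v <- X$values
  if (any(v[!is.na(v)] <= 0))
    stop("present values must be > 0 for log2 transform; convert zeros to missing first")
  X$values <- log2(v)
  X$scale <- "log2"
  X
}

#' Inverse of [to_log2()]
#' @param X an `IntensityMatrix` on the log2 scale
#' @return the matrix on the linear scale
#' @export
to_linear <- function(X) {
  stopifnot(inherits(X, "IntensityMatrix"))
  if (X$scale != "log2") stop("matrix is already on the linear scale")
  X$values <- 2^X$values
  X$scale <- "linear"
  X
}

#' Global normalization of per-sample abundance scales
#'
#' Removes per-sample scale biases (loading/acquisition differences) so
#' fold changes and tests compare like with like. The default aligns every
#' sample's median of present log2 intensities to the grand median of the
#' pre-normalization sample medians; the `"total"` method aligns each
#' sample's log2 total (summed linear) intensity instead. Missing values are
#' excluded from the statistics and are untouched by the shift, so the
#' procedure is idempotent and rank-preserving within each sample.
#'
#' @param X an `IntensityMatrix` on the log2 scale.
#' @param method `"median"` (default) or `"total"`.
#' @return list with `matrix` (normalized `IntensityMatrix`) and `report`
#'   (data.frame: `sample`, `offset_log2` added to each cell,
#'   `n_features_used`).
#' @export
global_normalize <- function(X, method = c("median", "total")) {
  stopifnot(inherits(X, "IntensityMatrix"))
  method <- match.arg(method)
  if (X$scale != "log2") stop("global_normalize expects a log2-scale matrix")
  v <- X$values
  if (ncol(v) < 2) stop("need at least 2 samples to normalize")
  n_used <- colSums(!is.na(v))
  empty <- colnames(v)[n_used == 0]
  if (length(empty))
    stop("sample(s) with no present values: ", paste(empty, collapse = ", "))
  stat <- switch(method,
    median = apply(v, 2, stats::median, na.rm = TRUE),
    total  = log2(colSums(2^v, na.rm = TRUE)))
  offset <- stats::median(stat) - stat
  X$values <- sweep(v, 2, offset, `+`)
  report <- data.frame(sample = colnames(v), offset_log2 = unname(offset),
                       n_features_used = unname(n_used),
                       stringsAsFactors = FALSE)
  list(matrix = X, report = report)
}
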