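#' Median-center the columns of a matrix
#'
#' Subtracts each column's median so every column has median exactly zero.
#' Applied to Mock replicates before any averaging: on the log scale an
#' array-wide multiplicative factor is an additive constant, and centering
#' removes it (the second clause of the shift-invariance property).
#'
#' @param m Numeric matrix with at least one row.
#' @return Matrix of the same shape with column medians zero.
#' @export
median_center <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 0) stop("cannot median-center an empty matrix", call. = FALSE)
  sweep(m, 2, apply(m, 2, stats::median))
}

#' Build the Mock background model
#'
#' Median-centers each Mock replicate, averages them into the mean Mock
#' profile (`mock_bar`), and computes every leave-one-out average
#' (`loo_bars`), i.e. for each Mock replicate the mean of the *other*
#' centered Mocks. The leave-one-out averages let each Mock be normalized
#' as if it were an IP replicate, which is how the selection bias of the
#' background-set estimator is measured.
#'
#' @param mocks Numeric matrix, genes x Mock replicates (n_mock >= 1;
#'   >= 2 whenever `loo_bars` will be consumed).
#' @return A list of class `mock_model` with elements `centered_mocks`,
#'   `mock_bar`, `loo_bars` (genes x n_mock matrix, or `NULL` when
#'   n_mock == 1) and `n_mock`.
#' @examples
#' mm <- build_mock_model(matrix(rnorm(30), 10, 3))
#' stopifnot(abs(apply(mm$centered_mocks, 2, median)) < 1e-12)
#' @export
build_mock_model <- function(mocks) {
  mocks <- as.matrix(mocks)
  if (ncol(mocks) == 0) stop("at least one Mock replicate required",
                             call. = FALSE)
  centered <- median_center(mocks)
  n_mock <- ncol(centered)
  mock_bar <- rowMeans(centered)
  loo_bars <- NULL
  if (n_mock >= 2) {
    # n * mock_bar = (n-1) * loo_bar_j + mock_j, so loo falls out of totals
    tot <- mock_bar * n_mock
    loo_bars <- (tot - centered) / (n_mock - 1)
    colnames(loo_bars) <- colnames(centered)
  }
  structure(list(centered_mocks = centered, mock_bar = mock_bar,
                 loo_bars = loo_bars, n_mock = n_mock),
            class = "mock_model")
}

#' @export
print.mock_model <- function(x, ...) {
  cat(sprintf("mock_model: %d genes, %d Mock replicate(s)\n",
              length(x$mock_bar), x$n_mock))
  invisible(x)
}
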