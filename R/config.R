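#' Analysis configuration
#'
#' Bundles the tunable parameters shared by normalization, background-set
#' size selection and target calling. Defaults follow the package's
#' genome-scale assumptions; see the methods vignette for the reasoning
#' behind each value.
#'
#' @param estimator Normalization-constant estimator: `"set-median"`
#'   (default; difference of the background set's medians in reference and
#'   replicate), `"set-mean"` (same with means), or `"orderstat-mean"`
#'   (mean of the top-k ranked differences).
#' @param k Background-set size: a positive integer applied to every
#'   replicate, or `"auto"` (default) to select per replicate with
#'   [select_k()].
#' @param k_min,k_max Candidate range for automatic selection. `k_min`
#'   defaults to `min_segment`; `k_max` may be an integer or a fraction of
#'   the gene count (default 0.9).
#' @param min_segment Minimum length, in ranks, of a linear piece of the
#'   ranked difference curve (default 500; scaled down for small panels).
#' @param r2_min Minimum window R-squared for a stretch of the curve to
#'   count as linear (default 0.995).
#' @param n_permutations Maximum number of label permutations for the
#'   permutation FDR (all distinct assignments are enumerated when fewer
#'   exist).
#' @param fdr_threshold FDR at which targets are called (default 0.05).
#' @param seed Integer seed for the permutation test and simulators.
#'
#' @return A list of class `ad_config`.
#' @export
ad_config <- function(estimator = c("set-median", "set-mean", "orderstat-mean"),
                      k = "auto",
                      k_min = NULL,
                      k_max = 0.9,
                      min_segment = 500,
                      r2_min = 0.995,
                      n_permutations = 1000,
                      fdr_threshold = 0.05,
                      seed = 1L) {
  estimator <- match.arg(estimator)
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (is.na(k) || k < 1) stop("'k' must be a positive integer or \"auto\"",
                                call. = FALSE)
  }
  if (min_segment < 2) stop("'min_segment' must be >= 2", call. = FALSE)
  if (r2_min <= 0 || r2_min >= 1) stop("'r2_min' must be in (0,1)", call. = FALSE)
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("'fdr_threshold' must be in (0,1)", call. = FALSE)
  if (n_permutations < 1) stop("'n_permutations' must be >= 1", call. = FALSE)
  structure(list(estimator = estimator, k = k, k_min = k_min, k_max = k_max,
                 min_segment = min_segment, r2_min = r2_min,
                 n_permutations = as.integer(n_permutations),
                 fdr_threshold = fdr_threshold, seed = as.integer(seed)),
            class = "ad_config")
}

#' Read a configuration file
#'
#' Flat YAML key-value document whose keys mirror the arguments of
#' [ad_config()]; unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return An `ad_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(ad_config)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(ad_config, vals)
}
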