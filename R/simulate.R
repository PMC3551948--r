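#' Specification of an idealized IP simulation
#'
#' Parameters of the generative model used throughout validation: every
#' value is mock background plus (for target genes in IP replicates) a
#' positive binding signal plus noise, and each replicate is shifted by an
#' unknown additive offset -- the constant the normalization must recover.
#'
#' @param n_genes Number of genes (default 6000).
#' @param target_fraction Fraction of genes that are true targets
#'   (default 0.1).
#' @param background_mean Mean of the background distribution (default 0).
#' @param target_mean Mean of the target distribution in IP replicates
#'   (default 3).
#' @param sd Standard deviation of both distributions (default 1).
#' @param n_ip,n_mock Replicates per condition (default 3 and 3).
#' @param replicate_offsets Per-replicate true additive offsets, IP
#'   replicates first; `NULL` (default) draws them Uniform(-2, 2) so that
#'   recovery is non-trivial.
#' @param seed Integer seed.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 6000, target_fraction = 0.1,
                            background_mean = 0, target_mean = 3, sd = 1,
                            n_ip = 3, n_mock = 3,
                            replicate_offsets = NULL, seed = 1L) {
  if (sd <= 0) stop("'sd' must be positive", call. = FALSE)
  if (target_fraction < 0 || target_fraction > 1)
    stop("'target_fraction' must be in [0, 1]", call. = FALSE)
  if (n_ip < 1 || n_mock < 1)
    stop("need at least one replicate per condition", call. = FALSE)
  if (!is.null(replicate_offsets) &&
      length(replicate_offsets) != n_ip + n_mock)
    stop("'replicate_offsets' must have one entry per replicate",
         call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 target_fraction = target_fraction,
                 background_mean = background_mean,
                 target_mean = target_mean, sd = sd,
                 n_ip = as.integer(n_ip), n_mock = as.integer(n_mock),
                 replicate_offsets = replicate_offsets,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate an idealized IP/Mock experiment
#'
#' Draws Mock replicate values from `Normal(background_mean, sd)` for every
#' gene; IP replicate values from the same distribution for background genes
#' and from `Normal(target_mean, sd)` for target genes; then shifts each
#' replicate by its true offset. Target genes are sampled uniformly without
#' replacement. Fully reproducible given the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `simulated_dataset`: `matrix` (an
#'   [enrichment_matrix()], IP columns first), `truth` (factor
#'   `"background"`/`"target"` per gene), `true_shift`
#'   (`target_mean - background_mean`), `true_offsets` (named per
#'   replicate), `spec`.
#' @examples
#' sim <- simulate_ip_experiment(simulation_spec(n_genes = 500, seed = 42))
#' table(sim$truth)
#' @export
simulate_ip_experiment <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  n_target <- round(spec$target_fraction * n)
  target_idx <- if (n_target > 0) sample.int(n, n_target) else integer(0)
  offsets <- spec$replicate_offsets
  if (is.null(offsets)) offsets <- stats::runif(spec$n_ip + spec$n_mock, -2, 2)

  ip <- vapply(seq_len(spec$n_ip), function(j) {
    v <- stats::rnorm(n, spec$background_mean, spec$sd)
    if (n_target > 0)
      v[target_idx] <- stats::rnorm(n_target, spec$target_mean, spec$sd)
    v + offsets[j]
  }, numeric(n))
  mock <- vapply(seq_len(spec$n_mock), function(j) {
    stats::rnorm(n, spec$background_mean, spec$sd) + offsets[spec$n_ip + j]
  }, numeric(n))

  vals <- cbind(ip, mock)
  rownames(vals) <- sprintf("g%05d", seq_len(n))
  colnames(vals) <- c(sprintf("IP_%d", seq_len(spec$n_ip)),
                      sprintf("Mock_%d", seq_len(spec$n_mock)))
  truth <- factor(rep("background", n), levels = c("background", "target"))
  truth[target_idx] <- "target"
  names(offsets) <- colnames(vals)
  structure(list(
    matrix = enrichment_matrix(vals, rep(c("IP", "Mock"),
                                         c(spec$n_ip, spec$n_mock))),
    truth = stats::setNames(truth, rownames(vals)),
    true_shift = spec$target_mean - spec$background_mean,
    true_offsets = offsets,
    spec = spec
  ), class = "simulated_dataset")
}

#' Simulate a Mock-versus-Mock false-target experiment
#'
#' All replicates are drawn from the same background process -- a shared
#' per-gene random level (mimicking the gene-to-gene variation of biological
#' replicates) plus independent noise -- and randomly split into a
#' pseudo-"IP" group and a Mock group. Any gene subsequently called enriched
#' is by construction a false target. This synthetic design stands in for
#' the published mock-array reassignment experiment, which used real arrays;
#' the additive-Gaussian structure here does not reproduce real-array
#' artifacts (see the methods vignette).
#'
#' @param n_mocks Total number of mock replicates (default 6).
#' @param group_sizes Sizes of the pseudo-IP and Mock groups; must sum to
#'   `n_mocks` (default `c(3, 3)`).
#' @param n_genes Number of genes (default 6000).
#' @param sd Replicate noise standard deviation (default 1).
#' @param gene_sd Standard deviation of the shared per-gene level
#'   (default 1).
#' @param seed Integer seed.
#' @return A `simulated_dataset`; `truth` is all-background and
#'   `true_shift` is 0.
#' @export
simulate_mock_mock <- function(n_mocks = 6, group_sizes = c(3, 3),
                               n_genes = 6000, sd = 1, gene_sd = 1,
                               seed = 1L) {
  if (length(group_sizes) != 2 || sum(group_sizes) != n_mocks ||
      any(group_sizes < 1))
    stop("'group_sizes' must be two positive counts summing to n_mocks",
         call. = FALSE)
  set.seed(seed)
  level <- stats::rnorm(n_genes, 0, gene_sd)
  vals <- vapply(seq_len(n_mocks), function(j)
    level + stats::rnorm(n_genes, 0, sd), numeric(n_genes))
  perm <- sample.int(n_mocks)
  vals <- vals[, perm, drop = FALSE]
  rownames(vals) <- sprintf("g%05d", seq_len(n_genes))
  colnames(vals) <- c(sprintf("IP_%d", seq_len(group_sizes[1])),
                      sprintf("Mock_%d", seq_len(group_sizes[2])))
  truth <- factor(rep("background", n_genes),
                  levels = c("background", "target"))
  structure(list(
    matrix = enrichment_matrix(vals, rep(c("IP", "Mock"), group_sizes)),
    truth = stats::setNames(truth, rownames(vals)),
    true_shift = 0,
    true_offsets = stats::setNames(rep(0, n_mocks), colnames(vals)),
    spec = list(n_mocks = n_mocks, group_sizes = group_sizes,
                n_genes = n_genes, sd = sd, gene_sd = gene_sd, seed = seed)
  ), class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d genes, %d target(s)\n",
              length(x$truth), sum(x$truth == "target")))
  print(x$matrix)
  invisible(x)
}

#' Convert per-bin read counts to a log2 enrichment table
#'
#' The sequencing adaptation: bins with a zero count in either the IP or the
#' Mock are removed (no pseudocounts), remaining counts are optionally
#' divided by a total-RNA reference (bins with zero reference also removed),
#' and the result is log2-transformed, ready to assemble into an
#' [enrichment_matrix()].
#'
#' @param ip_counts,mock_counts Named non-negative integer vectors over the
#'   same bins.
#' @param reference_counts Optional named non-negative integer vector of
#'   total-RNA reference counts over the same bins.
#' @return A data.frame with columns `bin`, `ip`, `mock` (log2 values,
#'   retained bins only). Zero retained bins yields an empty data.frame
#'   with a warning.
#' @examples
#' counts_to_logmatrix(c(b1 = 4, b2 = 0, b3 = 8), c(b1 = 2, b2 = 5, b3 = 8))
#' @export
counts_to_logmatrix <- function(ip_counts, mock_counts,
                                reference_counts = NULL) {
  if (length(ip_counts) != length(mock_counts))
    stop("IP and Mock bin sets differ", call. = FALSE)
  bins <- names(ip_counts)
  if (!is.null(bins) && !is.null(names(mock_counts)) &&
      !identical(bins, names(mock_counts)))
    stop("IP and Mock bin sets differ", call. = FALSE)
  if (is.null(bins)) bins <- sprintf("bin%d", seq_along(ip_counts))
  if (any(ip_counts < 0) || any(mock_counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  keep <- ip_counts > 0 & mock_counts > 0
  ip <- ip_counts; mock <- mock_counts
  if (!is.null(reference_counts)) {
    if (length(reference_counts) != length(ip_counts))
      stop("reference bin set differs", call. = FALSE)
    keep <- keep & reference_counts > 0
    ip <- ip / reference_counts
    mock <- mock / reference_counts
  }
  if (!any(keep))
    warning("no bins with non-zero counts in both IP and Mock",
            call. = FALSE)
  data.frame(bin = bins[keep],
             ip = log2(ip[keep]),
             mock = log2(mock[keep]),
             row.names = NULL)
}
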