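#' Moderated two-class enrichment statistic
#'
#' A simplified SAM-style statistic: for each gene,
#' `d = (mean_IP - mean_Mock) / (s + s0)` where `s` is the pooled two-sample
#' standard error and the fuzz constant `s0` damps genes whose tiny scatter
#' would otherwise make ordinary t statistics explode. `s0` defaults to the
#' median of all `s` (full SAM's coefficient-of-variation search is
#' deliberately not reproduced; the moderated-t structure is what matters
#' for comparing normalizations).
#'
#' @param x An [enrichment_matrix()] with at least 2 replicates per
#'   condition (typically a normalized matrix).
#' @param s0 Fuzz constant; `NULL` (default) uses `median(s)`.
#' @return A list with per-gene `d`, `s`, group means `mean_ip` and
#'   `mean_mock`, and the scalar `s0`.
#' @export
sam_statistic <- function(x, s0 = NULL) {
  stopifnot(inherits(x, "enrichment_matrix"))
  ip <- condition_values(x, "IP")
  mock <- condition_values(x, "Mock")
  if (ncol(ip) < 2 || ncol(mock) < 2)
    stop("need at least 2 replicates per condition", call. = FALSE)
  stat <- sam_d_matrix(ip, mock, s0)
  c(stat, list(mean_ip = rowMeans(ip), mean_mock = rowMeans(mock)))
}

# statistic on plain matrices; used by both the observed and the permuted
# computations (s0 is held fixed across permutations once estimated)
sam_d_matrix <- function(ip, mock, s0 = NULL) {
  n1 <- ncol(ip); n2 <- ncol(mock)
  m1 <- rowMeans(ip); m2 <- rowMeans(mock)
  ss <- rowSums((ip - m1)^2) + rowSums((mock - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  if (is.null(s0)) s0 <- stats::median(s)
  list(d = (m1 - m2) / (s + s0), s = s, s0 = s0)
}

#' Permutation-based FDR for IP enrichment
#'
#' Calls IP-enriched genes one-sidedly from the moderated statistic of
#' [sam_statistic()]. Condition labels are permuted over replicates: all
#' distinct balanced label assignments are enumerated when there are at most
#' `n_permutations` of them (the observed assignment included), otherwise
#' `n_permutations` are sampled with the seed. At each candidate threshold
#' (every positive observed `d`, descending) the estimated FDR is the mean
#' permuted count of exceedances divided by the observed count; per-gene `q`
#' is the smallest estimated FDR over thresholds at or below the gene's
#' `d` (step-up), and the called set collects genes with `q <= fdr_threshold`.
#'
#' @param x A normalized [enrichment_matrix()].
#' @param n_permutations Maximum number of label assignments to use.
#' @param fdr_threshold FDR at which to call targets.
#' @param seed Integer seed (used only when assignments must be sampled;
#'   recorded either way so results are reproducible).
#' @param s0 Optional fuzz constant forwarded to [sam_statistic()].
#' @return A list of class `test_result`: per-gene `d`, `s`, `q`, `called`
#'   (character gene ids), `s0`, `n_permutations` (used), `seed`, `method`.
#' @examples
#' sim <- simulate_ip_experiment(simulation_spec(n_genes = 1000,
#'                                               target_fraction = 0.05,
#'                                               seed = 2))
#' res <- normalize_experiment(sim$matrix)
#' tr <- permutation_fdr(res$normalized, fdr_threshold = 0.1, seed = 2)
#' length(tr$called)
#' @export
permutation_fdr <- function(x, n_permutations = 1000, fdr_threshold = 0.05,
                            seed = 1L, s0 = NULL) {
  stopifnot(inherits(x, "enrichment_matrix"))
  is_ip <- x$condition == "IP"
  n1 <- sum(is_ip); nn <- length(is_ip)
  if (n1 < 2 || nn - n1 < 2)
    stop("need at least 2 replicates per condition", call. = FALSE)
  obs <- sam_statistic(x, s0 = s0)

  combs <- utils::combn(nn, n1)
  if (ncol(combs) > n_permutations) {
    set.seed(seed)
    combs <- combs[, sample.int(ncol(combs), n_permutations), drop = FALSE]
  }
  n_used <- ncol(combs)

  pos <- which(obs$d > 0)
  genes <- gene_ids(x)
  q <- rep(NA_real_, length(obs$d))
  called <- character(0)
  if (length(pos)) {
    ord <- pos[order(obs$d[pos], decreasing = TRUE)]
    dd <- obs$d[ord]
    # exceedance counts of each permuted d vector over every threshold
    cnt <- vapply(seq_len(n_used), function(i) {
      ii <- logical(nn); ii[combs[, i]] <- TRUE
      dp <- sort(sam_d_matrix(x$values[, ii, drop = FALSE],
                              x$values[, !ii, drop = FALSE], obs$s0)$d)
      length(dp) - findInterval(dd - 1e-12, dp)
    }, numeric(length(dd)))
    cnt <- matrix(cnt, nrow = length(dd))
    fdr_r <- pmin(1, rowMeans(cnt) / seq_along(dd))
    qq <- rev(cummin(rev(fdr_r)))
    q[ord] <- qq
    called <- genes[ord[qq <= fdr_threshold]]
  }
  structure(list(d = stats::setNames(obs$d, genes),
                 s = stats::setNames(obs$s, genes),
                 s0 = obs$s0,
                 q = stats::setNames(q, genes),
                 called = called,
                 fdr_threshold = fdr_threshold,
                 n_permutations = n_used,
                 seed = as.integer(seed),
                 method = "sam-permutation"),
            class = "test_result")
}

#' One-sided Welch t test with Benjamini-Hochberg FDR
#'
#' The plain alternative to [permutation_fdr()]: per-gene one-sided
#' (IP > Mock) Welch t test, Benjamini-Hochberg adjustment, and a called set
#' at the requested FDR. Deterministic.
#'
#' @param x A normalized [enrichment_matrix()].
#' @param fdr_threshold FDR at which to call targets.
#' @return A `test_result` with per-gene `t`, `p`, `q`, and `called`.
#' @export
welch_t_test <- function(x, fdr_threshold = 0.05) {
  stopifnot(inherits(x, "enrichment_matrix"))
  ip <- condition_values(x, "IP")
  mock <- condition_values(x, "Mock")
  n1 <- ncol(ip); n2 <- ncol(mock)
  if (n1 < 2 || n2 < 2)
    stop("need at least 2 replicates per condition", call. = FALSE)
  m1 <- rowMeans(ip); m2 <- rowMeans(mock)
  v1 <- rowSums((ip - m1)^2) / (n1 - 1)
  v2 <- rowSums((mock - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- stats::pt(tstat, df, lower.tail = FALSE)
  q <- stats::p.adjust(p, "BH")
  genes <- gene_ids(x)
  structure(list(t = stats::setNames(tstat, genes),
                 p = stats::setNames(p, genes),
                 q = stats::setNames(q, genes),
                 called = genes[q <= fdr_threshold],
                 fdr_threshold = fdr_threshold,
                 method = "welch-bh"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("test_result (%s): %d gene(s) called at FDR %.2g\n",
              x$method, length(x$called), x$fdr_threshold))
  invisible(x)
}

#' Export a test result as a data.frame
#'
#' @param x A `test_result`.
#' @param ... Unused.
#' @return data.frame with gene, statistic, q and called columns.
#' @export
as.data.frame.test_result <- function(x, ...) {
  stat <- if (!is.null(x$d)) x$d else x$t
  data.frame(gene = names(stat),
             statistic = unname(stat),
             q = unname(x$q[names(stat)]),
             called = names(stat) %in% x$called,
             row.names = NULL)
}
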