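# Independent oracles used across tests; deliberately brute-force and
# separate from the package's implementation paths.

# first candidate rank from which every min_segment-wide lm fit of the
# sorted curve (vs rank) reaches r2_min, scanning windows one by one
oracle_first_linear_rank <- function(d, w, r2_min, k_min, k_max) {
  n <- length(d)
  r2_of <- function(s) {
    idx <- s:(s + w - 1)
    suppressWarnings(summary(stats::lm(d[idx] ~ idx))$r.squared)
  }
  nw <- n - w + 1
  r2 <- vapply(seq_len(nw), r2_of, numeric(1))
  for (kappa in k_min:min(k_max, nw)) {
    starts <- kappa:min(kappa + w - 1, nw)
    if (all(r2[starts] >= r2_min)) return(kappa)
  }
  NA_integer_
}

# mean of the k largest values of (reference - replicate), computed by a
# full sort, independent of difference_profile/background_set
oracle_topk_mean <- function(reference, replicate, k) {
  mean(sort(reference - replicate, decreasing = TRUE)[seq_len(k)])
}

# tiny matrix builder
em <- function(vals, condition, genes = NULL, reps = NULL) {
  vals <- as.matrix(vals)
  rownames(vals) <- if (is.null(genes)) paste0("g", seq_len(nrow(vals))) else genes
  colnames(vals) <- if (is.null(reps)) paste0("r", seq_len(ncol(vals))) else reps
  enrichment_matrix(vals, condition)
}
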