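# Sliding-window R^2 of a linear fit of y against rank, one value per
# window start. y is globally centered first for numerical conditioning;
# exactly constant windows get R^2 = 1 (a constant is a perfect line).
window_r2 <- function(y, w) {
  n <- length(y)
  if (w > n) stop("window longer than curve", call. = FALSE)
  y <- y - mean(y)
  x <- seq_len(n)
  cs <- function(v) cumsum(as.numeric(v))
  cy <- cs(y); cy2 <- cs(y * y); cxy <- cs(x * y)
  cx <- cs(x); cx2 <- cs(x * x)
  s <- seq_len(n - w + 1); e <- s + w - 1
  win <- function(c1) c1[e] - c(0, c1)[s]
  sy <- win(cy); sy2 <- win(cy2); sxy <- win(cxy)
  sx <- win(cx); sx2 <- win(cx2)
  ssxx <- sx2 - sx^2 / w
  ssyy <- pmax(0, sy2 - sy^2 / w)
  ssxy <- sxy - sx * sy / w
  r2 <- ifelse(ssyy <= 0, 1, (ssxy * ssxy) / (ssxx * ssyy))
  pmin(pmax(r2, 0), 1)
}

#' Select the background-set size k from a ranked difference curve
#'
#' Locates the rank at which the descending Mock-minus-IP order-statistic
#' curve becomes piecewise linear. The extreme upper tail of the curve is
#' dominated by extreme order statistics and is visibly curved; true
#' background genes produce a long, nearly linear stretch beyond it. k is
#' taken as the earliest candidate rank from which the curve stays linear
#' for at least one full segment:
#' the smallest candidate kappa in `[k_min, k_max]` such that every sliding
#' window of `min_segment` ranks starting in `[kappa, kappa + min_segment)`
#' fits a line with R-squared at least `r2_min`. If no candidate qualifies,
#' the candidate maximizing the worst window R-squared is returned with a
#' warning.
#'
#' @param profile A [difference_profile()], or a numeric vector already
#'   sorted in descending order.
#' @param min_segment Minimum linear-piece length in ranks (default 500,
#'   chosen for genome-scale panels). For panels with fewer than
#'   `2 * min_segment` genes it is scaled down to `floor(n/4)` with a
#'   warning.
#' @param r2_min Linearity threshold for a window (default 0.995).
#' @param k_min Smallest candidate; defaults to the effective `min_segment`.
#' @param k_max Largest candidate; an integer, or a fraction of the gene
#'   count (default 0.9, keeping a tail of candidate targets out of the
#'   normalization set).
#' @return A list of class `k_selection`: `k`, `r2_profile` (window
#'   R-squared at each window start), `window` (effective `min_segment`),
#'   `accepted_region` (range of qualifying candidate ranks, or `NULL`),
#'   `k_min`, `k_max`, and `qualified` (logical).
#' @examples
#' prof <- difference_profile(rnorm(3000), rnorm(3000))
#' sel <- select_k(prof)
#' sel$k
#' @export
select_k <- function(profile, min_segment = 500, r2_min = 0.995,
                     k_min = NULL, k_max = 0.9) {
  d <- if (inherits(profile, "difference_profile")) profile$sorted_diffs
       else as.numeric(profile)
  if (is.unsorted(rev(d)))
    stop("difference curve must be sorted in descending order", call. = FALSE)
  n <- length(d)
  w <- as.integer(min_segment)
  if (n < 2 * w) {
    w <- max(20L, as.integer(floor(n / 4)))
    warning("fewer than 2*min_segment genes; window scaled down to ", w,
            call. = FALSE)
  }
  if (is.null(k_min)) k_min <- w
  k_min <- as.integer(k_min)
  k_max <- if (k_max <= 1) as.integer(floor(k_max * n)) else as.integer(k_max)
  if (k_min < 1 || k_max > n || k_min >= k_max)
    stop("need 1 <= k_min < k_max <= n_genes", call. = FALSE)
  if (n < k_min + w)
    stop("too few genes for k selection (need >= k_min + window)",
         call. = FALSE)

  r2 <- window_r2(d, w)
  nw <- length(r2)
  cand <- k_min:min(k_max, nw)
  hi <- pmin(cand + w - 1L, nw)
  bad <- which(r2 < r2_min)
  n_bad <- findInterval(hi, bad) - findInterval(cand - 1L, bad)
  ok <- n_bad == 0L
  if (any(ok)) {
    k <- cand[which(ok)[1]]
    accepted <- range(cand[ok])
    qualified <- TRUE
  } else {
    worst <- vapply(seq_along(cand),
                    function(i) min(r2[cand[i]:hi[i]]), numeric(1))
    k <- cand[which.max(worst)]
    accepted <- NULL
    qualified <- FALSE
    warning("no candidate rank reaches r2_min = ", r2_min,
            "; using the best-fitting candidate k = ", k, call. = FALSE)
  }
  structure(list(k = k, r2_profile = r2, window = w,
                 accepted_region = accepted, k_min = k_min,
                 k_max = min(k_max, nw), qualified = qualified),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("k_selection: k = %d (window %d, candidates [%d, %d]%s)\n",
              x$k, x$window, x$k_min, x$k_max,
              if (x$qualified) "" else ", no window met r2_min"))
  invisible(x)
}

#' Rank plot of a difference profile
#'
#' Plots the Mock-minus-IP values against their descending rank (background
#' genes on the left) with a vertical line at the selected k. This is the
#' diagnostic picture behind the k-selection rule: the curve should be
#' visibly non-linear left of the line and settle into a near-linear stretch
#' after it.
#'
#' @param profile A [difference_profile()].
#' @param selection A [select_k()] result computed on the same profile.
#' @param annotations Optional logical vector (one per gene, in the
#'   profile's input gene order) highlighting genes of interest, e.g.
#'   simulated true targets.
#' @param path Optional output file; `.pdf` uses the pdf device, anything
#'   else a png device. `NULL` draws on the current device.
#' @param main Plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
rank_plot <- function(profile, selection = NULL, annotations = NULL,
                      path = NULL, main = "Ranked Mock - IP differences") {
  stopifnot(inherits(profile, "difference_profile"))
  n <- length(profile$sorted_diffs)
  if (!is.null(path)) {
    if (grepl("\\.pdf$", path)) grDevices::pdf(path, width = 7, height = 5)
    else grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  col <- rep("black", n)
  if (!is.null(annotations)) {
    if (length(annotations) != n)
      stop("'annotations' must have one entry per gene", call. = FALSE)
    col[annotations[profile$order]] <- "orange"
  }
  graphics::plot(seq_len(n), profile$sorted_diffs, pch = 20, cex = 0.4,
                 col = col, xlim = c(1, n),
                 xlab = "rank (most Mock-enriched first)",
                 ylab = "Mock - IP", main = main)
  if (!is.null(selection))
    graphics::abline(v = selection$k, lty = 2, col = "blue")
  invisible(path)
}
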