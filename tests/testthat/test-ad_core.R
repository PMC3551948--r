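test_that("difference_profile ranks Mock-minus-IP descending with stable ties", {
  p <- difference_profile(c(g1 = 0, g2 = 0, g3 = 0),
                          c(g1 = -1, g2 = 2, g3 = 0))
  expect_equal(unname(p$diffs), c(1, -2, 0))
  expect_equal(unname(p$sorted_diffs), c(1, 0, -2))
  expect_equal(p$order, c(1L, 3L, 2L))
  # identical vectors: all-zero diffs, identity order (stable ties)
  v <- c(g1 = 0.3, g2 = -1, g3 = 2)
  p0 <- difference_profile(v, v)
  expect_equal(unname(p0$diffs), c(0, 0, 0))
  expect_equal(p0$order, 1:3)
  # pure shift
  ps <- difference_profile(v, v - 2)
  expect_equal(unname(ps$diffs), c(2, 2, 2))
  expect_error(difference_profile(1:3, 1:4), "gene sets")
})

test_that("background_set returns the top-k of the descending order", {
  p <- difference_profile(c(g1 = 0, g2 = 0, g3 = 0),
                          c(g1 = -1, g2 = 2, g3 = 0))
  expect_identical(names(background_set(p, 2)), c("g1", "g3"))
  expect_identical(sort(names(background_set(p, 3))), c("g1", "g2", "g3"))
  expect_error(background_set(p, 0), "k")
  expect_error(background_set(p, 4), "k")
})

test_that("normalization_constant variants match their definitions", {
  ref <- c(a = 0, b = 0)
  rep_ <- c(a = -1, b = 0)
  expect_equal(normalization_constant(ref, rep_, c("a", "b"), "set-median"),
               0.5)
  expect_equal(normalization_constant(ref, rep_, c("a", "b"), "set-mean"),
               0.5)
  expect_equal(normalization_constant(ref, rep_, c("a", "b"),
                                      "orderstat-mean"), 0.5)
  # a pure shift is recovered exactly by every estimator and any set
  set.seed(41)
  ref2 <- rnorm(50)
  rep2 <- ref2 - 2
  for (est in c("set-median", "set-mean", "orderstat-mean"))
    expect_equal(normalization_constant(ref2, rep2, sample(50, 10), est), 2)
  expect_error(normalization_constant(ref, rep_, integer(0)), "empty")
  expect_error(normalization_constant(ref, rep_, c("a", "z")), "outside")
})

test_that("orderstat-mean equals the brute-force top-k mean of sorted diffs", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(50:400, 1)
    ref <- rnorm(n); rep_ <- rnorm(n)
    k <- sample(n, 1)
    p <- difference_profile(ref, rep_)
    got <- normalization_constant(ref, rep_, background_set(p, k),
                                  "orderstat-mean")
    expect_equal(got, oracle_topk_mean(ref, rep_, k), tolerance = 1e-12)
  }
})

test_that("set-median over all genes reproduces pairwise median normalization", {
  set.seed(43)
  ref <- rnorm(500); rep_ <- rnorm(500, 1)
  p <- difference_profile(ref, rep_)
  got <- normalization_constant(ref, rep_, background_set(p, 500),
                                "set-median")
  expect_identical(got, median(ref) - median(rep_))
})

test_that("constant_vs_k_curve is flat under a pure shift and hits the median
           normalization boundary", {
  set.seed(44)
  ref <- rnorm(300)
  rep_ <- ref - 1.7
  cur <- constant_vs_k_curve(ref, rep_, c(10, 50, 150, 300))
  expect_true(all(abs(cur$constant - 1.7) < 1e-12))
  rep2 <- rnorm(300)
  cur2 <- constant_vs_k_curve(ref, rep2, 300, estimator = "set-median")
  expect_equal(cur2$constant, median(ref) - median(rep2))
  expect_error(constant_vs_k_curve(ref, rep2, c(0, 10)), "k_grid")
})

test_that("constant_vs_k_curve trends downward once targets enter the set", {
  # beyond the background region, larger k mixes true targets into the
  # normalization set and drags the constant down
  drop_ <- replicate(10, {
    sim <- simulate_ip_experiment(
      simulation_spec(n_genes = 2000, target_fraction = 0.3,
                      replicate_offsets = rep(0, 6),
                      seed = sample.int(1e6, 1)))
    mocks <- condition_values(sim$matrix, "Mock")
    mb <- build_mock_model(mocks)$mock_bar
    ip1 <- condition_values(sim$matrix, "IP")[, 1]
    cur <- constant_vs_k_curve(mb, ip1, c(1000, 1900))
    cur$constant[2] - cur$constant[1]
  })
  expect_lt(mean(drop_), 0)
})

test_that("normalize_experiment recovers exact per-replicate shifts in the
           noise-free case", {
  set.seed(45)
  base <- rnorm(2000)
  base <- base - median(base)          # a fixed background profile
  shifts <- c(0.8, -1.2, 2.5)
  vals <- cbind(vapply(shifts, function(a) base - a, numeric(2000)),
                base, base)
  colnames(vals) <- c("ip1", "ip2", "ip3", "m1", "m2")
  rownames(vals) <- paste0("g", 1:2000)
  x <- enrichment_matrix(vals, c("IP", "IP", "IP", "Mock", "Mock"))
  res <- normalize_experiment(x)
  expect_equal(unname(res$constants[c("ip1", "ip2", "ip3")]), shifts,
               tolerance = 1e-10)
  for (id in c("ip1", "ip2", "ip3"))
    expect_equal(unname(res$normalized$values[, id]), unname(base),
                 tolerance = 1e-10)
})

test_that("normalization is exactly invariant to per-IP-replicate and common
           Mock shifts", {
  sim <- simulate_ip_experiment(simulation_spec(n_genes = 3000, seed = 46))
  x <- sim$matrix
  res0 <- normalize_experiment(x)

  x_ip <- x
  x_ip$values[, "IP_2"] <- x_ip$values[, "IP_2"] + 5.43
  res1 <- normalize_experiment(x_ip)
  expect_equal(res1$normalized$values, res0$normalized$values,
               tolerance = 1e-12)
  expect_equal(res1$k_used, res0$k_used)

  x_mo <- x
  mo_cols <- x$condition == "Mock"
  x_mo$values[, mo_cols] <- x_mo$values[, mo_cols] - 2.2
  res2 <- normalize_experiment(x_mo)
  expect_equal(res2$normalized$values, res0$normalized$values,
               tolerance = 1e-12)
})

test_that("normalized values are raw values plus the recorded constant", {
  sim <- simulate_ip_experiment(simulation_spec(n_genes = 2500, seed = 47))
  res <- normalize_experiment(sim$matrix)
  for (id in replicate_ids(sim$matrix)[sim$matrix$condition == "IP"])
    expect_equal(res$normalized$values[, id],
                 sim$matrix$values[, id] + res$constants[[id]],
                 tolerance = 1e-12)
  expect_equal(unname(res$k_used),
               unname(vapply(res$background_sets, length, integer(1))))
})

test_that("normalize_experiment needs two Mock replicates and honours fixed k", {
  sim <- simulate_ip_experiment(simulation_spec(n_genes = 1500, n_mock = 1,
                                                seed = 48))
  expect_error(normalize_experiment(sim$matrix), "2 Mock")
  sim2 <- simulate_ip_experiment(simulation_spec(n_genes = 1500, seed = 48))
  res <- normalize_experiment(sim2$matrix, ad_config(k = 200))
  expect_true(all(res$k_used == 200))
  # at 1,500 genes a 500-rank window spans a third of the curve, so auto
  # selection legitimately falls back with a warning for the other replicates
  suppressWarnings(
    res2 <- normalize_experiment(sim2$matrix,
                                 k_per_replicate = c(IP_1 = 333)))
  expect_identical(unname(res2$k_used["IP_1"]), 333)
})

test_that("the leave-one-out constants estimate the selection bias of a
           background-only experiment", {
  # all-background null with known IP offsets: the bias-corrected difference
  # between the mean IP and mean Mock constants recovers the true offset
  # difference (the Mock offsets vanish with median centering)
  true_cdiff <- mean(c(1.3, -0.4, -0.9))
  est <- vapply(1:60, function(s) {
    sim <- simulate_ip_experiment(
      simulation_spec(n_genes = 6000, target_fraction = 0,
                      replicate_offsets = c(-1.3, 0.4, 0.9, 0, 0, 0),
                      seed = 1000 + s))
    res <- normalize_experiment(sim$matrix)
    mean(res$constants[sim$matrix$condition == "IP"]) -
      mean(res$constants[sim$matrix$condition == "Mock"])
  }, numeric(1))
  expect_lt(abs(mean(est) - true_cdiff), 0.05)
})
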