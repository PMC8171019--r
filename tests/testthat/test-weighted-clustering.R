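# The feature-weighted k-medians updates and the alternating fit.

test_that("per-feature distances match a scalar loop oracle", {
  expect_equal(per_feature_distance(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(per_feature_distance(c(0, 4), c(1, 2)), c(1, 2))
  set.seed(1)
  x <- runif(10); c_ <- runif(10)
  oracle <- vapply(1:10, function(j) abs(x[j] - c_[j]), numeric(1))
  expect_equal(per_feature_distance(x, c_), oracle)
  expect_error(per_feature_distance(1:3, 1:4), class = "cafw_cluster_error")
})

test_that("weighted distance reduces to its hand-computed values", {
  w <- rand_simplex_rows(1, 5)[1, ]
  expect_equal(weighted_distance(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), w), 0)
  # uniform weights factorise to Manhattan / n
  x <- c(3, 0, 7); c_ <- c(1, 1, 1)
  expect_equal(weighted_distance(x, c_, rep(1 / 3, 3)),
               sum(abs(x - c_)) / 3)
  # n = 2, w = (0.75, 0.25), d = (1, 2) -> 1.25
  expect_equal(weighted_distance(c(0, 4), c(1, 2), c(0.75, 0.25)), 1.25,
               tolerance = 1e-12)
})

test_that("cells go to the nearest center, ties to the lowest index", {
  centers <- rbind(c(0, 0), c(5, 5), c(9, 9))
  W <- matrix(1 / 2, 3, 2)
  expect_equal(assign_cells(rbind(c(5, 5)), centers, W), 2L)
  # cell at (2.5, 2.5) is equidistant from clusters 1 and 2 -> 1
  tie <- assign_cells(rbind(c(2.5, 2.5), c(2.5, 2.5)), centers, W)
  expect_equal(tie, c(1L, 1L))
  set.seed(4)
  x <- matrix(runif(20 * 6, 0, 10), 20, 6)
  centers <- matrix(runif(3 * 6, 0, 10), 3, 6)
  W <- rand_simplex_rows(3, 6)
  got <- assign_cells(x, centers, W)
  oracle <- vapply(1:20, function(i) {
    d <- vapply(1:3, function(k) sum(W[k, ] * abs(x[i, ] - centers[k, ])), numeric(1))
    which.min(d)
  }, integer(1))
  expect_equal(got, oracle)
})

test_that("center update takes per-feature medians and honours zero weights", {
  x <- matrix(c(1, 5, 9, 1, 3, 8), ncol = 2) # feature 1: {1,5,9}; feature 2: {1,3,8}
  centers <- matrix(0, 1, 2)
  got <- update_centers(x, rep(1L, 3), centers, W = matrix(c(0.4, 0.6), 1))
  expect_equal(got[1, ], c(5, 3))
  # zero weight forces the center coordinate to 0
  got0 <- update_centers(x, rep(1L, 3), centers, W = matrix(c(1, 0), 1))
  expect_equal(got0[1, ], c(5, 0))
  # even cluster size: mean of the two middle values
  x2 <- matrix(c(1, 3), ncol = 1)
  got2 <- update_centers(x2, c(1L, 1L), matrix(0, 1, 1), W = matrix(1, 1, 1))
  expect_equal(got2[1, 1], 2)
})

test_that("weight-row update matches the closed form and sums to one", {
  # single feature: the simplex constraint forces w = 1
  one <- update_weight_row(matrix(c(1, 5), 2, 1), 1:2, 3, delta = 2)
  expect_equal(one$w, 1)
  # all members at the center -> uniform row
  xc <- matrix(2, 3, 4)
  unif <- update_weight_row(xc, 1:3, rep(2, 4), delta = 1)
  expect_equal(unif$w, rep(0.25, 4))
  # hand case: cluster {(0,0),(2,4)}, center (1,2), delta 2 -> (0.75, 0.25)
  hand <- update_weight_row(rbind(c(0, 0), c(2, 4)), 1:2, c(1, 2), delta = 2)
  expect_equal(hand$raw, c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(hand$w, c(0.75, 0.25), tolerance = 1e-12)
  # raw rows always sum to exactly 1 (algebraic identity), projection stays
  # on the simplex inside [0, 1]
  set.seed(8)
  for (i in 1:20) {
    m <- sample(2:12, 1); n <- sample(2:15, 1)
    x <- matrix(runif(m * n, 0, 10), m, n)
    upd <- update_weight_row(x, seq_len(m), runif(n, 0, 10), delta = runif(1, 0.05, 2))
    expect_lt(abs(sum(upd$raw) - 1), 1e-9)
    expect_lt(abs(sum(upd$w) - 1), 1e-9)
    expect_true(all(upd$w >= 0 & upd$w <= 1))
  }
})

test_that("delta update matches its hand value, degenerate policy and linearity", {
  # two cells, previous w = (0.5, 0.5), d-rows (1,3) and (2,0), C_delta = 1 -> 6
  x <- rbind(c(1, 5), c(4, 2))
  center <- c(2, 2)
  expect_equal(update_delta(x, 1:2, center, c(0.5, 0.5), c_delta = 1), 6)
  expect_equal(update_delta(x, 1:2, center, c(0.5, 0.5), c_delta = 2), 12)
  # zero total distance keeps the previous value
  expect_equal(update_delta(matrix(2, 3, 2), 1:3, c(2, 2), c(0.5, 0.5),
                            c_delta = 1, prev_delta = 7), 7)
})

test_that("objective value equals a triple-loop oracle", {
  # single cluster, all cells at the center: only the penalty term remains
  x0 <- matrix(3, 4, 2)
  W0 <- matrix(c(0.7, 0.3), 1)
  expect_equal(objective_value(x0, W0, matrix(3, 1, 2), delta = 2, rep(1L, 4)),
               2 * (0.7^2 + 0.3^2))
  # uniform weights, 2 cells with d-rows (1,1) and (1,1), delta = 1 -> 2.5
  x1 <- rbind(c(0, 0), c(2, 2))
  expect_equal(objective_value(x1, matrix(0.5, 1, 2), matrix(1, 1, 2),
                               delta = 1, c(1L, 1L)), 2.5)
  set.seed(12)
  x <- matrix(runif(15 * 4, 0, 5), 15, 4)
  K <- 3
  W <- rand_simplex_rows(K, 4)
  centers <- matrix(runif(K * 4, 0, 5), K, 4)
  delta <- runif(K, 0.5, 3)
  asg <- sample(1:K, 15, replace = TRUE)
  oracle <- 0
  for (k in 1:K) {
    for (i in which(asg == k)) {
      for (j in 1:4) oracle <- oracle + W[k, j] * abs(x[i, j] - centers[k, j])
    }
    oracle <- oracle + delta[k] * sum(W[k, ]^2)
  }
  expect_equal(objective_value(x, W, centers, delta, asg), oracle)
})

test_that("well-separated blobs are recovered perfectly", {
  blobs <- make_blobs(K = 2, per = 15, n = 8, sep = 60, sd = 1, seed = 2)
  fit <- weighted_kmedians(blobs$x, K = 2, seed = 3)
  expect_equal(adjusted_rand_index(blobs$labels, fit$assignments), 1)
  expect_true(fit$converged)
})

test_that("K = m degenerates to one cell per cluster with zero distance term", {
  set.seed(30)
  x <- matrix(runif(5 * 3, 0, 10), 5, 3)
  fit <- weighted_kmedians(x, K = 5, seed = 1)
  expect_equal(sort(tabulate(fit$assignments, 5)), rep(1L, 5))
  D <- weighted_distances(x, fit$centers, fit$W)
  expect_equal(sum(D[cbind(1:5, fit$assignments)]), 0)
  expect_error(weighted_kmedians(x, K = 6, seed = 1), class = "cafw_cluster_error")
})

test_that("fits are reproducible from the seed", {
  blobs <- make_blobs(K = 3, per = 10, n = 6, sep = 20, sd = 2, seed = 6)
  f1 <- weighted_kmedians(blobs$x, K = 3, seed = 42)
  f2 <- weighted_kmedians(blobs$x, K = 3, seed = 42)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("permuting gene order permutes weight columns identically", {
  blobs <- make_blobs(K = 2, per = 12, n = 7, sep = 15, sd = 2, seed = 7)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  f1 <- weighted_kmedians(blobs$x, K = 2, seed = 5)
  f2 <- weighted_kmedians(blobs$x[, perm], K = 2, seed = 5)
  expect_equal(f2$W, f1$W[, perm])
  expect_identical(f1$assignments, f2$assignments)
})

test_that("a huge C_delta drives all weights to uniform", {
  blobs <- make_blobs(K = 3, per = 10, n = 9, sep = 25, sd = 2, seed = 9)
  fit <- weighted_kmedians(blobs$x, K = 3, c_delta = 1e9, seed = 2)
  expect_lt(max(abs(fit$W - 1 / 9)), 1e-3)
})
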