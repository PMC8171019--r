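# Independent oracles and fixture builders used across the suite.

# Plain Manhattan k-medians, written independently of the package internals
# but following the same update order (assign -> re-seed empties -> medians)
# and tie/empty-cluster policies, so a weight-frozen fit must match exactly.
kmedians_oracle <- function(x, centers0, max_iter = 100) {
  K <- nrow(centers0)
  m <- nrow(x)
  centers <- centers0
  assignments <- NULL
  manhattan <- function(centers) {
    sapply(seq_len(K), function(k) {
      rowSums(abs(x - matrix(centers[k, ], m, ncol(x), byrow = TRUE)))
    })
  }
  for (iter in seq_len(max_iter)) {
    D <- manhattan(centers)
    new <- max.col(-D, ties.method = "first")
    for (k in setdiff(seq_len(K), unique(new))) {
      D2 <- manhattan(centers)
      own <- D2[cbind(seq_len(m), new)]
      far <- which.max(own)
      centers[k, ] <- x[far, ]
      new[far] <- k
    }
    stable <- iter > 1 && identical(new, assignments)
    assignments <- new
    for (k in seq_len(K)) {
      members <- which(assignments == k)
      if (length(members) > 0) {
        centers[k, ] <- apply(x[members, , drop = FALSE], 2, stats::median)
      }
    }
    if (stable) break
  }
  list(assignments = assignments, centers = centers)
}

# Pair-counting adjusted Rand index (Hubert-Arabie closed form on the four
# pair categories), independent of the contingency-table route.
ari_pair_oracle <- function(a, b) {
  ut <- upper.tri(diag(length(a)))
  same_a <- outer(a, a, "==")[ut]
  same_b <- outer(b, b, "==")[ut]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) 1 else 2 * (n11 * n00 - n10 * n01) / den
}

# Closed-form simple-regression coefficients (normal equations).
ols_oracle <- function(u, y) {
  su <- sum(u); sy <- sum(y); n <- length(u)
  slope <- (n * sum(u * y) - su * sy) / (n * sum(u^2) - su^2)
  intercept <- (sy - slope * su) / n
  list(slope = slope, intercept = intercept,
       residuals = y - intercept - slope * u)
}

# Scripted re-statement of the Sturges bin-removal rule, mechanically
# different from the package implementation (floor-based bin index).
screen_count_oracle <- function(scores, target) {
  s <- scores
  repeat {
    if (length(s) < target) break
    if (max(s) == min(s)) break
    nb <- max(2, floor(abs(3.322 * log10(length(s)) - 1) + 0.5) *
                sign(3.322 * log10(length(s)) - 1))
    width <- (max(s) - min(s)) / nb
    bin <- pmin(pmax(floor((s - min(s)) / width) + 1, 1), nb)
    lowest <- min(bin)
    if (sum(bin == lowest) == length(s)) break
    s <- s[bin != lowest]
  }
  length(s)
}

# Well-separated non-negative Gaussian blobs.
make_blobs <- function(K = 2, per = 20, n = 10, sep = 50, sd = 1, seed = 1) {
  set.seed(seed)
  mu <- matrix(stats::runif(K * n, 0, sep), K, n)
  labels <- rep(seq_len(K), each = per)
  x <- mu[labels, , drop = FALSE] + matrix(stats::rnorm(K * per * n, sd = sd),
                                           K * per, n)
  x <- abs(x)
  dimnames(x) <- list(sprintf("c%03d", seq_len(nrow(x))),
                      sprintf("g%03d", seq_len(n)))
  list(x = x, labels = labels)
}

# Random weight rows on the simplex.
rand_simplex_rows <- function(K, n) {
  W <- matrix(stats::rexp(K * n), K, n)
  W / rowSums(W)
}
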