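# Clustering evaluation: adjusted Rand index against reference labels and
# the Davies-Bouldin compactness/separation index.

#' Adjusted Rand index
#'
#' Chance-corrected agreement of two partitions computed from the contingency
#' table: 1 means identical partitions (up to relabeling), values near 0 mean
#' chance-level agreement, negative values mean worse than chance. When both
#' partitions are degenerate (the adjustment denominator is zero, e.g. both
#' single-cluster) the index is defined as 1.
#'
#' @param labels_true,labels_pred equal-length label vectors (any atomic
#'   type; labels are compared by value).
#' @param details if `TRUE`, return a list with the `ari`, the contingency
#'   table and its margins instead of a bare number.
#' @return Numeric in `[-1, 1]`, or a list when `details = TRUE`.
#' @examples
#' adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)) # 1: same partition
#' adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)) # -0.5: crossed pairs
#' @export
adjusted_rand_index <- function(labels_true, labels_pred, details = FALSE) {
  if (length(labels_true) != length(labels_pred)) {
    stop_io("Label vectors have different lengths.")
  }
  if (length(labels_true) < 2) stop_io("Need at least 2 labelled cells.")
  tab <- table(labels_true, labels_pred)
  m <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  sum_tij <- sum(choose(tab, 2))
  sum_a <- sum(choose(a, 2))
  sum_b <- sum(choose(b, 2))
  expected <- sum_a * sum_b / choose(m, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  ari <- if (denom == 0) 1 else (sum_tij - expected) / denom
  if (!details) return(ari)
  list(ari = ari, contingency = unclass(tab), row_sums = a, col_sums = b, m = m)
}

#' Davies-Bouldin index
#'
#' Compactness-to-separation score of a labelled data set:
#' `DBI = (1/k) * sum_i agg_{j != i} (d_i + d_j) / d_ij`, where `d_i` is the
#' mean Euclidean distance of cluster i's points to their centroid (the
#' coordinate mean) and `d_ij` the Euclidean distance between centroids.
#' Smaller values mean tighter, better-separated clusters.
#'
#' The default aggregator is `min` over the other clusters; the conventional
#' definition uses `max` and is available via `aggregate = "max"` (the two
#' orderings usually agree in direction on separated data; a note is emitted
#' once per session when the `min` form is used).
#'
#' @param x an [expr_matrix()] or plain cells x genes numeric matrix.
#' @param labels cluster label per cell; at least 2 non-empty clusters.
#' @param aggregate `"min"` (default) or `"max"` over the other clusters.
#' @param details if `TRUE`, also return per-cluster scatters and the
#'   centroid distance matrix.
#' @return Non-negative numeric, or a list when `details = TRUE`.
#' @examples
#' x <- matrix(c(0, 2, 10, 12), ncol = 1)
#' davies_bouldin_index(x, c(1, 1, 2, 2)) # 0.2
#' @export
davies_bouldin_index <- function(x, labels, aggregate = c("min", "max"),
                                 details = FALSE) {
  aggregate <- match.arg(aggregate)
  xm <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (nrow(xm) != length(labels)) stop_io("`labels` length must match the number of cells.")
  lev <- sort(unique(labels))
  k <- length(lev)
  if (k < 2) stop_io("Davies-Bouldin index needs at least 2 clusters.")
  if (aggregate == "min") {
    inform(paste("Davies-Bouldin aggregation uses min over the other clusters;",
                 "set aggregate = \"max\" for the conventional definition."),
           .frequency = "once", .frequency_id = "cafw_dbi_min")
  }
  centroids <- matrix(0, k, ncol(xm))
  for (i in seq_len(k)) {
    centroids[i, ] <- colMeans(xm[labels == lev[i], , drop = FALSE])
  }
  d_i <- vapply(seq_len(k), function(i) {
    pts <- xm[labels == lev[i], , drop = FALSE]
    mean(sqrt(rowSums((pts - matrix(centroids[i, ], nrow(pts), ncol(pts),
                                    byrow = TRUE))^2)))
  }, numeric(1))
  d_ij <- as.matrix(stats::dist(centroids))
  off <- d_ij[upper.tri(d_ij)]
  if (any(off == 0)) {
    pair <- which(d_ij == 0 & upper.tri(d_ij), arr.ind = TRUE)[1, ]
    stop_io(sprintf("Clusters '%s' and '%s' have coincident centroids; DBI undefined.",
                    lev[pair[1]], lev[pair[2]]))
  }
  ratio <- outer(d_i, d_i, "+") / d_ij
  diag(ratio) <- if (aggregate == "min") Inf else -Inf
  per_cluster <- apply(ratio, 1, aggregate)
  dbi <- mean(per_cluster)
  if (!details) return(dbi)
  list(dbi = dbi, d_i = setNames(d_i, lev), d_ij = d_ij,
       per_cluster = setNames(per_cluster, lev), aggregate = aggregate)
}

#' Evaluate a clustering against reference labels
#'
#' Convenience wrapper computing the adjusted Rand index of predicted versus
#' reference labels and (optionally) the Davies-Bouldin index of the data
#' under the reference labels.
#'
#' @param labels_true,labels_pred label vectors.
#' @param x optional [expr_matrix()] for the Davies-Bouldin index.
#' @inheritParams davies_bouldin_index
#' @return A one-row tibble with `ari` and (when `x` is given) `dbi`.
#' @export
evaluate_clustering <- function(labels_true, labels_pred, x = NULL,
                                aggregate = c("min", "max")) {
  out <- tibble::tibble(ari = adjusted_rand_index(labels_true, labels_pred))
  if (!is.null(x)) {
    out$dbi <- davies_bouldin_index(x, labels_true, aggregate = match.arg(aggregate))
  }
  out
}
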