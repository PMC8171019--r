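# Feature-weighted k-medians. The objective is
#
#   J = sum_k sum_{i in cluster k} sum_j w_kj |x_ij - c_kj|
#       + sum_k delta_k sum_j w_kj^2,   rows of W on the simplex,
#
# minimised by alternating four updates: assign cells to the nearest center
# under the weighted Manhattan distance, recompute centers as per-cluster
# medians, re-estimate the regulariser delta_k, and refresh each weight row
# from the closed-form stationarity condition. The weight matrix W is the
# quantity of interest downstream: genes that shrink intra-cluster spread
# gain weight above 1/n, noisy genes fall below it.

#' Per-feature Manhattan distance between a cell and a center
#'
#' @param x_i numeric vector, one cell's expression profile.
#' @param c_k numeric vector of the same length, a cluster center.
#' @return Non-negative vector `|x_i - c_k|`, elementwise.
#' @export
per_feature_distance <- function(x_i, c_k) {
  if (length(x_i) != length(c_k)) {
    stop_cluster("Cell and center vectors have different lengths.")
  }
  abs(x_i - c_k)
}

#' Weighted Manhattan distance of one cell to one center
#'
#' @inheritParams per_feature_distance
#' @param w numeric weight vector for the cluster (row of W).
#' @return `sum(w * |x_i - c_k|)`.
#' @export
weighted_distance <- function(x_i, c_k, w) {
  sum(w * per_feature_distance(x_i, c_k))
}

#' All cell-to-center weighted distances
#'
#' @param x numeric cells x genes matrix (or [expr_matrix()]).
#' @param centers K x genes center matrix.
#' @param W K x genes weight matrix.
#' @return m x K matrix of weighted Manhattan distances.
#' @export
weighted_distances <- function(x, centers, W) {
  x <- if (inherits(x, "expr_matrix")) x$values else x
  m <- nrow(x)
  K <- nrow(centers)
  D <- matrix(0, m, K)
  for (k in seq_len(K)) {
    D[, k] <- abs(x - matrix(centers[k, ], m, ncol(x), byrow = TRUE)) %*% W[k, ]
  }
  D
}

#' Assign each cell to its nearest cluster
#'
#' Ties are broken toward the lowest cluster index.
#'
#' @inheritParams weighted_distances
#' @return Integer vector of cluster indices, one per cell.
#' @export
assign_cells <- function(x, centers, W) {
  D <- weighted_distances(x, centers, W)
  max.col(-D, ties.method = "first")
}

#' Update cluster centers as per-feature medians
#'
#' Center coordinate `c_kj` is the median of feature j over the cells of
#' cluster k (even cluster sizes take the mean of the two middle values), and
#' is forced to 0 wherever `w_kj = 0`. Empty clusters keep their previous
#' center; the fitting loop handles re-seeding.
#'
#' @inheritParams weighted_distances
#' @param assignments integer vector of cluster indices per cell.
#' @param W weight matrix; pass `NULL` to skip the `w_kj = 0` zeroing.
#' @return Updated K x genes center matrix.
#' @export
update_centers <- function(x, assignments, centers, W = NULL) {
  x <- if (inherits(x, "expr_matrix")) x$values else x
  K <- nrow(centers)
  out <- centers
  for (k in seq_len(K)) {
    members <- which(assignments == k)
    if (length(members) == 0L) next
    out[k, ] <- col_medians(x[members, , drop = FALSE])
    if (!is.null(W)) out[k, W[k, ] == 0] <- 0
  }
  out
}

#' Closed-form weight-row update
#'
#' Evaluates the stationarity condition of the objective for one cluster:
#' `w_kj = 1/n + (1 / (2 delta_k)) * sum_i [ mean_j'(d_ki^j') - d_ki^j ]`
#' summed over the cluster's cells, where `d_ki^j = |x_ij - c_kj|`. The raw
#' row sums to 1 by construction; negatives are then clamped to 0 and the row
#' renormalised so the constraints `w_kj in [0, 1]`, `sum_j w_kj = 1` hold.
#'
#' @param x cells x genes matrix (or [expr_matrix()]).
#' @param members integer indices of the cells in the cluster.
#' @param center numeric center vector for the cluster.
#' @param delta positive regulariser `delta_k`.
#' @return List with `raw` (the unprojected row) and `w` (the projected row).
#' @export
update_weight_row <- function(x, members, center, delta) {
  x <- if (inherits(x, "expr_matrix")) x$values else x
  n <- ncol(x)
  if (length(members) == 0L) stop_cluster("Cannot update weights of an empty cluster.")
  if (delta <= 0) stop_cluster("`delta` must be positive.")
  d <- abs(x[members, , drop = FALSE] -
             matrix(center, length(members), n, byrow = TRUE))
  bracket <- rowSums(d) / n - d                       # m_k x n
  raw <- 1 / n + colSums(bracket) / (2 * delta)
  w <- pmax(raw, 0)
  w <- w / sum(w)
  list(raw = raw, w = w)
}

#' Re-estimate the per-cluster regulariser
#'
#' `delta_k = C_delta * [sum_i sum_j w_kj d_ki^j] / [sum_j w_kj^2]`, computed
#' from the supplied (previous-iteration) weight row, center and membership.
#' A degenerate cluster with zero total distance keeps `prev_delta`.
#'
#' @inheritParams update_weight_row
#' @param w weight row used in the numerator and denominator.
#' @param c_delta the proportionality constant `C_delta`.
#' @param prev_delta value to keep when the numerator is zero.
#' @return Positive scalar `delta_k`.
#' @export
update_delta <- function(x, members, center, w, c_delta = 1, prev_delta = 1) {
  x <- if (inherits(x, "expr_matrix")) x$values else x
  if (length(members) == 0L) return(prev_delta)
  d <- abs(x[members, , drop = FALSE] -
             matrix(center, length(members), ncol(x), byrow = TRUE))
  num <- sum(d %*% w)
  if (num == 0) return(prev_delta)
  c_delta * num / sum(w^2)
}

#' Objective value of a full model state
#'
#' @inheritParams update_centers
#' @param delta length-K vector of regularisers.
#' @return The scalar objective `J`.
#' @export
objective_value <- function(x, W, centers, delta, assignments) {
  D <- weighted_distances(x, centers, W)
  sum(D[cbind(seq_len(nrow(D)), assignments)]) + sum(delta * rowSums(W^2))
}

#' Fit the feature-weighted k-medians model
#'
#' Initialises uniform weights and centers at K distinct cells drawn under
#' `seed`, then sweeps assign -> centers -> delta -> weights until the
#' assignments stop changing, the relative objective change drops below
#' `tol`, or `max_iter` sweeps have run. The delta update for sweep t uses
#' the weight rows of sweep t-1 together with the freshly updated assignments
#' and centers.
#'
#' @param x an [expr_matrix()] (or plain cells x genes matrix), preprocessed.
#' @param K number of clusters, `2 <= K <= n_cells` (the cluster count is a
#'   required input; the model does not estimate it).
#' @param c_delta proportionality constant of the delta update. The single
#'   most consequential free parameter: large values push all weight rows
#'   back toward uniform, small values sharpen them. Default 1.
#' @param max_iter maximum number of sweeps.
#' @param tol relative objective-change convergence tolerance.
#' @param seed integer seed controlling the center initialisation.
#' @param freeze_weights if `TRUE`, weights stay uniform and delta is never
#'   updated, reducing the fit to plain Manhattan k-medians (useful for
#'   cross-checks).
#' @return A `cafw_fit` object: list with `W`, `centers`, `delta`,
#'   `assignments`, `c_delta`, `objective_trace`, `n_iter`, `converged`,
#'   `seed`, `init_cells`, `max_raw_row_dev` (largest deviation of any raw
#'   weight-row sum from 1 seen during the fit), `n_reseeds`, `gene_ids`,
#'   `cell_ids`.
#' @examples
#' ds <- simulate_expression(K = 2, cells_per_cluster = 20, n_informative = 5,
#'                           n_noise = 20, seed = 1)
#' fit <- weighted_kmedians(ds$matrix, K = 2, seed = 1)
#' glance(fit)
#' @export
weighted_kmedians <- function(x, K, c_delta = 1, max_iter = 100, tol = 1e-6,
                              seed = 1L, freeze_weights = FALSE) {
  xm <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  m <- nrow(xm)
  n <- ncol(xm)
  if (K < 2 || K > m) stop_cluster("`K` must satisfy 2 <= K <= number of cells.")

  set.seed(as.integer(seed))
  init <- init_centers(xm, K)
  centers <- init$centers
  W <- matrix(1 / n, K, n)
  delta <- rep(1, K)
  assignments <- assign_cells(xm, centers, W)
  # first delta estimate from the uniform weights and initial assignments
  if (!freeze_weights) {
    for (k in seq_len(K)) {
      delta[k] <- update_delta(xm, which(assignments == k), centers[k, ],
                               W[k, ], c_delta, prev_delta = 1)
    }
  }

  trace <- numeric(0)
  prev_J <- NA_real_
  converged <- FALSE
  max_raw_dev <- 0
  n_reseeds <- 0L
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    new_assign <- assign_cells(xm, centers, W)

    # empty-cluster policy: re-seed at the cell farthest from its own center
    empty <- setdiff(seq_len(K), unique(new_assign))
    for (k in empty) {
      D_own <- weighted_distances(xm, centers, W)
      own <- D_own[cbind(seq_len(m), new_assign)]
      far <- which.max(own)
      centers[k, ] <- xm[far, ]
      W[k, ] <- 1 / n
      new_assign[far] <- k
      n_reseeds <- n_reseeds + 1L
    }

    stable <- identical(new_assign, assignments) && iter > 1L
    assignments <- new_assign
    centers <- update_centers(xm, assignments, centers, W)

    if (!freeze_weights) {
      for (k in seq_len(K)) {
        members <- which(assignments == k)
        delta[k] <- update_delta(xm, members, centers[k, ], W[k, ],
                                 c_delta, prev_delta = delta[k])
      }
      for (k in seq_len(K)) {
        members <- which(assignments == k)
        if (length(members) == 0L) next
        upd <- update_weight_row(xm, members, centers[k, ], delta[k])
        max_raw_dev <- max(max_raw_dev, abs(sum(upd$raw) - 1))
        W[k, ] <- upd$w
      }
    }

    J <- objective_value(xm, W, centers, delta, assignments)
    trace <- c(trace, J)
    if (stable || (!is.na(prev_J) && abs(J - prev_J) / max(J, 1) < tol)) {
      converged <- TRUE
      break
    }
    prev_J <- J
  }

  structure(
    list(
      W = `colnames<-`(W, colnames(xm)),
      centers = `colnames<-`(centers, colnames(xm)),
      delta = delta,
      assignments = assignments,
      c_delta = c_delta,
      objective_trace = trace,
      n_iter = iter,
      converged = converged,
      seed = as.integer(seed),
      init_cells = init$idx,
      max_raw_row_dev = max_raw_dev,
      n_reseeds = n_reseeds,
      freeze_weights = freeze_weights,
      gene_ids = colnames(xm),
      cell_ids = rownames(xm)
    ),
    class = "cafw_fit"
  )
}

init_centers <- function(xm, K) {
  m <- nrow(xm)
  dup <- duplicated(xm)
  distinct <- which(!dup)
  if (length(distinct) >= K) {
    idx <- sort(sample(distinct, K))
  } else {
    warn("Fewer than K distinct cells; sampling with replacement plus jitter for initial centers.")
    idx <- sort(sample(seq_len(m), K, replace = TRUE))
  }
  centers <- xm[idx, , drop = FALSE]
  if (length(distinct) < K) {
    centers <- centers + matrix(runif(length(centers), 0, 1e-8), K, ncol(xm))
  }
  list(centers = centers, idx = idx)
}

#' @export
print.cafw_fit <- function(x, ...) {
  cat(sprintf(
    "<cafw_fit> K=%d clusters, %d genes, %d cells | C_delta=%g | %d sweeps (%s)\n",
    nrow(x$W), ncol(x$W), length(x$assignments), x$c_delta, x$n_iter,
    if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  objective %.6g | cluster sizes: %s\n",
              x$objective_trace[length(x$objective_trace)],
              paste(tabulate(x$assignments, nrow(x$W)), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.cafw_fit <- function(x, ...) {
  K <- nrow(x$W)
  gid <- x$gene_ids %||% paste0("gene_", seq_len(ncol(x$W)))
  tibble::tibble(
    gene_id = rep(gid, each = K),
    cluster = rep(seq_len(K), times = ncol(x$W)),
    weight = as.vector(x$W),
    center = as.vector(x$centers)
  )
}

#' @export
glance.cafw_fit <- function(x, ...) {
  tibble::tibble(
    K = nrow(x$W),
    n_genes = ncol(x$W),
    n_cells = length(x$assignments),
    c_delta = x$c_delta,
    n_iter = x$n_iter,
    converged = x$converged,
    objective = x$objective_trace[length(x$objective_trace)],
    max_raw_row_dev = x$max_raw_row_dev
  )
}

#' Serialise a fitted model to a JSON + TSV bundle
#'
#' Writes `<stem>.json` (delta, assignments, trace, metadata) and
#' `<stem>_weights.tsv` / `<stem>_centers.tsv` (genes in columns, gene ids in
#' the header, one row per cluster).
#'
#' @param fit a `cafw_fit`.
#' @param stem output path stem (directory must exist).
#' @return `stem`, invisibly.
#' @export
write_fit <- function(fit, stem) {
  meta <- list(
    K = nrow(fit$W), c_delta = fit$c_delta, seed = fit$seed,
    n_iter = fit$n_iter, converged = fit$converged,
    delta = fit$delta, objective_trace = fit$objective_trace,
    assignments = setNames(as.list(fit$assignments), fit$cell_ids)
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  wdf <- tibble::as_tibble(fit$W, .name_repair = "minimal")
  names(wdf) <- fit$gene_ids
  readr::write_tsv(wdf, paste0(stem, "_weights.tsv"), progress = FALSE)
  cdf <- tibble::as_tibble(fit$centers, .name_repair = "minimal")
  names(cdf) <- fit$gene_ids
  readr::write_tsv(cdf, paste0(stem, "_centers.tsv"), progress = FALSE)
  invisible(stem)
}
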