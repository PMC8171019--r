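# Synthetic scRNA-seq-like data with known cluster structure: a small set of
# planted marker ("informative") genes whose mean expression is shifted in
# one cluster each, a large background of noise genes with a shared mean,
# negative-binomial counts and independent dropout zero-inflation.

#' Simulate a clustered expression matrix
#'
#' Base expression means are drawn log-normally. Each informative gene is a
#' marker of one cluster (assigned round-robin): its mean in that cluster is
#' multiplied by `2^effect_size`. Noise genes share one mean across clusters.
#' Counts are negative-binomial with the given dispersion (variance
#' `mu + dispersion * mu^2`; `dispersion = 0` gives Poisson), and zeros are
#' injected independently at `dropout_rate` to mimic dropout events.
#'
#' @param K number of clusters, at least 2.
#' @param cells_per_cluster cells in each cluster.
#' @param n_informative number of planted marker genes (0 allowed, for pure
#'   noise fixtures).
#' @param n_noise number of background genes.
#' @param effect_size log2 fold change of a marker gene in its own cluster;
#'   must be positive when `n_informative > 0`.
#' @param dropout_rate probability that any entry is zeroed, in `[0, 1)`.
#' @param dispersion negative-binomial dispersion (0 for Poisson counts).
#' @param base_mean median of the log-normal base-mean distribution.
#' @param seed integer seed; the data set is fully reproducible from it.
#' @return A `synthetic_dataset`: list with `matrix` (an [expr_matrix()]),
#'   `labels` (named integer vector of true cluster indices),
#'   `informative_genes` (character) and `params`.
#' @examples
#' ds <- simulate_expression(K = 2, cells_per_cluster = 10, n_informative = 4,
#'                           n_noise = 30, seed = 42)
#' table(ds$labels)
#' @export
simulate_expression <- function(K = 5, cells_per_cluster = 100,
                                n_informative = 50, n_noise = 1950,
                                effect_size = 3, dropout_rate = 0.2,
                                dispersion = 0.3, base_mean = 5, seed = 1L) {
  if (K < 2) stop_io("`K` must be at least 2.")
  if (n_informative < 0 || n_noise < 0 || n_informative + n_noise < 2) {
    stop_io("Need at least 2 genes in total.")
  }
  if (n_informative > 0 && effect_size <= 0) stop_io("`effect_size` must be positive.")
  if (dropout_rate < 0 || dropout_rate >= 1) stop_io("`dropout_rate` must be in [0, 1).")
  if (dispersion < 0) stop_io("`dispersion` must be non-negative.")
  if (K * cells_per_cluster < 2) stop_io("Need at least 2 cells.")

  set.seed(as.integer(seed))
  n <- n_informative + n_noise
  m <- K * cells_per_cluster
  labels <- rep(seq_len(K), each = cells_per_cluster)
  genes <- sprintf("gene_%04d", seq_len(n))
  cells <- sprintf("cell_%04d", seq_len(m))
  informative <- if (n_informative > 0) genes[seq_len(n_informative)] else character(0)

  base <- rlnorm(n, meanlog = log(base_mean), sdlog = 0.5)
  # K x n matrix of cluster means; marker gene g is shifted in cluster
  # (g - 1) %% K + 1
  mu <- matrix(base, K, n, byrow = TRUE)
  if (n_informative > 0) {
    marker_cluster <- ((seq_len(n_informative) - 1L) %% K) + 1L
    mu[cbind(marker_cluster, seq_len(n_informative))] <-
      base[seq_len(n_informative)] * 2^effect_size
  }

  mu_cells <- mu[labels, , drop = FALSE]
  counts <- if (dispersion == 0) {
    matrix(rpois(m * n, lambda = mu_cells), m, n)
  } else {
    matrix(rnbinom(m * n, mu = mu_cells, size = 1 / dispersion), m, n)
  }
  if (dropout_rate > 0) {
    counts[matrix(runif(m * n) < dropout_rate, m, n)] <- 0
  }
  dimnames(counts) <- list(cells, genes)

  structure(
    list(
      matrix = expr_matrix(counts, unit = "UMI"),
      labels = setNames(labels, cells),
      informative_genes = informative,
      params = list(K = K, cells_per_cluster = cells_per_cluster,
                    n_informative = n_informative, n_noise = n_noise,
                    effect_size = effect_size, dropout_rate = dropout_rate,
                    dispersion = dispersion, base_mean = base_mean,
                    seed = as.integer(seed))
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> K=%d, %d cells, %d genes (%d informative), seed %d\n",
              x$params$K, n_cells(x$matrix), n_genes(x$matrix),
              x$params$n_informative, x$params$seed))
  invisible(x)
}

#' Write a synthetic data set to a directory
#'
#' Emits `matrix.tsv` (cells x genes), `labels.tsv` (cell id, cluster) and
#' `truth.json` (simulation parameters and planted informative genes).
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(ds$matrix, file.path(dir, "matrix.tsv"))
  write_labels(ds$labels, file.path(dir, "labels.tsv"))
  jsonlite::write_json(
    list(params = ds$params, informative_genes = ds$informative_genes),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
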