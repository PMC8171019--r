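# Preprocessing: drop genes detected in too few cells, then collapse
# near-duplicate genes by Pearson correlation. Both filters leave surviving
# values untouched and never drop cells.

#' Remove rarely expressed genes
#'
#' A gene survives when it is expressed (value strictly greater than zero) in
#' at least `ceiling(min_cell_frac * n_cells)` cells; genes expressed in fewer
#' cells — "less than 2%" of cells at the default — are deleted. Genes sitting
#' exactly on the threshold are kept.
#'
#' @param x an [expr_matrix()].
#' @param min_cell_frac minimum fraction of expressing cells, in `[0, 1)`.
#' @return A list with `matrix` (the filtered [expr_matrix()]) and `report`
#'   (tibble: `gene_id`, `n_expressing`, `kept`).
#' @export
filter_rare_genes <- function(x, min_cell_frac = 0.02) {
  x <- as_expr_matrix(x)
  if (min_cell_frac < 0 || min_cell_frac >= 1) {
    stop_preprocess("`min_cell_frac` must be in [0, 1).")
  }
  m <- n_cells(x)
  n_expressing <- colSums(x$values > 0)
  keep <- n_expressing >= ceiling(min_cell_frac * m)
  if (!any(keep)) {
    stop_preprocess(sprintf(
      "All %d genes are expressed in fewer than %.1f%% of cells; lower `min_cell_frac`.",
      n_genes(x), 100 * min_cell_frac))
  }
  report <- tibble::tibble(
    gene_id = gene_ids(x),
    n_expressing = as.integer(n_expressing),
    kept = unname(keep)
  )
  list(
    matrix = expr_matrix(x$values[, keep, drop = FALSE], unit = x$unit),
    report = report
  )
}

#' Collapse redundant genes by Pearson correlation
#'
#' Sweeps genes in input order and absorbs each gene into the first
#' earlier-indexed retained gene whose Pearson correlation across cells is
#' strictly greater than `pcc_threshold`. Constant genes (zero variance,
#' undefined correlation) are always retained and never absorb or get
#' absorbed.
#'
#' @param x an [expr_matrix()] with at least 2 genes.
#' @param pcc_threshold correlation threshold in `(0, 1]`; the default 0.99
#'   keeps one representative for groups of near-identical genes.
#' @return A list with `matrix` (representatives only) and `report` (tibble:
#'   `gene_id`, `kept`, `representative` — the absorbing gene for dropped
#'   genes, `NA` for survivors).
#' @export
remove_redundant_genes <- function(x, pcc_threshold = 0.99) {
  x <- as_expr_matrix(x)
  if (pcc_threshold <= 0 || pcc_threshold > 1) {
    stop_preprocess("`pcc_threshold` must be in (0, 1].")
  }
  v <- x$values
  n <- ncol(v)
  constant <- apply(v, 2, function(col) all(col == col[1]))
  cc <- suppressWarnings(cor(v))
  keep <- logical(n)
  representative <- rep(NA_character_, n)
  ids <- gene_ids(x)
  for (j in seq_len(n)) {
    if (constant[j]) {
      keep[j] <- TRUE
      next
    }
    prior <- which(keep[seq_len(j - 1L)] & !constant[seq_len(j - 1L)])
    hit <- prior[which(cc[prior, j] > pcc_threshold)[1L]]
    if (length(hit) == 1L && !is.na(hit)) {
      representative[j] <- ids[hit]
    } else {
      keep[j] <- TRUE
    }
  }
  report <- tibble::tibble(gene_id = ids, kept = keep, representative = representative)
  list(
    matrix = expr_matrix(v[, keep, drop = FALSE], unit = x$unit),
    report = report
  )
}

#' Run both preprocessing filters
#'
#' Applies [filter_rare_genes()] then [remove_redundant_genes()] and collects
#' a combined provenance report. The order (rare filter first) is fixed.
#'
#' @inheritParams filter_rare_genes
#' @inheritParams remove_redundant_genes
#' @return A list with `matrix` (the preprocessed [expr_matrix()]) and
#'   `report`, a `preprocess_report` object.
#' @export
preprocess <- function(x, min_cell_frac = 0.02, pcc_threshold = 0.99) {
  x <- as_expr_matrix(x)
  n_input <- n_genes(x)
  rare <- filter_rare_genes(x, min_cell_frac)
  red <- remove_redundant_genes(rare$matrix, pcc_threshold)
  removed_rare <- rare$report$gene_id[!rare$report$kept]
  absorbed <- red$report[!red$report$kept, , drop = FALSE]
  groups <- split(absorbed$gene_id, absorbed$representative)
  report <- structure(
    list(
      n_input_genes = n_input,
      n_after_rare_filter = n_genes(rare$matrix),
      n_after_redundancy = n_genes(red$matrix),
      removed_rare = removed_rare,
      redundancy_groups = groups,
      survivors = gene_ids(red$matrix),
      min_cell_frac = min_cell_frac,
      pcc_threshold = pcc_threshold
    ),
    class = "preprocess_report"
  )
  list(matrix = red$matrix, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("<preprocess_report> %d genes -> %d after rare-gene filter -> %d after redundancy\n",
              x$n_input_genes, x$n_after_rare_filter, x$n_after_redundancy))
  invisible(x)
}

#' @export
glance.preprocess_report <- function(x, ...) {
  tibble::tibble(
    n_input_genes = x$n_input_genes,
    n_after_rare_filter = x$n_after_rare_filter,
    n_after_redundancy = x$n_after_redundancy,
    n_removed_rare = length(x$removed_rare),
    n_absorbed = x$n_after_rare_filter - x$n_after_redundancy
  )
}
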