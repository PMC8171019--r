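# End-to-end driver: preprocess -> weighted clustering -> two-stage gene
# screen -> artifacts. Mirrors the three-step selection pipeline and logs the
# per-stage gene counts (#Genes, #Genes-S1, #Genes-S2 with percentages).

#' Run the full gene-selection pipeline
#'
#' Loads (or takes) an expression matrix, applies the rare-gene and
#' redundancy filters, fits the feature-weighted k-medians model, screens
#' genes in two stages, and optionally evaluates the clustering against
#' reference labels and writes all artifacts under `out_dir`.
#'
#' @param input a file path (see [load_expression()]), an [expr_matrix()] or
#'   a `synthetic_dataset` (whose true labels are then used for evaluation
#'   unless `labels` is supplied).
#' @inheritParams load_expression
#' @inheritParams weighted_kmedians
#' @inheritParams preprocess
#' @inheritParams select_genes
#' @param labels optional reference labels: a named vector or a path to a
#'   two-column TSV (cell id, label).
#' @param out_dir optional output directory; when given, writes
#'   `preprocess_report.json`, the model bundle (`model.json`,
#'   `model_weights.tsv`, `model_centers.tsv`), `screening_report.json`,
#'   `selected_genes.txt`, `reduced_matrix.tsv`, `assignments.tsv` and, with
#'   labels, `metrics.json`. Input files are never touched.
#' @param verbose print per-stage gene counts.
#' @return A `cafw_run` list: `preprocess` report, `fit`, `screening` report,
#'   `selected_genes`, `reduced` matrix, `metrics` (tibble or `NULL`) and
#'   `counts` (one-row tibble of per-stage gene counts).
#' @export
run_pipeline <- function(input, K,
                         layout = c("cells-by-genes", "genes-by-cells"),
                         format = c("auto", "delimited", "mtx"),
                         min_cell_frac = 0.02, pcc_threshold = 0.99,
                         c_delta = 1, max_iter = 100, tol = 1e-6, seed = 1L,
                         s1_target = 10000, p_threshold = 0.05,
                         labels = NULL, out_dir = NULL, verbose = TRUE) {
  truth <- NULL
  if (inherits(input, "synthetic_dataset")) {
    truth <- input$labels
    x <- input$matrix
  } else if (inherits(input, "expr_matrix")) {
    x <- input
  } else {
    x <- load_expression(input, layout = match.arg(layout), format = match.arg(format))
  }
  if (is.character(labels) && length(labels) == 1L) labels <- read_labels(labels)
  if (is.null(labels)) labels <- truth

  pp <- preprocess(x, min_cell_frac = min_cell_frac, pcc_threshold = pcc_threshold)
  sel <- select_genes(pp$matrix, K = K, c_delta = c_delta, max_iter = max_iter,
                      tol = tol, seed = seed, s1_target = s1_target,
                      p_threshold = p_threshold)

  counts <- tibble::tibble(
    n_genes = n_genes(x),
    n_genes_s1 = length(sel$report$survivors_s1),
    n_genes_s2 = length(sel$report$survivors_s2),
    pct_s1 = 100 * length(sel$report$survivors_s1) / n_genes(x),
    pct_s2 = 100 * length(sel$report$survivors_s2) / n_genes(x)
  )
  if (verbose) {
    message(sprintf("#Genes %d | #Genes-S1 %d (%.1f%%) | #Genes-S2 %d (%.1f%%)",
                    counts$n_genes, counts$n_genes_s1, counts$pct_s1,
                    counts$n_genes_s2, counts$pct_s2))
  }

  metrics <- NULL
  if (!is.null(labels)) {
    lab <- align_labels(labels, cell_ids(x))
    metrics <- tibble::tibble(
      ari = adjusted_rand_index(lab, sel$fit$assignments),
      dbi_all_genes = davies_bouldin_index(pp$matrix, lab),
      dbi_selected = if (!is.null(sel$matrix))
        davies_bouldin_index(sel$matrix, lab) else NA_real_
    )
  }

  run <- structure(
    list(preprocess = pp$report, fit = sel$fit, screening = sel$report,
         selected_genes = sel$report$survivors_s2, reduced = sel$matrix,
         metrics = metrics, counts = counts),
    class = "cafw_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

align_labels <- function(labels, cells) {
  if (!is.null(names(labels)) && all(cells %in% names(labels))) {
    return(unname(labels[cells]))
  }
  if (length(labels) != length(cells)) {
    stop_io("Labels do not cover all cells (by name) and lengths differ.")
  }
  unname(labels)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pr <- run$preprocess
  jsonlite::write_json(
    list(n_input_genes = pr$n_input_genes,
         n_after_rare_filter = pr$n_after_rare_filter,
         n_after_redundancy = pr$n_after_redundancy,
         removed_rare = pr$removed_rare,
         redundancy_groups = pr$redundancy_groups,
         min_cell_frac = pr$min_cell_frac, pcc_threshold = pr$pcc_threshold),
    file.path(out_dir, "preprocess_report.json"), auto_unbox = TRUE, digits = NA)
  write_fit(run$fit, file.path(out_dir, "model"))
  write_screening_report(run$screening, file.path(out_dir, "screening_report.json"))
  readr::write_lines(run$selected_genes, file.path(out_dir, "selected_genes.txt"))
  if (!is.null(run$reduced)) {
    write_expression(run$reduced, file.path(out_dir, "reduced_matrix.tsv"))
  }
  write_labels(setNames(run$fit$assignments, run$fit$cell_ids),
               file.path(out_dir, "assignments.tsv"))
  if (!is.null(run$metrics)) {
    jsonlite::write_json(as.list(run$metrics), file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' @export
print.cafw_run <- function(x, ...) {
  cat(sprintf("<cafw_run> #Genes %d | #Genes-S1 %d (%.1f%%) | #Genes-S2 %d (%.1f%%)\n",
              x$counts$n_genes, x$counts$n_genes_s1, x$counts$pct_s1,
              x$counts$n_genes_s2, x$counts$pct_s2))
  if (!is.null(x$metrics)) {
    cat(sprintf("  ARI %.3f | DBI all genes %.3f | DBI selected %.3f\n",
                x$metrics$ari, x$metrics$dbi_all_genes, x$metrics$dbi_selected))
  }
  invisible(x)
}
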