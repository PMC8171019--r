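# The cells x genes expression container used throughout the package.

#' Construct an expression matrix
#'
#' Wraps a non-negative cells x genes matrix of expression values (UMI counts,
#' CPM or FPKM) together with unique cell and gene identifiers. All downstream
#' steps — preprocessing filters, feature-weighted clustering, gene screening —
#' consume this container.
#'
#' @param values numeric matrix, cells in rows, genes in columns. A sparse
#'   `Matrix` is accepted and densified.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   the row names of `values`).
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   the column names of `values`).
#' @param unit free-text label for the expression unit (e.g. `"UMI"`,
#'   `"CPM"`, `"FPKM"`).
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the named matrix) and `unit`.
#' @examples
#' m <- matrix(rpois(12, 4), nrow = 3,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' x <- expr_matrix(m, unit = "UMI")
#' n_cells(x)
#' n_genes(x)
#' @export
expr_matrix <- function(values, cell_ids = rownames(values),
                        gene_ids = colnames(values), unit = "counts") {
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_io("`values` must be a numeric matrix (cells x genes).")
  }
  storage.mode(values) <- "double"
  m <- nrow(values)
  n <- ncol(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(m))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(n))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != m) stop_io("`cell_ids` length does not match the number of rows.")
  if (length(gene_ids) != n) stop_io("`gene_ids` length does not match the number of columns.")
  # loaders enforce m, n >= 2; downstream filters may legitimately reduce a
  # matrix to a single surviving gene, so the container itself only needs 1
  if (m < 1L || n < 1L) stop_io("An expression matrix needs at least 1 cell and 1 gene.")
  if (anyNA(values)) stop_io("Expression values contain missing entries.")
  if (any(values < 0)) stop_io("Expression values must be non-negative.")
  if (anyDuplicated(cell_ids)) stop_io("Duplicate cell identifiers.")
  if (anyDuplicated(gene_ids)) stop_io("Duplicate gene identifiers.")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, unit = unit), class = "expr_matrix")
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
n_cells <- function(x) nrow(x$values)

#' @rdname expr_matrix
#' @export
n_genes <- function(x) ncol(x$values)

#' @rdname expr_matrix
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname expr_matrix
#' @export
gene_ids <- function(x) colnames(x$values)

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' @export
print.expr_matrix <- function(x, ...) {
  zf <- mean(x$values == 0)
  cat(sprintf("<expr_matrix> %d cells x %d genes [%s], %.1f%% zeros\n",
              n_cells(x), n_genes(x), x$unit, 100 * zf))
  invisible(x)
}

#' Restrict an expression matrix to a gene subset
#'
#' @param x an `expr_matrix`.
#' @param genes character vector of gene identifiers to keep (order is
#'   preserved as given).
#' @return An `expr_matrix` with only the requested genes.
#' @export
subset_genes <- function(x, genes) {
  missing <- setdiff(genes, gene_ids(x))
  if (length(missing) > 0) {
    stop_io(sprintf("Unknown gene identifiers: %s", paste(head(missing, 5), collapse = ", ")))
  }
  expr_matrix(x$values[, genes, drop = FALSE], unit = x$unit)
}

#' Optional log transform
#'
#' Applies `log2(x + 1)` to all values. Off by default everywhere in the
#' package: distances, weights and screens operate on the loaded values.
#'
#' @param x an `expr_matrix`.
#' @return A transformed `expr_matrix` with unit label suffixed `" (log2+1)"`.
#' @export
transform_log2 <- function(x) {
  expr_matrix(log2(x$values + 1), unit = paste0(x$unit, " (log2+1)"))
}

as_expr_matrix <- function(x, unit = "counts") {
  if (inherits(x, "expr_matrix")) return(x)
  expr_matrix(as.matrix(x), unit = unit)
}
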