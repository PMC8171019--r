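# Readers and writers for the two on-disk matrix layouts: delimited text
# (TSV/CSV with a header row and an id column) and Matrix Market triplets
# with gene / barcode sidecar files (10x-style).

#' Load an expression matrix from disk
#'
#' Reads dense delimited text (TSV/CSV; header row of ids, first column of
#' ids) or a Matrix Market triplet file with plain-text gene and barcode
#' sidecars, and returns the data in cells x genes orientation regardless of
#' the on-disk layout.
#'
#' @param path path to the matrix file (`.tsv`/`.csv`/`.txt` or `.mtx`).
#' @param layout orientation of the on-disk matrix: `"cells-by-genes"` or
#'   `"genes-by-cells"`.
#' @param format `"auto"` (by file extension), `"delimited"` or `"mtx"`.
#' @param genes_file,cells_file sidecar paths for `mtx` input; default to
#'   `genes.tsv` (or `features.tsv`) and `barcodes.tsv` next to `path`.
#' @param unit expression unit label carried through to the result.
#' @return An [expr_matrix()] in cells x genes orientation.
#' @export
load_expression <- function(path,
                            layout = c("cells-by-genes", "genes-by-cells"),
                            format = c("auto", "delimited", "mtx"),
                            genes_file = NULL, cells_file = NULL,
                            unit = "counts") {
  layout <- match.arg(layout)
  format <- match.arg(format)
  if (!file.exists(path)) stop_io(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "delimited"
  }
  x <- switch(format,
    delimited = read_delimited_matrix(path),
    mtx = read_mtx_matrix(path, genes_file, cells_file, layout)
  )
  if (layout == "genes-by-cells") x <- t(x)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop_io(sprintf("'%s' holds fewer than 2 cells or 2 genes.", path))
  }
  tryCatch(
    expr_matrix(x, unit = unit),
    cafw_io_error = function(e) {
      stop_io(sprintf("Malformed expression file '%s': %s", path, conditionMessage(e)))
    }
  )
}

read_delimited_matrix <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE,
                          name_repair = "minimal")
  if (ncol(df) < 2L) stop_io(sprintf("'%s' has no data columns.", path))
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_io(sprintf("Non-numeric entries in '%s'.", path))
  rownames(m) <- ids
  m
}

read_mtx_matrix <- function(path, genes_file, cells_file, layout) {
  dir <- dirname(path)
  if (is.null(genes_file)) {
    for (cand in c("genes.tsv", "features.tsv")) {
      if (file.exists(file.path(dir, cand))) genes_file <- file.path(dir, cand)
    }
  }
  if (is.null(cells_file) && file.exists(file.path(dir, "barcodes.tsv"))) {
    cells_file <- file.path(dir, "barcodes.tsv")
  }
  if (is.null(genes_file) || !file.exists(genes_file)) {
    stop_io("Gene sidecar file for MTX input not found; pass `genes_file`.")
  }
  if (is.null(cells_file) || !file.exists(cells_file)) {
    stop_io("Barcode sidecar file for MTX input not found; pass `cells_file`.")
  }
  sm <- Matrix::readMM(path)
  genes <- read_id_column(genes_file)
  cells <- read_id_column(cells_file)
  if (layout == "genes-by-cells") {
    if (nrow(sm) != length(genes) || ncol(sm) != length(cells)) {
      stop_io(sprintf("MTX dimensions %d x %d do not match sidecars (%d genes, %d cells).",
                      nrow(sm), ncol(sm), length(genes), length(cells)))
    }
    dimnames(sm) <- list(genes, cells)
  } else {
    if (nrow(sm) != length(cells) || ncol(sm) != length(genes)) {
      stop_io(sprintf("MTX dimensions %d x %d do not match sidecars (%d cells, %d genes).",
                      nrow(sm), ncol(sm), length(cells), length(genes)))
    }
    dimnames(sm) <- list(cells, genes)
  }
  as.matrix(sm)
}

read_id_column <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write an expression matrix to disk
#'
#' @param x an [expr_matrix()].
#' @param path output path; `.csv` writes comma-separated, anything else
#'   tab-separated, and `.mtx` writes a Matrix Market triplet with
#'   `genes.tsv` / `barcodes.tsv` sidecars next to it.
#' @param layout on-disk orientation to write.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, layout = c("cells-by-genes", "genes-by-cells")) {
  layout <- match.arg(layout)
  m <- x$values
  if (layout == "genes-by-cells") m <- t(m)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    # sidecars always describe the cells x genes object, 10x-style
    readr::write_lines(gene_ids(x), file.path(dirname(path), "genes.tsv"))
    readr::write_lines(cell_ids(x), file.path(dirname(path), "barcodes.tsv"))
    return(invisible(path))
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tibble::as_tibble(m, rownames = "id")
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a two-column label file
#'
#' @param path TSV with columns cell id and cluster label (no header needed;
#'   a header line is detected and skipped when its second field is not
#'   numeric and matches common header words).
#' @return A named vector of labels (names are cell ids).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("Label file not found: %s", path))
  df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                        progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2L) stop_io("Label file needs two columns: cell id, cluster label.")
  if (nrow(df) > 0 && tolower(df[[2]][1]) %in% c("label", "cluster", "cluster_label")) {
    df <- df[-1, , drop = FALSE]
  }
  setNames(df[[2]], df[[1]])
}

#' @rdname read_labels
#' @param labels named vector of cluster labels (names are cell ids).
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(tibble::tibble(cell_id = names(labels), cluster = unname(labels)),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
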