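#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported: MatrixMarket coordinate format
#' (`<stem>.mtx` with sidecar gene and cell lists `<stem>.genes.txt`,
#' `<stem>.cells.txt`) for sparse counts, and dense delimited text (CSV/TSV,
#' first column = gene symbol, header = cell IDs). On disk genes are rows by
#' default; set `orientation = "cells_by_genes"` for transposed sources such
#' as the Allen SMART-Seq distribution.
#'
#' @param path Path to the `.mtx` or `.csv`/`.tsv` file.
#' @param format `"auto"` (from extension), `"mtx"` or `"csv"`.
#' @param unit Unit tag of the stored values, `"counts"` or `"CPM"`.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`.
#' @param sep Field separator for dense text (`","` for .csv, `"\t"` for .tsv).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "mtx", "csv"),
                            unit = c("counts", "CPM"),
                            orientation = c("genes_by_cells", "cells_by_genes"),
                            sep = NULL) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    gene_file <- paste0(stem, ".genes.txt")
    cell_file <- paste0(stem, ".cells.txt")
    for (f in c(gene_file, cell_file)) {
      if (!file.exists(f)) stop("sidecar file not found: ", f, call. = FALSE)
    }
    .validate_mtx_coords(path)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (orientation == "cells_by_genes") {
      m <- t(m)
      tmp <- genes  # sidecars follow the stored orientation
      genes <- cells
      cells <- tmp
    }
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop(sprintf("dimension mismatch: matrix %dx%d vs %d genes, %d cells",
                   nrow(m), ncol(m), length(genes), length(cells)),
           call. = FALSE)
    }
    dimnames(m) <- list(genes, cells)
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric values in ", path, call. = FALSE)
    if (orientation == "cells_by_genes") m <- t(m)
  }
  expression_matrix(m, unit = unit)
}

# Pre-scan a MatrixMarket file so an out-of-range coordinate is reported with
# its line number; Matrix::readMM remains the actual parser.
.validate_mtx_coords <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "%") & nzchar(trimws(lines)))
  if (length(body) < 1) stop("empty MatrixMarket file: ", path, call. = FALSE)
  dims <- scan(text = lines[body[1]], quiet = TRUE)
  if (length(dims) < 2) {
    stop("malformed MatrixMarket size line ", body[1], " in ", path,
         call. = FALSE)
  }
  for (ln in body[-1]) {
    v <- scan(text = lines[ln], quiet = TRUE)
    if (length(v) < 2 || v[1] < 1 || v[1] > dims[1] || v[2] < 1 || v[2] > dims[2]) {
      stop(sprintf("MatrixMarket entry out of declared %dx%d shape at line %d: '%s'",
                   dims[1], dims[2], ln, lines[ln]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write an expression matrix to disk
#'
#' @param x An [expression_matrix()].
#' @param path Output path (`.mtx` writes sparse plus `.genes.txt` /
#'   `.cells.txt` sidecars; `.csv`/`.tsv` writes dense with genes as rows).
#' @param format `"auto"`, `"mtx"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
    writeLines(rownames(x$values), paste0(stem, ".genes.txt"))
    writeLines(colnames(x$values), paste0(stem, ".cells.txt"))
  } else {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    df <- data.frame(symbol = rownames(x$values), x$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read cell annotations (and the taxonomy they imply)
#'
#' The annotation table carries, per cell, the region and the full taxonomy
#' path. The 4-level taxonomy is reconstructed from the unique paths (plus an
#' optional `nt_class` column) and both objects are validated together: a cell
#' whose path contradicts another's (same type under a different supertype,
#' say) is an error.
#'
#' @param path CSV/TSV with columns `cell_id`, `region`, `type_id`,
#'   `supertype_id`, `subclass_id`, `class_id` and optionally `nt_class`.
#' @return List with elements `taxonomy` and `annotation`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  tax_cols <- c("type_id", "supertype_id", "subclass_id", "class_id")
  if ("nt_class" %in% names(df)) tax_cols <- c(tax_cols, "nt_class")
  tax <- taxonomy(unique(df[, tax_cols]))
  ann <- cell_annotation(df[, c("cell_id", "region", "type_id",
                                "supertype_id", "subclass_id", "class_id")],
                         tax)
  list(taxonomy = tax, annotation = ann)
}

#' Write cell annotations (with taxonomy path and nt class) as CSV
#'
#' @param annotation A `cell_annotation`.
#' @param tax The matching `taxonomy` (supplies `nt_class`).
#' @param path Output CSV path.
#' @export
write_annotation <- function(annotation, tax, path) {
  df <- as.data.frame(annotation)
  df$nt_class <- tax$nt_class[match(df$type_id, tax$type_id)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a taxonomy table
#'
#' @param path CSV with one row per leaf type (columns as in [taxonomy()]).
#' @return A `taxonomy`.
#' @export
read_taxonomy <- function(path) {
  taxonomy(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_taxonomy
#' @param tax A `taxonomy` to write.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.csv(as.data.frame(tax), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a curated gene panel from CSV
#'
#' Expected columns: `symbol`, `category`, optionally `subcategory`,
#' `transduction`, `cognate_group` (empty fields become `NA`). Stands in for
#' the kind of curated panel tables distributed as supplementary worksheets.
#'
#' @param path CSV/TSV path.
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  gene_panel(df)
}

#' @rdname read_gene_panel
#' @param panel A `gene_panel` to write.
#' @export
write_gene_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
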