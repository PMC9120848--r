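#' Construct a gene-by-cell expression matrix
#'
#' The basic data container: a non-negative numeric matrix with genes as rows
#' and cells as columns, tagged with its unit (raw `counts` or `CPM`,
#' counts per million mapped reads). Gene symbols (rownames) and cell IDs
#' (colnames) must be present and unique.
#'
#' @param values Numeric matrix (genes x cells) with rownames and colnames;
#'   a `Matrix` sparse matrix is densified.
#' @param unit `"counts"` or `"CPM"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `unit`.
#' @export
#' @examples
#' m <- matrix(c(90, 10, 5, 5), nrow = 2,
#'             dimnames = list(c("Sst", "Npy"), c("c1", "c2")))
#' expression_matrix(m, unit = "counts")
expression_matrix <- function(values, unit = c("counts", "CPM")) {
  unit <- match.arg(unit)
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x cells)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene symbols as rownames and cell IDs as colnames",
         call. = FALSE)
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g) > 0) {
    stop("duplicate gene symbols: ", paste(utils::head(dup_g, 5), collapse = ", "),
         call. = FALSE)
  }
  dup_c <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_c) > 0) {
    stop("duplicate cell IDs: ", paste(utils::head(dup_c, 5), collapse = ", "),
         call. = FALSE)
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative values, e.g. gene '", rownames(values)[neg[1, 1]],
         "' cell '", colnames(values)[neg[1, 2]], "'", call. = FALSE)
  }
  structure(list(values = values, unit = unit), class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
dimnames.expression_matrix <- function(x) dimnames(x$values)

#' Subset an expression matrix
#'
#' Standard `[` subsetting by gene and/or cell; the unit tag is preserved and
#' dimensions are never dropped.
#'
#' @param x An `expression_matrix`.
#' @param i,j Gene / cell indices (integer, logical or character).
#' @param ... Ignored.
#' @export
`[.expression_matrix` <- function(x, i, j, ...) {
  v <- x$values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  expression_matrix(v[i, j, drop = FALSE], unit = x$unit)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Gene symbols of an expression matrix or signature matrix
#' @param x An `expression_matrix` or `signature_matrix`.
#' @return Character vector of gene symbols.
#' @export
gene_symbols <- function(x) {
  if (inherits(x, "signature_matrix")) rownames(x$means) else rownames(x$values)
}

#' Cell IDs of an expression matrix
#' @param x An `expression_matrix`.
#' @export
cell_ids <- function(x) colnames(x$values)
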