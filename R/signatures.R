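#' Filtering thresholds for the signature pipeline
#'
#' Defaults follow the CA1 curation rules: keep cells from region `"CA1"`,
#' keep leaf types represented by at least 16 such cells (inclusive at the
#' boundary), and call a gene expressed when its maximum type-mean CPM is
#' strictly greater than 10 (a level well above measurement noise).
#'
#' @param region Target region label.
#' @param min_cells_per_type Inclusive minimum cells per retained type.
#' @param expression_threshold CPM threshold; comparisons are strict (`>`).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(region = "CA1", min_cells_per_type = 16,
                        expression_threshold = 10) {
  if (min_cells_per_type < 1) stop("min_cells_per_type must be >= 1", call. = FALSE)
  if (expression_threshold < 0) {
    stop("expression_threshold must be non-negative", call. = FALSE)
  }
  structure(list(region = region,
                 min_cells_per_type = as.integer(min_cells_per_type),
                 expression_threshold = expression_threshold),
            class = "filter_spec")
}

#' Normalize counts to counts per million (CPM)
#'
#' Scales every cell (column) so its values sum to one million. The
#' denominator is the total over all genes present in the input matrix, so
#' any panel subsetting must happen after normalization, never before.
#' Idempotent: a matrix already tagged CPM is returned unchanged.
#'
#' @param x An [expression_matrix()]; unit `"counts"` (or `"CPM"`, passed
#'   through).
#' @return An [expression_matrix()] with unit `"CPM"`.
#' @export
to_cpm <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$unit == "CPM") return(x)
  totals <- colSums(x$values)
  zero <- colnames(x$values)[totals == 0]
  if (length(zero) > 0) {
    stop("cells with zero total counts: ",
         paste(utils::head(zero, 10), collapse = ", "), call. = FALSE)
  }
  expression_matrix(sweep(x$values, 2, totals / 1e6, "/"), unit = "CPM")
}

#' Select region cells and adequately sampled types
#'
#' Keeps cells sampled from the target region that belong to leaf types with
#' at least `min_cells_per_type` such cells, mirroring the curation that
#' restricts analysis to types with at least 16 CA1 cells. Retained types are
#' returned in taxonomy order.
#'
#' @param x An [expression_matrix()].
#' @param annotation A `cell_annotation` covering the cells of `x`.
#' @param tax The `taxonomy`.
#' @param spec A [filter_spec()].
#' @return List with `matrix`, `annotation` (both subset) and
#'   `retained_types` (character, taxonomy order).
#' @export
select_cells <- function(x, annotation, tax, spec = filter_spec()) {
  stopifnot(inherits(x, "expression_matrix"))
  idx <- match(colnames(x$values), annotation$cell_id)
  if (anyNA(idx)) {
    stop("annotation does not cover cells: ",
         paste(utils::head(colnames(x$values)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  ann <- annotation[idx, , drop = FALSE]
  in_region <- ann$region == spec$region
  counts <- table(ann$type_id[in_region])
  keep_types <- names(counts)[counts >= spec$min_cells_per_type]
  retained <- taxonomy_leaves(tax)[taxonomy_leaves(tax) %in% keep_types]
  if (length(retained) == 0) {
    stop("no type has >= ", spec$min_cells_per_type, " cells in region ",
         spec$region, call. = FALSE)
  }
  keep_cells <- in_region & ann$type_id %in% retained
  out_ann <- ann[keep_cells, , drop = FALSE]
  class(out_ann) <- class(annotation)
  list(matrix = x[, keep_cells], annotation = out_ann,
       retained_types = retained)
}

#' Type-mean expression signatures
#'
#' For every gene, the vector of untrimmed arithmetic mean CPM values across
#' the retained leaf types -- the gene's "type-mean expression signature".
#' No outlier trimming is applied at any point.
#'
#' @param x An [expression_matrix()] in CPM.
#' @param annotation A `cell_annotation` for the cells of `x`.
#' @param retained_types Character vector of leaf types (defines the column
#'   order); every listed type must have at least one cell.
#' @return A `signature_matrix`: list with `means` (gene x type matrix) and
#'   `cells_per_type` (named integer).
#' @export
type_means <- function(x, annotation, retained_types) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$unit != "CPM") {
    stop("type_means expects CPM input; call to_cpm() first", call. = FALSE)
  }
  idx <- match(colnames(x$values), annotation$cell_id)
  if (anyNA(idx)) stop("annotation does not cover all cells", call. = FALSE)
  fac <- factor(annotation$type_id[idx], levels = retained_types)
  if (anyNA(fac)) {
    stop("cells belong to types outside retained_types; run select_cells()",
         call. = FALSE)
  }
  n_per <- table(fac)
  empty <- names(n_per)[n_per == 0]
  if (length(empty) > 0) {
    stop("retained types with zero cells: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  # per-type mean via mean() per gene so results are bit-identical to a
  # naive group-by (mean() refines its long-double sum; rowsum does not)
  means <- vapply(retained_types, function(ty) {
    apply(x$values[, fac == ty, drop = FALSE], 1, mean)
  }, numeric(nrow(x$values)))
  if (nrow(x$values) == 1) {
    means <- matrix(means, nrow = 1,
                    dimnames = list(rownames(x$values), retained_types))
  }
  dimnames(means) <- list(rownames(x$values), retained_types)
  structure(list(means = means,
                 cells_per_type = stats::setNames(as.integer(n_per),
                                                  names(n_per))),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d genes x %d types (%d cells)\n",
              nrow(x$means), ncol(x$means), sum(x$cells_per_type)))
  invisible(x)
}

#' The delta type-specificity statistic
#'
#' For a gene with type means `mu_1..mu_n` and maximum `mu_max`,
#' `delta = (n - sum(mu_i / mu_max)) / (n - 1)`. Delta is 0 when all type
#' means are equal (no type specificity) and 1 when all but one mean are zero
#' (maximal specificity); it is invariant to positive rescaling and to
#' permutation of the types, and is mathematically the tissue-specificity
#' index tau. When `mu_max = 0` (gene undetected everywhere) delta is
#' undefined and `NA` is returned rather than 0.
#'
#' @param mu Numeric vector of non-negative type means, length >= 2.
#' @return Delta in `[0, 1]`, or `NA` if `max(mu) == 0`.
#' @export
#' @examples
#' delta(rep(5, 5))        # 0: uniform
#' delta(c(0, 0, 7, 0))    # 1: one-hot
#' delta(c(10, 5, 0, 0))   # 2.5/3
delta <- function(mu) {
  n <- length(mu)
  if (n < 2) stop("delta needs at least 2 type means", call. = FALSE)
  if (any(mu < 0)) stop("type means must be non-negative", call. = FALSE)
  m <- max(mu)
  if (m == 0) return(NA_real_)
  (n - sum(mu / m)) / (n - 1)
}

#' Per-gene delta table for a signature matrix
#'
#' Computes, per gene, delta, the maximum type mean `mu_max` and its log10
#' (the "log(rowmax)" side annotation of the matrix displays). Genes with
#' `mu_max = 0` carry `NA` delta and `NA` log10.
#'
#' @param signature A `signature_matrix`.
#' @param panel Optional [gene_panel()]; adds a `category` column where
#'   symbols match.
#' @return Data frame (`delta_table`) with columns `symbol`, `delta`,
#'   `mu_max`, `log10_rowmax` and optionally `category`.
#' @export
delta_table <- function(signature, panel = NULL) {
  m <- signature$means
  n <- ncol(m)
  if (n < 2) stop("need at least 2 types to compute delta", call. = FALSE)
  mu_max <- apply(m, 1, max)
  d <- ifelse(mu_max > 0, (n - rowSums(m) / mu_max) / (n - 1), NA_real_)
  out <- data.frame(symbol = rownames(m), delta = unname(d),
                    mu_max = unname(mu_max),
                    log10_rowmax = ifelse(mu_max > 0, log10(mu_max), NA_real_),
                    stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    out$category <- panel$category[match(out$symbol, panel$symbol)]
  }
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Filter genes by peak type-mean expression
#'
#' Keeps genes whose maximum type-mean CPM is strictly greater than the
#' expression threshold, optionally restricted to a curated panel. Panel
#' symbols absent from the signature matrix are reported (not fatal). The
#' filtering cascade (candidates -> detected -> retained) is recorded.
#'
#' @param signature A `signature_matrix`.
#' @param panel Optional [gene_panel()] restricting the candidates.
#' @param spec A [filter_spec()]; only `expression_threshold` is used.
#' @return List with `signature` (retained genes), `delta_table` (retained
#'   genes, input order), `cascade` (named counts) and `missing_symbols`.
#' @export
filter_genes <- function(signature, panel = NULL, spec = filter_spec()) {
  all_genes <- rownames(signature$means)
  if (is.null(panel)) {
    candidates <- all_genes
    missing <- character(0)
  } else {
    candidates <- panel$symbol
    missing <- setdiff(candidates, all_genes)
    if (length(missing) > 0) {
      message(length(missing), " panel symbol(s) not in signature matrix: ",
              paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  detected <- intersect(candidates, all_genes)
  sub <- signature$means[detected, , drop = FALSE]
  keep <- apply(sub, 1, max) > spec$expression_threshold
  retained <- detected[keep]
  if (length(retained) == 0) {
    warning("no gene exceeds ", spec$expression_threshold, " CPM in any type")
  }
  out_sig <- structure(list(means = signature$means[retained, , drop = FALSE],
                            cells_per_type = signature$cells_per_type),
                       class = "signature_matrix")
  list(signature = out_sig,
       delta_table = delta_table(out_sig, panel = panel),
       cascade = c(candidates = length(candidates),
                   detected = length(detected),
                   retained = length(retained)),
       missing_symbols = missing)
}

#' Delta-descending display order
#'
#' The row order used in all matrix displays: descending delta, ties broken
#' by descending `mu_max`, then lexicographic symbol. Genes with undefined
#' delta (`mu_max = 0`) are excluded from the ordering.
#'
#' @param table A `delta_table`.
#' @return Integer permutation (row indices of `table`, defined-delta rows
#'   only, in display order).
#' @export
order_by_delta <- function(table) {
  idx <- which(!is.na(table$delta))
  idx[order(-table$delta[idx], -table$mu_max[idx], table$symbol[idx])]
}

#' Write a signature matrix (and its per-type cell counts) as CSV
#'
#' @param signature A `signature_matrix`.
#' @param path Output CSV (gene x type means); cell counts go to
#'   `<stem>.types.csv`.
#' @export
write_signature <- function(signature, path) {
  df <- data.frame(symbol = rownames(signature$means), signature$means,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  types <- data.frame(type_id = names(signature$cells_per_type),
                      n_cells = as.integer(signature$cells_per_type))
  utils::write.csv(types, paste0(sub("\\.csv$", "", path), ".types.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  types <- utils::read.csv(paste0(sub("\\.csv$", "", path), ".types.csv"),
                           stringsAsFactors = FALSE)
  structure(list(means = m,
                 cells_per_type = stats::setNames(as.integer(types$n_cells),
                                                  types$type_id)),
            class = "signature_matrix")
}
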