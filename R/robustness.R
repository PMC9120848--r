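#' Within-type single-cell CPM distributions for one gene
#'
#' Returns the raw per-cell CPM vectors for a gene within selected leaf
#' types, plus log2 histogram breaks for display. When `types` is omitted and
#' a signature matrix is supplied, the display convention is applied: the
#' type with the highest mean and a mid-range type whose mean is nearest 25%
#' of that maximum.
#'
#' @param x CPM [expression_matrix()].
#' @param annotation `cell_annotation` for the cells of `x`.
#' @param gene Gene symbol.
#' @param types Character vector of leaf types; or `NULL` to auto-select.
#' @param signature `signature_matrix` (required for auto-selection).
#' @param mid_fraction Mid-range target as a fraction of the peak mean.
#' @return Named list of numeric vectors (one per type, cells as names) with
#'   attribute `log2_breaks`.
#' @export
within_type_histograms <- function(x, annotation, gene, types = NULL,
                                   signature = NULL, mid_fraction = 0.25) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!gene %in% rownames(x$values)) {
    stop("gene not in matrix: ", gene, call. = FALSE)
  }
  if (is.null(types)) {
    if (is.null(signature)) {
      stop("supply `types` or a `signature` for max/mid auto-selection",
           call. = FALSE)
    }
    types <- select_display_types(signature, gene, mid_fraction)
  }
  idx <- match(colnames(x$values), annotation$cell_id)
  vals <- lapply(types, function(ty) {
    keep <- annotation$type_id[idx] == ty
    if (!any(keep)) stop("type has no cells: ", ty, call. = FALSE)
    stats::setNames(x$values[gene, keep], colnames(x$values)[keep])
  })
  names(vals) <- types
  top <- max(1, unlist(vals))
  attr(vals, "log2_breaks") <- c(-Inf, seq(0, ceiling(log2(top + 1)), by = 0.5))
  vals
}

#' Max-mean and mid-range display types for a gene
#'
#' @param signature A `signature_matrix`.
#' @param gene Gene symbol.
#' @param mid_fraction Fraction of the peak mean targeted by the mid-range
#'   pick (default 0.25).
#' @return Character vector `c(max_type, mid_type)`.
#' @export
select_display_types <- function(signature, gene, mid_fraction = 0.25) {
  mu <- signature$means[gene, ]
  max_ty <- names(mu)[which.max(mu)]
  target <- mid_fraction * max(mu)
  rest <- mu[names(mu) != max_ty]
  mid_ty <- names(rest)[which.min(abs(rest - target))]
  c(max_ty, mid_ty)
}

#' Flag within-type expression anomalies and outliers
#'
#' Operational versions of by-eye anomaly calls on within-type CPM
#' histograms: a cell is a high-CPM outlier when its `log2(CPM + 1)` exceeds
#' `Q3 + iqr_mult * IQR` of the subset (quartiles by linear interpolation,
#' `stats::quantile` type 7); the subset shows a low-end zero anomaly when
#' its zero fraction exceeds `zero_fraction_max` while the median of the
#' nonzero values still exceeds the expression threshold (i.e. the type
#' clearly expresses the gene, yet many cells report zero).
#'
#' @param values Per-cell CPM values within one gene x type subset (names =
#'   cell IDs, optional).
#' @param min_cells Minimum subset size (default 16).
#' @param iqr_mult IQR multiplier for the high fence (default 3).
#' @param zero_fraction_max Zero-fraction trigger for the low anomaly
#'   (default 0.25).
#' @param expression_threshold CPM level the nonzero median must exceed
#'   (default 10).
#' @return List: `n_cells`, `zero_fraction`, `low_anomaly`,
#'   `high_outlier_cells` (character; indices if unnamed), `fence`
#'   (log2 scale).
#' @export
flag_outliers <- function(values, min_cells = 16, iqr_mult = 3,
                          zero_fraction_max = 0.25,
                          expression_threshold = 10) {
  n <- length(values)
  if (n < min_cells) {
    stop("subset has ", n, " cells; minimum is ", min_cells, call. = FALSE)
  }
  lg <- log2(values + 1)
  q <- stats::quantile(lg, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2] + iqr_mult * (q[2] - q[1])
  hi <- which(lg > fence)
  ids <- if (!is.null(names(values))) names(values)[hi] else as.character(hi)
  zf <- mean(values == 0)
  nz_med <- if (any(values > 0)) stats::median(values[values > 0]) else 0
  list(n_cells = n, zero_fraction = zf,
       low_anomaly = zf > zero_fraction_max && nz_med > expression_threshold,
       high_outlier_cells = ids, fence = unname(fence))
}

#' Distribution diagnostics across genes and types
#'
#' Applies [flag_outliers()] to every requested gene x type subset with at
#' least `min_cells` cells and tabulates the results.
#'
#' @param x CPM [expression_matrix()].
#' @param annotation `cell_annotation`.
#' @param genes Gene symbols (default: all genes in `x`).
#' @param types Leaf types (default: all types present in `annotation`).
#' @inheritParams flag_outliers
#' @return Data frame with one row per computed (gene, type) pair.
#' @export
distribution_diagnostics <- function(x, annotation, genes = NULL,
                                     types = NULL, min_cells = 16,
                                     iqr_mult = 3, zero_fraction_max = 0.25,
                                     expression_threshold = 10) {
  if (is.null(genes)) genes <- rownames(x$values)
  if (is.null(types)) types <- unique(annotation$type_id)
  idx <- match(colnames(x$values), annotation$cell_id)
  type_of <- annotation$type_id[idx]
  rows <- list()
  for (ty in types) {
    cells <- which(type_of == ty)
    if (length(cells) < min_cells) next
    for (g in intersect(genes, rownames(x$values))) {
      fl <- flag_outliers(x$values[g, cells], min_cells = min_cells,
                          iqr_mult = iqr_mult,
                          zero_fraction_max = zero_fraction_max,
                          expression_threshold = expression_threshold)
      rows[[length(rows) + 1]] <- data.frame(
        symbol = g, type_id = ty, n_cells = fl$n_cells,
        zero_fraction = fl$zero_fraction, low_anomaly = fl$low_anomaly,
        n_high_outliers = length(fl$high_outlier_cells),
        high_outlier_cells = paste(fl$high_outlier_cells, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    stop("no gene x type subset reaches ", min_cells, " cells", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Subsampling stability of type-mean signatures
#'
#' Measures how reproducible each gene's type-mean signature is under
#' half-splitting: in every replicate the cells of each type are split into
#' two disjoint random halves, signatures are recomputed on each half, and
#' the per-gene Pearson correlation across types between the two halves is
#' recorded. Genes with zero variance in either half of a replicate get `NA`
#' for that replicate (reported, not dropped silently).
#'
#' @param x CPM [expression_matrix()].
#' @param annotation `cell_annotation`; types with fewer than 2 cells are
#'   excluded with a warning.
#' @param genes Gene symbols to assess (default: all).
#' @param n_reps Number of half-split replicates (default 50).
#' @param seed RNG seed.
#' @return A `stability_report`: list with `per_gene` (data frame: `symbol`,
#'   `median_cor`, `iqr`, `n_defined`), `replicates` (gene x rep matrix),
#'   `n_reps`, `seed`, `types`.
#' @export
subsample_stability <- function(x, annotation, genes = NULL, n_reps = 50,
                                seed = 1L) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$unit != "CPM") stop("subsample_stability expects CPM", call. = FALSE)
  if (is.null(genes)) genes <- rownames(x$values)
  genes <- intersect(genes, rownames(x$values))
  idx <- match(colnames(x$values), annotation$cell_id)
  type_of <- annotation$type_id[idx]
  counts <- table(type_of)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("types with < 2 cells excluded: ", paste(small, collapse = ", "))
  }
  types <- names(counts)[counts >= 2]
  if (length(types) < 2) stop("need >= 2 usable types", call. = FALSE)
  v <- x$values[genes, , drop = FALSE]

  set.seed(seed)
  reps <- matrix(NA_real_, nrow = length(genes), ncol = n_reps,
                 dimnames = list(genes, NULL))
  for (r in seq_len(n_reps)) {
    a_cells <- integer(0)
    b_cells <- integer(0)
    for (ty in types) {
      cells <- which(type_of == ty)
      half <- length(cells) %/% 2
      perm <- sample(cells)
      a_cells <- c(a_cells, perm[seq_len(half)])
      b_cells <- c(b_cells, perm[half + seq_len(half)])
    }
    fa <- factor(type_of[a_cells], levels = types)
    fb <- factor(type_of[b_cells], levels = types)
    ma <- sweep(t(rowsum(t(v[, a_cells, drop = FALSE]), fa)), 2,
                as.vector(table(fa)), "/")
    mb <- sweep(t(rowsum(t(v[, b_cells, drop = FALSE]), fb)), 2,
                as.vector(table(fb)), "/")
    ca <- ma - rowMeans(ma)
    cb <- mb - rowMeans(mb)
    den <- sqrt(rowSums(ca^2) * rowSums(cb^2))
    r_g <- rowSums(ca * cb) / den
    r_g[den == 0] <- NA_real_
    reps[, r] <- r_g
  }
  per_gene <- data.frame(
    symbol = genes,
    median_cor = apply(reps, 1, stats::median, na.rm = TRUE),
    iqr = apply(reps, 1, stats::IQR, na.rm = TRUE),
    n_defined = rowSums(!is.na(reps)),
    stringsAsFactors = FALSE)
  per_gene$median_cor[per_gene$n_defined == 0] <- NA_real_
  per_gene$iqr[per_gene$n_defined == 0] <- NA_real_
  structure(list(per_gene = per_gene, replicates = reps, n_reps = n_reps,
                 seed = seed, types = types),
            class = "stability_report")
}

#' Summarize a stability report by gene category
#'
#' @param report A `stability_report`.
#' @param panel A [gene_panel()] mapping symbols to categories.
#' @return Data frame: `category`, `n_genes`, `median_cor`.
#' @export
stability_by_category <- function(report, panel) {
  pg <- report$per_gene
  pg$category <- panel$category[match(pg$symbol, panel$symbol)]
  pg <- pg[!is.na(pg$category) & !is.na(pg$median_cor), , drop = FALSE]
  agg <- stats::aggregate(median_cor ~ category, pg, stats::median)
  n <- stats::aggregate(symbol ~ category, pg, length)
  data.frame(category = agg$category, n_genes = n$symbol,
             median_cor = agg$median_cor, stringsAsFactors = FALSE)
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d genes, %d half-split replicates over %d types; median r = %.3f\n",
              nrow(x$per_gene), x$n_reps, length(x$types),
              stats::median(x$per_gene$median_cor, na.rm = TRUE)))
  invisible(x)
}
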