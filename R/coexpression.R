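#' Per-cell co-expression counts
#'
#' For each cell, the number of distinct panel genes expressed strictly above
#' the CPM threshold in that cell. Panel symbols absent from the matrix
#' contribute nothing (they are reported via a message).
#'
#' @param x An [expression_matrix()] in CPM.
#' @param panel A [gene_panel()].
#' @param threshold CPM threshold (strict `>`), default 10.
#' @return Named integer vector, one count per cell.
#' @export
coexpression_counts <- function(x, panel, threshold = 10) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$unit != "CPM") stop("coexpression_counts expects CPM", call. = FALSE)
  if (nrow(panel) == 0) stop("empty gene panel", call. = FALSE)
  present <- intersect(panel$symbol, rownames(x$values))
  if (length(present) < nrow(panel)) {
    message(nrow(panel) - length(present),
            " panel symbol(s) not in matrix; ignored")
  }
  if (length(present) == 0) {
    return(stats::setNames(integer(ncol(x$values)), colnames(x$values)))
  }
  colSums(x$values[present, , drop = FALSE] > threshold)
}

#' Co-expression histograms and modes by neuron class
#'
#' Bins per-cell co-expression counts into unit-width integer bins for all
#' cells together and for each neurotransmitter class (GABAergic /
#' glutamatergic) separately. The modal value is the smallest count attaining
#' the maximal frequency.
#'
#' @param counts Named integer vector from [coexpression_counts()].
#' @param classes Factor (or character) giving each cell's class, aligned
#'   with `counts`.
#' @return A `coexpression_result`: list of groups (`all` plus one per class
#'   level), each with `n_cells`, `histogram` (named counts over the
#'   0..max range) and `mode`.
#' @export
count_histogram <- function(counts, classes = NULL) {
  groups <- list(all = seq_along(counts))
  if (!is.null(classes)) {
    if (length(classes) != length(counts)) {
      stop("`classes` must align with `counts`", call. = FALSE)
    }
    classes <- as.factor(classes)
    for (lv in levels(classes)) groups[[lv]] <- which(classes == lv)
  }
  top <- if (length(counts) > 0) max(counts) else 0L
  out <- lapply(groups, function(ix) {
    h <- tabulate(counts[ix] + 1L, nbins = top + 1L)
    names(h) <- 0:top
    mode <- if (length(ix) > 0) as.integer(names(h)[which.max(h)]) else NA_integer_
    list(n_cells = length(ix), histogram = h, mode = mode)
  })
  structure(out, class = "coexpression_result", threshold_counts = counts)
}

#' @export
print.coexpression_result <- function(x, ...) {
  for (g in names(x)) {
    cat(sprintf("%-14s n=%5d  mode=%s\n", g, x[[g]]$n_cells,
                ifelse(is.na(x[[g]]$mode), "NA", x[[g]]$mode)))
  }
  invisible(x)
}

#' Co-expression summary for a set of panels
#'
#' Convenience wrapper: computes counts and class-split histograms for each
#' named panel (and optional merged panels), as in the per-category and
#' pooled co-expression displays.
#'
#' @param x CPM [expression_matrix()].
#' @param panels Named list of [gene_panel()]s.
#' @param annotation,tax Cell annotation and taxonomy (for the class split).
#' @param threshold CPM threshold (strict).
#' @return Named list of `coexpression_result`, one per panel.
#' @export
coexpression_summary <- function(x, panels, annotation, tax, threshold = 10) {
  classes <- cell_classes(annotation[match(colnames(x$values),
                                           annotation$cell_id), ], tax)
  lapply(panels, function(p) {
    count_histogram(coexpression_counts(x, p, threshold), classes)
  })
}

#' Flatten a coexpression result to a data frame
#'
#' @param result A `coexpression_result`.
#' @return Data frame with columns `group`, `count`, `n_cells_at_count`.
#' @export
coexpression_as_df <- function(result) {
  do.call(rbind, lapply(names(result), function(g) {
    h <- result[[g]]$histogram
    data.frame(group = g, count = as.integer(names(h)),
               n_cells_at_count = as.integer(h), stringsAsFactors = FALSE)
  }))
}
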