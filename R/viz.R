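#' Row-normalize a signature matrix for display
#'
#' Divides each gene's row by its maximum type mean, so every expressed
#' gene's row peaks at exactly 1. All-zero rows are returned as zeros and
#' flagged via the `all_zero` attribute. Rescaling the input by any positive
#' constant leaves the output unchanged.
#'
#' @param signature A `signature_matrix` or a bare gene x type matrix.
#' @return Numeric matrix with attribute `all_zero` (logical per row).
#' @export
row_normalize <- function(signature) {
  m <- if (inherits(signature, "signature_matrix")) signature$means else signature
  mx <- apply(m, 1, max)
  zero <- mx == 0
  out <- m / ifelse(zero, 1, mx)
  attr(out, "all_zero") <- zero
  out
}

.open_device <- function(file, width, height) {
  if (grepl("\\.svg$", file)) {
    grDevices::svg(file, width = width, height = height)
  } else if (grepl("\\.pdf$", file)) {
    grDevices::pdf(file, width = width, height = height)
  } else if (grepl("\\.png$", file)) {
    grDevices::png(file, width = width * 96, height = height * 96, res = 96)
  } else stop("unsupported figure format: ", file, call. = FALSE)
}

.delta_palette <- function(n = 100) {
  grDevices::hcl.colors(n, "Blue-Red", rev = TRUE)  # blue low, red high
}
.cpm_palette <- function(n = 100) {
  grDevices::hcl.colors(n, "YlOrRd", rev = TRUE)
}

#' Render a neurotaxonomic signature heatmap
#'
#' The standard matrix display: rows are genes in delta-descending order,
#' columns are leaf types in taxonomy order, cells show row-normalized
#' type-mean CPM. The header is a 4-level taxonomy color mosaic; a magenta
#' vertical line marks the GABAergic / glutamatergic boundary; per-row side
#' swatches encode log10 of the row maximum and delta. Rendering is
#' deterministic, so re-rendering identical inputs yields byte-identical
#' vector output.
#'
#' @param signature A `signature_matrix`.
#' @param table Matching `delta_table` (defines delta and ordering).
#' @param tax The `taxonomy` (column order and mosaic colors).
#' @param file Output path (`.svg`, `.pdf` or `.png`).
#' @param show_labels Draw per-row gene symbols (suppress for large sets).
#' @param width,height Device size in inches.
#' @return `file`, invisibly.
#' @export
render_signature_figure <- function(signature, table, tax, file,
                                    show_labels = TRUE, width = 8,
                                    height = NULL) {
  types <- intersect(taxonomy_leaves(tax), colnames(signature$means))
  if (length(types) == 0) stop("no taxonomy types in signature", call. = FALSE)
  ord <- order_by_delta(table)
  syms <- table$symbol[ord]
  syms <- syms[syms %in% rownames(signature$means)]
  if (length(syms) == 0) stop("no genes to display", call. = FALSE)
  m <- row_normalize(signature$means[syms, types, drop = FALSE])
  d <- table$delta[match(syms, table$symbol)]
  lr <- log10(pmax(table$mu_max[match(syms, table$symbol)], 1e-12))

  if (is.null(height)) height <- max(3, 1.2 + 0.12 * length(syms))
  .open_device(file, width, height)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(c(4, 5, 5, 1, 2, 3), nrow = 2, byrow = TRUE),
                   widths = c(8, 0.6, 0.6), heights = c(0.8, 8))
  old <- graphics::par(mar = c(1.5, 6, 0.2, 0.2))
  on.exit(graphics::par(old), add = TRUE)

  nt <- tax$nt_class[match(types, tax$type_id)]
  boundary <- which(diff(nt == "GABAergic") != 0)

  # 1: main matrix (row 1 at top)
  graphics::image(x = seq_along(types), y = seq_along(syms),
                  z = t(m[rev(seq_along(syms)), , drop = FALSE]),
                  col = .cpm_palette(), zlim = c(0, 1), axes = FALSE,
                  xlab = "", ylab = "")
  if (length(boundary) > 0) {
    graphics::abline(v = boundary + 0.5, col = "magenta", lwd = 2)
  }
  if (show_labels) {
    graphics::axis(2, at = rev(seq_along(syms)), labels = syms, las = 2,
                   cex.axis = 0.55, tick = FALSE)
    graphics::axis(1, at = seq_along(types), labels = types, las = 2,
                   cex.axis = 0.5, tick = FALSE)
  }
  graphics::box()

  # 2: log10(rowmax) swatch
  graphics::par(mar = c(1.5, 0.1, 0.2, 0.1))
  rng <- range(lr)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  graphics::image(x = 1, y = seq_along(syms),
                  z = matrix(rev(lr), nrow = 1), zlim = rng,
                  col = grDevices::hcl.colors(100, "Viridis"), axes = FALSE,
                  xlab = "", ylab = "")
  graphics::mtext("log(rowmax)", side = 1, cex = 0.45, line = 0.3)
  graphics::box()

  # 3: delta swatch
  graphics::image(x = 1, y = seq_along(syms),
                  z = matrix(rev(d), nrow = 1), zlim = c(0, 1),
                  col = .delta_palette(), axes = FALSE, xlab = "", ylab = "")
  graphics::mtext("delta", side = 1, cex = 0.45, line = 0.3)
  graphics::box()

  # 4: taxonomy mosaic (class / subclass / supertype / type bands)
  graphics::par(mar = c(0.1, 6, 0.3, 0.2))
  graphics::plot(NULL, xlim = c(0.5, length(types) + 0.5), ylim = c(0, 4),
                 axes = FALSE, xlab = "", ylab = "", xaxs = "i", yaxs = "i")
  bands <- c("class_color", "subclass_color", "supertype_color", "type_color")
  ti <- match(types, tax$type_id)
  for (b in seq_along(bands)) {
    graphics::rect(seq_along(types) - 0.5, 4 - b, seq_along(types) + 0.5,
                   5 - b, col = tax[[bands[b]]][ti], border = NA)
  }
  if (length(boundary) > 0) {
    graphics::abline(v = boundary + 0.5, col = "magenta", lwd = 2)
  }
  graphics::box()

  # 5: spacer
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  invisible(file)
}

#' Render co-expression histograms with annotated modes
#'
#' One panel per grouping of a `coexpression_result` (all cells, then each
#' neuron class); bars are unit-width integer bins, the modal count is
#' printed inside each panel. GABAergic cells are drawn red and
#' glutamatergic blue by convention; empty groupings get an explicit
#' "no cells" panel.
#'
#' @param result A `coexpression_result` (or named list of them; panel per
#'   entry per grouping).
#' @param file Output path (`.svg`, `.pdf`, `.png`).
#' @param colors Named fill colors per grouping.
#' @param width,height Device size in inches.
#' @return `file`, invisibly.
#' @export
render_coexpression_figure <- function(result, file,
                                       colors = c(all = "grey40",
                                                  GABAergic = "red3",
                                                  glutamatergic = "blue3"),
                                       width = 8, height = NULL) {
  results <- if (inherits(result, "coexpression_result")) {
    list(panel = result)
  } else result
  n_row <- length(results)
  n_col <- max(vapply(results, length, integer(1)))
  if (is.null(height)) height <- 2.2 * n_row
  .open_device(file, width, height)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(n_row, n_col), mar = c(2.5, 2.5, 1.5, 0.5),
                       mgp = c(1.4, 0.4, 0))
  on.exit(graphics::par(old), add = TRUE)
  for (nm in names(results)) {
    res <- results[[nm]]
    for (g in names(res)) {
      h <- res[[g]]$histogram
      col <- if (g %in% names(colors)) colors[[g]] else "grey40"
      if (res[[g]]$n_cells == 0) {
        graphics::plot.new()
        graphics::title(main = paste(nm, g, sep = " / "), cex.main = 0.7)
        graphics::text(0.5, 0.5, "no cells", cex = 0.9)
        next
      }
      graphics::barplot(h, space = 0, border = NA, col = col,
                        main = paste(nm, g, sep = " / "), cex.main = 0.7,
                        xlab = "genes > threshold", ylab = "cells",
                        cex.axis = 0.6, cex.names = 0.5, cex.lab = 0.6)
      graphics::legend("topright", bty = "n", cex = 0.8,
                       legend = paste0("mode = ", res[[g]]$mode))
    }
    # pad short rows so the grid stays aligned
    for (k in seq_len(n_col - length(res))) graphics::plot.new()
  }
  invisible(file)
}

#' Render within-type CPM histograms for one gene
#'
#' Max-mean type on top, mid-range type below, log2-scaled bins; high-CPM
#' outlier cells (per [flag_outliers()]) are marked with a star, and a
#' darkened zero bar indicates a low-end zero anomaly.
#'
#' @param values Output of [within_type_histograms()].
#' @param gene Gene symbol (panel titles).
#' @param file Output path.
#' @param min_cells Passed to [flag_outliers()]; panels with fewer cells are
#'   drawn without flags.
#' @param width,height Device size in inches.
#' @return `file`, invisibly.
#' @export
render_within_type_figure <- function(values, gene, file, min_cells = 16,
                                      width = 4, height = NULL) {
  if (is.null(height)) height <- 1.8 * length(values)
  .open_device(file, width, height)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(length(values), 1),
                       mar = c(2.5, 2.5, 1.5, 0.5), mgp = c(1.4, 0.4, 0))
  on.exit(graphics::par(old), add = TRUE)
  for (ty in names(values)) {
    v <- values[[ty]]
    lg <- log2(v + 1)
    br <- seq(0, max(1, ceiling(max(lg))), by = 0.5)
    fl <- if (length(v) >= min_cells) flag_outliers(v, min_cells = min_cells)
          else NULL
    h <- graphics::hist(lg, breaks = br, plot = FALSE)
    cols <- rep("grey60", length(h$counts))
    if (!is.null(fl) && fl$low_anomaly) cols[1] <- "grey20"
    graphics::plot(h, col = cols, border = "white",
                   main = sprintf("%s / %s (n=%d)", gene, ty, length(v)),
                   cex.main = 0.7, xlab = "log2(CPM + 1)", ylab = "cells",
                   cex.axis = 0.6, cex.lab = 0.6)
    if (!is.null(fl) && length(fl$high_outlier_cells) > 0) {
      out_lg <- lg[fl$high_outlier_cells]
      graphics::points(out_lg, rep(max(h$counts) * 0.9, length(out_lg)),
                       pch = 8, col = "red3")
    }
  }
  invisible(file)
}
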