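#' Curated gene panels
#'
#' A gene panel is a curated list of genes with a functional category
#' (GPCR subfamilies, channel subfamilies, neuropeptide precursors, G-protein
#' subunits), a free-text subcategory, an optional G-protein transduction
#' preference for receptors, and an optional cognate-group key that links
#' neuropeptide precursor (NPP) genes to their neuropeptide-selective GPCR
#' (NP-GPCR) receptor genes (e.g. Sst and Sstr2 share group `"SST"`).
#'
#' @name gene_panel
NULL

#' Recognized panel categories
#' @export
PANEL_CATEGORIES <- c("monoamine_GPCR", "small_molecule_GPCR", "NP_GPCR",
                      "NPP", "G_protein", "Na_channel", "Ca_channel",
                      "K_channel", "ligand_gated_channel", "other")

#' Categories allowed to carry cognate-group keys
#' @noRd
.cognate_categories <- c("NPP", "NP_GPCR")

#' Construct a validated gene panel
#'
#' @param df Data frame with columns `symbol`, `category`, and optionally
#'   `subcategory`, `transduction` (one of `Gi/o`, `Gs`, `Gq/11` or `NA`) and
#'   `cognate_group` (only for `NPP` / `NP_GPCR` rows; `;`-separated keys
#'   allowed for promiscuous ligands).
#' @return A `gene_panel` data frame.
#' @export
gene_panel <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("symbol", "category") %in% names(df))) {
    stop("gene panel needs `symbol` and `category` columns", call. = FALSE)
  }
  for (col in c("subcategory", "transduction", "cognate_group")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
    df[[col]][!is.na(df[[col]]) & !nzchar(trimws(df[[col]]))] <- NA_character_
  }
  dup <- unique(df$symbol[duplicated(df$symbol)])
  if (length(dup) > 0) {
    stop("duplicate symbols in panel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(df$category), PANEL_CATEGORIES)
  if (length(bad_cat) > 0) {
    stop("unknown panel categories: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  bad_td <- !is.na(df$transduction) & !df$transduction %in% c("Gi/o", "Gs", "Gq/11")
  if (any(bad_td)) {
    stop("unknown transduction preference: ",
         paste(unique(df$transduction[bad_td]), collapse = ", "), call. = FALSE)
  }
  bad_cg <- !is.na(df$cognate_group) & !df$category %in% .cognate_categories
  if (any(bad_cg)) {
    stop("cognate_group only allowed for NPP / NP_GPCR rows; offending: ",
         paste(df$symbol[bad_cg], collapse = ", "), call. = FALSE)
  }
  df <- df[, c("symbol", "category", "subcategory", "transduction",
               "cognate_group")]
  class(df) <- c("gene_panel", "data.frame")
  df
}

#' Merge gene panels into one
#'
#' Union of the panels' symbols; a symbol present in several panels must carry
#' the same category everywhere (its first-seen row is kept), otherwise the
#' merge fails. Used e.g. to aggregate the three GPCR panels (84 genes) or the
#' four ion-channel panels (133 genes) for pooled co-expression tallies.
#'
#' @param ... `gene_panel` objects, or a single list of them.
#' @return A merged `gene_panel`.
#' @export
merge_panels <- function(...) {
  panels <- list(...)
  if (length(panels) == 1 && is.list(panels[[1]]) &&
      !inherits(panels[[1]], "data.frame")) {
    panels <- panels[[1]]
  }
  if (length(panels) == 0) stop("no panels to merge", call. = FALSE)
  all_rows <- do.call(rbind, lapply(panels, as.data.frame))
  cat_by_sym <- tapply(all_rows$category, all_rows$symbol,
                       function(v) length(unique(v)))
  conflict <- names(cat_by_sym)[cat_by_sym > 1]
  if (length(conflict) > 0) {
    stop("conflicting categories for symbols: ",
         paste(conflict, collapse = ", "), call. = FALSE)
  }
  gene_panel(all_rows[!duplicated(all_rows$symbol), ])
}

#' Subset a panel by category
#' @param panel A `gene_panel`.
#' @param categories Character vector of categories to keep.
#' @export
panel_subset <- function(panel, categories) {
  bad <- setdiff(categories, PANEL_CATEGORIES)
  if (length(bad) > 0) {
    stop("unknown categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- panel[panel$category %in% categories, , drop = FALSE]
  class(out) <- c("gene_panel", "data.frame")
  out
}
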