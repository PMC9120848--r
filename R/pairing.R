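#' Cognate neuropeptide / receptor pairing
#'
#' Tests, area-wide, whether every expressed neuropeptide precursor (NPP)
#' gene is matched by at least one expressed cognate neuropeptide-selective
#' GPCR (NP-GPCR) gene. "Expressed" means passing the peak type-mean filter
#' (`mu_max` strictly above the threshold). Cognate links come from the
#' panel's `cognate_group` keys: an NPP is paired when some NP-GPCR sharing
#' one of its groups is expressed. NPPs without a cognate-group key are
#' reported as unresolvable and excluded from the denominator.
#'
#' With `type_resolved = TRUE` (and signature matrices supplied) a stricter
#' definition is used: the NPP and some cognate receptor must each exceed the
#' threshold in at least one common leaf type. The area-level definition is
#' the headline statistic.
#'
#' @param npp_table `delta_table` for the NPP genes (needs `symbol`,
#'   `mu_max`).
#' @param npgpcr_table `delta_table` for the NP-GPCR genes.
#' @param panel A [gene_panel()] containing the NPP and NP_GPCR rows with
#'   `cognate_group` keys (`;`-separated for promiscuous ligands).
#' @param threshold Expression threshold on `mu_max` (strict `>`), default 10.
#' @param type_resolved Use the per-type definition instead of area-level.
#' @param npp_signature,npgpcr_signature `signature_matrix` objects, required
#'   when `type_resolved = TRUE`.
#' @return A `pairing_report`: list with `table` (one row per NPP) and
#'   `summary` (`n_npp_expressed`, `n_paired`, `paired_fraction`,
#'   `unresolvable`).
#' @export
cognate_pairing <- function(npp_table, npgpcr_table, panel, threshold = 10,
                            type_resolved = FALSE, npp_signature = NULL,
                            npgpcr_signature = NULL) {
  npp_rows <- panel[panel$category == "NPP", , drop = FALSE]
  rec_rows <- panel[panel$category == "NP_GPCR", , drop = FALSE]
  if (nrow(npp_rows) == 0) stop("panel contains no NPP rows", call. = FALSE)
  if (type_resolved && (is.null(npp_signature) || is.null(npgpcr_signature))) {
    stop("type_resolved pairing needs both signature matrices", call. = FALSE)
  }
  split_groups <- function(g) {
    if (is.na(g)) character(0) else trimws(strsplit(g, ";", fixed = TRUE)[[1]])
  }
  expressed <- function(tab, sym) {
    i <- match(sym, tab$symbol)
    !is.na(i) & tab$mu_max[i] > threshold
  }
  rec_groups <- lapply(rec_rows$cognate_group, split_groups)

  rows <- lapply(seq_len(nrow(npp_rows)), function(i) {
    sym <- npp_rows$symbol[i]
    grps <- split_groups(npp_rows$cognate_group[i])
    unresolvable <- length(grps) == 0
    cogs <- rec_rows$symbol[vapply(rec_groups, function(g) any(g %in% grps),
                                   logical(1))]
    expr <- expressed(npp_table, sym)
    if (type_resolved && expr && length(cogs) > 0) {
      ok_type <- npp_signature$means[sym, ] > threshold
      cogs_in <- intersect(cogs, rownames(npgpcr_signature$means))
      n_cog <- sum(vapply(cogs_in, function(cs) {
        any(ok_type & npgpcr_signature$means[cs, ] > threshold)
      }, logical(1)))
    } else {
      n_cog <- sum(expressed(npgpcr_table, cogs))
    }
    data.frame(symbol = sym, expressed = expr, unresolvable = unresolvable,
               cognate_symbols = paste(cogs, collapse = ";"),
               n_cognates_expressed = as.integer(n_cog),
               paired = expr & !unresolvable & n_cog > 0,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  eligible <- tab$expressed & !tab$unresolvable
  n_expr <- sum(eligible)
  n_paired <- sum(tab$paired)
  structure(list(
    table = tab,
    summary = list(n_npp_expressed = n_expr, n_paired = n_paired,
                   paired_fraction = if (n_expr > 0) n_paired / n_expr else NA_real_,
                   unresolvable = tab$symbol[tab$unresolvable],
                   threshold = threshold,
                   type_resolved = type_resolved)),
    class = "pairing_report")
}

#' @export
print.pairing_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pairing_report> %d/%d expressed NPPs have an expressed cognate NP-GPCR (paired fraction %s)\n",
              s$n_paired, s$n_npp_expressed,
              ifelse(is.na(s$paired_fraction), "NA",
                     format(s$paired_fraction, digits = 3))))
  if (length(s$unresolvable) > 0) {
    cat("  unresolvable (no cognate group): ",
        paste(s$unresolvable, collapse = ", "), "\n")
  }
  invisible(x)
}
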