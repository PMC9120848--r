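#' Construct a 4-level neurotaxonomy
#'
#' A hierarchical classification of neuron types with four levels
#' (class > subclass > supertype > type), one row per leaf type. Every leaf
#' must have exactly one ancestor at each level, i.e. a supertype may not
#' appear under two subclasses nor a subclass under two classes. Each leaf
#' carries a neurotransmitter class label (`"GABAergic"` or
#' `"glutamatergic"`) and display colors per level, used by the figure layer.
#'
#' @param df Data frame with columns `type_id`, `supertype_id`,
#'   `subclass_id`, `class_id`, and optionally `nt_class` (defaults to the
#'   `class_id` when that is already one of the two labels) and color columns
#'   `type_color`, `supertype_color`, `subclass_color`, `class_color`
#'   (auto-assigned from fixed palettes when absent).
#' @return A `taxonomy` object (validated data frame, one row per leaf type).
#' @export
taxonomy <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("type_id", "supertype_id", "subclass_id", "class_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("taxonomy table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$type_id)) {
    stop("duplicate leaf type_id in taxonomy: ",
         paste(unique(df$type_id[duplicated(df$type_id)]), collapse = ", "),
         call. = FALSE)
  }
  # each taxon must have a single parent
  check_single_parent <- function(child, parent, lab) {
    tab <- unique(df[, c(child, parent)])
    bad <- tab[[child]][duplicated(tab[[child]])]
    if (length(bad) > 0) {
      stop(lab, " ", paste(unique(bad), collapse = ", "),
           " assigned to more than one parent", call. = FALSE)
    }
  }
  check_single_parent("supertype_id", "subclass_id", "supertype")
  check_single_parent("subclass_id", "class_id", "subclass")

  if (is.null(df$nt_class)) {
    if (all(tolower(df$class_id) %in% c("gabaergic", "glutamatergic"))) {
      df$nt_class <- ifelse(tolower(df$class_id) == "gabaergic",
                            "GABAergic", "glutamatergic")
    } else {
      stop("`nt_class` column required when class IDs are not ",
           "GABAergic/glutamatergic", call. = FALSE)
    }
  }
  ok <- df$nt_class %in% c("GABAergic", "glutamatergic")
  if (!all(ok)) {
    stop("nt_class must be 'GABAergic' or 'glutamatergic'; got: ",
         paste(unique(df$nt_class[!ok]), collapse = ", "), call. = FALSE)
  }

  level_cols <- c(type = "type_id", supertype = "supertype_id",
                  subclass = "subclass_id", class = "class_id")
  palettes <- c(type = "Spectral", supertype = "Dark 3",
                subclass = "Set 2", class = "Harmonic")
  for (lv in names(level_cols)) {
    col <- paste0(lv, "_color")
    if (is.null(df[[col]])) {
      ids <- unique(df[[level_cols[[lv]]]])
      pal <- grDevices::hcl.colors(max(length(ids), 2L), palettes[[lv]])
      df[[col]] <- pal[match(df[[level_cols[[lv]]]], ids)]
    }
  }
  class(df) <- c("taxonomy", "data.frame")
  df
}

#' Leaf types of a taxonomy, in taxonomy order
#' @param tax A `taxonomy`.
#' @export
taxonomy_leaves <- function(tax) tax$type_id

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf(
    "<taxonomy> %d classes / %d subclasses / %d supertypes / %d types (%d GABAergic, %d glutamatergic)\n",
    length(unique(x$class_id)), length(unique(x$subclass_id)),
    length(unique(x$supertype_id)), nrow(x),
    sum(x$nt_class == "GABAergic"), sum(x$nt_class == "glutamatergic")))
  invisible(x)
}

#' Construct and validate per-cell annotations against a taxonomy
#'
#' Each cell is assigned a sampling region and a leaf type plus its ancestors;
#' the whole root-to-leaf path must agree with the taxonomy. Cells whose path
#' is inconsistent are rejected with an error naming them.
#'
#' @param df Data frame with columns `cell_id`, `region`, `type_id`,
#'   `supertype_id`, `subclass_id`, `class_id`.
#' @param tax The `taxonomy` the annotations must be consistent with.
#' @return A validated `cell_annotation` data frame.
#' @export
cell_annotation <- function(df, tax) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("cell_id", "region", "type_id", "supertype_id", "subclass_id",
            "class_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("annotation missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id in annotation", call. = FALSE)
  }
  unknown <- setdiff(df$type_id, tax$type_id)
  if (length(unknown) > 0) {
    stop("annotation references unknown leaf types: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(df$type_id, tax$type_id)
  bad <- df$supertype_id != tax$supertype_id[idx] |
    df$subclass_id != tax$subclass_id[idx] |
    df$class_id != tax$class_id[idx]
  if (any(bad)) {
    stop("inconsistent taxonomy path for cells: ",
         paste(utils::head(df$cell_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("cell_annotation", "data.frame")
  df
}

#' Neurotransmitter class (GABAergic / glutamatergic) per cell
#'
#' @param annotation A `cell_annotation`.
#' @param tax The matching `taxonomy`.
#' @return Factor with levels `GABAergic`, `glutamatergic`, aligned with the
#'   rows of `annotation`.
#' @export
cell_classes <- function(annotation, tax) {
  factor(tax$nt_class[match(annotation$type_id, tax$type_id)],
         levels = c("GABAergic", "glutamatergic"))
}
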