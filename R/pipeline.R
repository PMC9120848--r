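#' Read a pipeline run configuration (YAML or JSON)
#'
#' A run configuration collects input paths, filter thresholds, co-expression
#' and robustness parameters, and the output directory shared by the
#' `cmd_*()` stage commands. Unset fields fall back to defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file; or an already-parsed list.
#' @return A `run_config` list.
#' @export
run_config <- function(path) {
  cfg <- if (is.list(path)) path else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg$out_dir <- cfg$out_dir %||% "neurosig_out"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  f <- cfg$filter %||% list()
  cfg$filter_spec <- filter_spec(
    region = f$region %||% "CA1",
    min_cells_per_type = f$min_cells_per_type %||% 16,
    expression_threshold = f$expression_threshold %||% 10)
  cfg$coexpression <- cfg$coexpression %||% list()
  cfg$coexpression$threshold <- cfg$coexpression$threshold %||%
    cfg$filter_spec$expression_threshold
  cfg$robustness <- cfg$robustness %||% list()
  cfg$robustness$n_reps <- cfg$robustness$n_reps %||% 50
  cfg$robustness$seed <- cfg$robustness$seed %||% cfg$seed
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

.write_manifest <- function(out_dir, command, params, files) {
  manifest <- list(command = command, params = params,
                   files = as.list(files))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(command, ".manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# shared input loading for the analysis stages
.load_inputs <- function(cfg) {
  p <- cfg$paths
  if (is.null(p$matrix) || is.null(p$annotation)) {
    stop("config must set paths$matrix and paths$annotation", call. = FALSE)
  }
  x <- read_expression(p$matrix,
                       unit = p$matrix_unit %||% "counts",
                       orientation = p$orientation %||% "genes_by_cells")
  ann <- read_annotation(p$annotation)
  panel <- if (!is.null(p$panel)) read_gene_panel(p$panel) else NULL
  list(matrix = x, taxonomy = ann$taxonomy, annotation = ann$annotation,
       panel = panel)
}

# run the core pipeline: select cells -> CPM -> signatures -> gene filter
.run_signatures <- function(cfg, inputs) {
  sel <- select_cells(inputs$matrix, inputs$annotation, inputs$taxonomy,
                      cfg$filter_spec)
  cpm <- to_cpm(sel$matrix)
  sig <- type_means(cpm, sel$annotation, sel$retained_types)
  flt <- filter_genes(sig, panel = inputs$panel, spec = cfg$filter_spec)
  c(flt, list(cpm = cpm, annotation = sel$annotation,
              retained_types = sel$retained_types, full_signature = sig))
}

#' Stage command: simulate a dataset to disk
#'
#' Writes the count matrix (MatrixMarket + sidecars), cell annotation,
#' taxonomy, planted ground truth, a panel describing the simulated genes,
#' the simulator config and a manifest into `out_dir`.
#'
#' @param config A `run_config`, config file path, or list; simulator
#'   parameters are read from its `simulate` entry (see [sim_config()]),
#'   with the top-level `seed` as default seed.
#' @return Invisibly, the named list of written files.
#' @export
cmd_simulate <- function(config) {
  cfg <- run_config(config)
  sim_args <- cfg$simulate %||% list()
  if (!is.null(sim_args$n_genes)) sim_args$n_genes <- unlist(sim_args$n_genes)
  sim_args$seed <- sim_args$seed %||% cfg$seed
  scfg <- do.call(sim_config, sim_args)
  sim <- simulate_cells(scfg)
  out <- .ensure_dir(cfg$out_dir)
  files <- c(matrix = file.path(out, "matrix.mtx"),
             annotation = file.path(out, "annotation.csv"),
             taxonomy = file.path(out, "taxonomy.csv"),
             truth_genes = file.path(out, "truth_genes.csv"),
             truth_profile = file.path(out, "truth_profile.csv"),
             panel = file.path(out, "panel.csv"),
             sim_config = file.path(out, "sim_config.yaml"))
  write_expression(sim$matrix, files[["matrix"]])
  write_annotation(sim$annotation, sim$taxonomy, files[["annotation"]])
  write_taxonomy(sim$taxonomy, files[["taxonomy"]])
  utils::write.csv(sim$truth$genes, files[["truth_genes"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(symbol = rownames(sim$truth$profile),
                              sim$truth$profile, check.names = FALSE),
                   files[["truth_profile"]], row.names = FALSE, quote = FALSE)
  write_gene_panel(simulated_panel(sim$truth), files[["panel"]])
  write_sim_config(scfg, files[["sim_config"]])
  .write_manifest(out, "simulate", unclass(scfg), files)
  invisible(files)
}

#' Stage command: compute signatures, delta table and filtering cascade
#'
#' Runs select_cells -> to_cpm -> type_means -> filter_genes ->
#' order_by_delta and writes `signatures.csv` (+ per-type cell counts),
#' `delta.csv` (delta-descending) and `cascade.json`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the named list of written files.
#' @export
cmd_signatures <- function(config) {
  cfg <- run_config(config)
  res <- .run_signatures(cfg, .load_inputs(cfg))
  out <- .ensure_dir(cfg$out_dir)
  files <- c(signatures = file.path(out, "signatures.csv"),
             delta = file.path(out, "delta.csv"),
             cascade = file.path(out, "cascade.json"))
  write_signature(res$signature, files[["signatures"]])
  ord <- order_by_delta(res$delta_table)
  utils::write.csv(res$delta_table[ord, , drop = FALSE], files[["delta"]],
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(as.list(res$cascade),
                         list(retained_types = res$retained_types,
                              missing_symbols = res$missing_symbols,
                              seed = cfg$seed)),
                       files[["cascade"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .write_manifest(out, "signatures", unclass(cfg$filter_spec), files)
  invisible(files)
}

#' Stage command: per-cell co-expression tallies
#'
#' Computes per-cell counts of panel genes above the threshold, split by
#' neuron class, for every panel category present plus any merged panels
#' configured under `coexpression$merge` (named lists of categories). Writes
#' `coexpression.csv` (long histogram table) and `coexpression_modes.json`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the named list of written files.
#' @export
cmd_coexpress <- function(config) {
  cfg <- run_config(config)
  inputs <- .load_inputs(cfg)
  if (is.null(inputs$panel)) stop("config must set paths$panel", call. = FALSE)
  sel <- select_cells(inputs$matrix, inputs$annotation, inputs$taxonomy,
                      cfg$filter_spec)
  cpm <- to_cpm(sel$matrix)
  cats <- intersect(PANEL_CATEGORIES, unique(inputs$panel$category))
  panels <- stats::setNames(lapply(cats, panel_subset, panel = inputs$panel),
                            cats)
  for (nm in names(cfg$coexpression$merge %||% list())) {
    panels[[nm]] <- panel_subset(inputs$panel,
                                 unlist(cfg$coexpression$merge[[nm]]))
  }
  res <- coexpression_summary(cpm, panels, sel$annotation, inputs$taxonomy,
                              threshold = cfg$coexpression$threshold)
  out <- .ensure_dir(cfg$out_dir)
  files <- c(histograms = file.path(out, "coexpression.csv"),
             modes = file.path(out, "coexpression_modes.json"))
  long <- do.call(rbind, lapply(names(res), function(nm) {
    cbind(panel = nm, coexpression_as_df(res[[nm]]))
  }))
  utils::write.csv(long, files[["histograms"]], row.names = FALSE,
                   quote = FALSE)
  modes <- lapply(res, function(r) lapply(r, function(g) {
    list(n_cells = g$n_cells, mode = g$mode)
  }))
  jsonlite::write_json(c(modes, list(threshold = cfg$coexpression$threshold)),
                       files[["modes"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .write_manifest(out, "coexpress",
                  list(threshold = cfg$coexpression$threshold), files)
  invisible(files)
}

#' Stage command: cognate NPP / NP-GPCR pairing
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the named list of written files.
#' @export
cmd_pair <- function(config) {
  cfg <- run_config(config)
  inputs <- .load_inputs(cfg)
  if (is.null(inputs$panel)) stop("config must set paths$panel", call. = FALSE)
  res <- .run_signatures(cfg, inputs)
  dt <- delta_table(res$full_signature, panel = inputs$panel)
  rep <- cognate_pairing(dt[dt$symbol %in%
                              inputs$panel$symbol[inputs$panel$category == "NPP"], ],
                         dt[dt$symbol %in%
                              inputs$panel$symbol[inputs$panel$category == "NP_GPCR"], ],
                         inputs$panel,
                         threshold = cfg$filter_spec$expression_threshold)
  out <- .ensure_dir(cfg$out_dir)
  files <- c(table = file.path(out, "pairing.csv"),
             summary = file.path(out, "pairing.json"))
  utils::write.csv(rep$table, files[["table"]], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(rep$summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .write_manifest(out, "pair",
                  list(threshold = cfg$filter_spec$expression_threshold),
                  files)
  invisible(files)
}

#' Stage command: stability and distribution diagnostics
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the named list of written files.
#' @export
cmd_robustness <- function(config) {
  cfg <- run_config(config)
  inputs <- .load_inputs(cfg)
  res <- .run_signatures(cfg, inputs)
  genes <- rownames(res$signature$means)  # genes passing the filter
  stab <- subsample_stability(res$cpm, res$annotation, genes = genes,
                              n_reps = cfg$robustness$n_reps,
                              seed = cfg$robustness$seed)
  diag <- distribution_diagnostics(
    res$cpm, res$annotation, genes = genes,
    min_cells = cfg$filter_spec$min_cells_per_type,
    expression_threshold = cfg$filter_spec$expression_threshold)
  out <- .ensure_dir(cfg$out_dir)
  files <- c(stability = file.path(out, "stability.csv"),
             diagnostics = file.path(out, "diagnostics.csv"),
             summary = file.path(out, "robustness.json"))
  utils::write.csv(stab$per_gene, files[["stability"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(diag, files[["diagnostics"]], row.names = FALSE,
                   quote = FALSE)
  summary <- list(n_reps = stab$n_reps, seed = stab$seed,
                  median_cor = stats::median(stab$per_gene$median_cor,
                                             na.rm = TRUE),
                  n_low_anomalies = sum(diag$low_anomaly),
                  n_high_outlier_subsets = sum(diag$n_high_outliers > 0))
  if (!is.null(inputs$panel)) {
    bc <- stability_by_category(stab, inputs$panel)
    summary$by_category <- stats::setNames(as.list(bc$median_cor),
                                           bc$category)
  }
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .write_manifest(out, "robustness", cfg$robustness, files)
  invisible(files)
}

#' Stage command: regenerate figures from saved stage outputs
#'
#' Consumes only the CSV outputs of previous stages (never the raw matrix):
#' `signatures.csv` + `delta.csv` + `taxonomy.csv` for the signature heatmap,
#' `coexpression.csv` for the histogram figure.
#'
#' @inheritParams cmd_simulate
#' @param format Figure format: `"svg"`, `"pdf"` or `"png"`.
#' @return Invisibly, the named list of written files.
#' @export
cmd_plot <- function(config, format = "svg") {
  cfg <- run_config(config)
  out <- cfg$out_dir
  files <- character(0)
  sig_path <- file.path(out, "signatures.csv")
  tax_path <- cfg$paths$taxonomy %||% file.path(out, "taxonomy.csv")
  if (file.exists(sig_path) && file.exists(tax_path)) {
    sig <- read_signature(sig_path)
    dt <- utils::read.csv(file.path(out, "delta.csv"),
                          stringsAsFactors = FALSE)
    tax <- read_taxonomy(tax_path)
    f <- file.path(out, paste0("signatures.", format))
    render_signature_figure(sig, dt, tax, f,
                            show_labels = nrow(sig$means) <= 60)
    files <- c(files, signature_figure = f)
  }
  coex_path <- file.path(out, "coexpression.csv")
  if (file.exists(coex_path)) {
    long <- utils::read.csv(coex_path, stringsAsFactors = FALSE)
    results <- lapply(split(long, long$panel), function(df) {
      groups <- lapply(split(df, df$group), function(g) {
        h <- stats::setNames(g$n_cells_at_count, g$count)
        mode <- if (sum(h) > 0) as.integer(names(h)[which.max(h)]) else NA_integer_
        list(n_cells = sum(h), histogram = h, mode = mode)
      })
      ord <- intersect(c("all", "GABAergic", "glutamatergic"), names(groups))
      structure(groups[ord], class = "coexpression_result")
    })
    f <- file.path(out, paste0("coexpression.", format))
    render_coexpression_figure(results, f)
    files <- c(files, coexpression_figure = f)
  }
  if (length(files) == 0) {
    stop("no stage outputs found in ", out, "; run cmd_signatures / ",
         "cmd_coexpress first", call. = FALSE)
  }
  .write_manifest(.ensure_dir(out), "plot", list(format = format), files)
  invisible(files)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the installed `neurosig` script:
#' `neurosig <simulate|signatures|coexpress|pair|robustness|plot> --config
#' <file> [--seed N] [--out DIR]`. Flags override the corresponding config
#' fields.
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit status (0 on success), invisibly.
#' @export
neurosig_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c(simulate = cmd_simulate, signatures = cmd_signatures,
            coexpress = cmd_coexpress, pair = cmd_pair,
            robustness = cmd_robustness, plot = cmd_plot)
  if (length(args) < 1 || !args[1] %in% names(cmds)) {
    message("usage: neurosig <", paste(names(cmds), collapse = "|"),
            "> --config <file> [--seed N] [--out DIR]")
    return(invisible(1L))
  }
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--log-level", type = "character",
                          default = "info", dest = "log_level")))
  opts <- optparse::parse_args(parser, args = args[-1])
  status <- tryCatch({
    cfg <- if (is.null(opts$config)) list() else run_config(opts$config)
    cfg <- unclass(cfg)
    if (!is.null(opts$seed)) cfg$seed <- opts$seed
    if (!is.null(opts$out)) cfg$out_dir <- opts$out
    cmds[[args[1]]](cfg)
    0L
  }, error = function(e) {
    message("neurosig ", args[1], " failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
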