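#' Configuration for the single-cell simulator
#'
#' The simulator emulates the structure of deep SMART-Seq-style single-cell
#' data over a 4-level neurotaxonomy: a planted hierarchy (default 2 classes /
#' 6 subclasses / 14 supertypes / 42 leaf types), uneven cells-per-type drawn
#' uniformly from a range (default 16--200, so the minimum-cell filter is
#' exercised at its boundary), and genes planted in four specificity classes:
#'
#' * `one_type_marker` -- elevated in exactly one leaf type,
#' * `supertype_program` -- elevated in all types of one supertype,
#' * `class_restricted` -- elevated throughout one class,
#' * `ubiquitous` -- flat baseline everywhere.
#'
#' Counts are negative binomial with per-gene dispersion around
#' `true CPM x library_size / 1e6`, with log-normal per-cell library sizes and
#' independent Bernoulli dropout. Targets are assigned round-robin across
#' taxa, which keeps the total planted expression per type balanced so CPM
#' renormalization does not distort the planted profiles.
#'
#' @param n_classes,n_subclasses,n_supertypes,n_types Hierarchy sizes; must be
#'   nested (`n_types >= n_supertypes >= n_subclasses >= n_classes >= 1`).
#' @param cells_per_type Length-2 integer range; cells per leaf type are drawn
#'   uniformly from it.
#' @param n_genes Named counts for the four specificity classes.
#' @param baseline_mean Baseline expression on the CPM scale (default 50).
#' @param marker_fold Fold-elevation of planted targets over `baseline_mean`
#'   (default 20, i.e. markers at 1000 CPM).
#' @param marker_baseline Off-target level of planted genes; the default 0
#'   gives pure one-hot markers (delta exactly 1 on expected profiles); set
#'   `> 0` to exercise intermediate-delta regimes.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   `0` gives Poisson counts.
#' @param library_size_meanlog,library_size_sdlog Log-scale parameters of the
#'   per-cell total-count multiplier.
#' @param dropout_rate Probability that any count is independently zeroed.
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_classes = 2, n_subclasses = 6, n_supertypes = 14,
                       n_types = 42, cells_per_type = c(16, 200),
                       n_genes = c(one_type_marker = 84,
                                   supertype_program = 28,
                                   class_restricted = 12,
                                   ubiquitous = 76),
                       baseline_mean = 50, marker_fold = 20,
                       marker_baseline = 0, dispersion = 0.5,
                       library_size_meanlog = log(5e5),
                       library_size_sdlog = 0.4,
                       dropout_rate = 0.05, seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes),
              n_subclasses = as.integer(n_subclasses),
              n_supertypes = as.integer(n_supertypes),
              n_types = as.integer(n_types),
              cells_per_type = as.integer(cells_per_type),
              n_genes = n_genes, baseline_mean = baseline_mean,
              marker_fold = marker_fold, marker_baseline = marker_baseline,
              dispersion = dispersion,
              library_size_meanlog = library_size_meanlog,
              library_size_sdlog = library_size_sdlog,
              dropout_rate = dropout_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
}

#' @noRd
validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!(n_types >= n_supertypes && n_supertypes >= n_subclasses &&
          n_subclasses >= n_classes && n_classes >= 1)) {
      stop("hierarchy counts must nest: n_types >= n_supertypes >= ",
           "n_subclasses >= n_classes >= 1", call. = FALSE)
    }
    if (length(cells_per_type) != 2 || any(cells_per_type < 1) ||
        cells_per_type[1] > cells_per_type[2]) {
      stop("cells_per_type must be an increasing positive range [min, max]",
           call. = FALSE)
    }
    want <- c("one_type_marker", "supertype_program", "class_restricted",
              "ubiquitous")
    if (!setequal(names(n_genes), want) || any(n_genes < 0) ||
        sum(n_genes) < 1) {
      stop("n_genes must name the four specificity classes with ",
           "non-negative counts (at least one gene overall)", call. = FALSE)
    }
    if (dropout_rate < 0 || dropout_rate > 1) {
      stop("dropout_rate must lie in [0, 1]", call. = FALSE)
    }
    if (marker_fold <= 1) stop("marker_fold must exceed 1", call. = FALSE)
    if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
    if (baseline_mean <= 0) stop("baseline_mean must be positive", call. = FALSE)
    if (marker_baseline < 0) stop("marker_baseline must be >= 0", call. = FALSE)
  })
  class(cfg) <- "sim_config"
  cfg
}

# distribute n children over k parents as evenly as possible
.split_evenly <- function(n, k) {
  base <- n %/% k
  base + (seq_len(k) <= n %% k)
}

#' Simulate a nested 4-level neurotaxonomy
#'
#' Leaves are distributed as evenly as possible over supertypes, supertypes
#' over subclasses, and subclasses over classes. With two classes they are
#' labelled GABAergic and glutamatergic; otherwise neurotransmitter labels
#' alternate by class. The construction is deterministic (no RNG is
#' consumed), so identical configs always give identical trees.
#'
#' @param config A [sim_config()].
#' @return A [taxonomy()] with `config$n_types` leaves.
#' @export
simulate_taxonomy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sc_of_class <- rep(seq_len(config$n_classes),
                     .split_evenly(config$n_subclasses, config$n_classes))
  st_of_sc <- rep(seq_len(config$n_subclasses),
                  .split_evenly(config$n_supertypes, config$n_subclasses))
  ty_of_st <- rep(seq_len(config$n_supertypes),
                  .split_evenly(config$n_types, config$n_supertypes))
  if (config$n_classes == 2) {
    class_ids <- c("GABAergic", "Glutamatergic")
    nt <- c("GABAergic", "glutamatergic")
  } else {
    class_ids <- sprintf("Class%02d", seq_len(config$n_classes))
    nt <- rep(c("GABAergic", "glutamatergic"),
              length.out = config$n_classes)
  }
  ty <- seq_len(config$n_types)
  st <- ty_of_st[ty]
  sc <- st_of_sc[st]
  cl <- sc_of_class[sc]
  taxonomy(data.frame(
    type_id = sprintf("T%02d", ty),
    supertype_id = sprintf("ST%02d", st),
    subclass_id = sprintf("SC%02d", sc),
    class_id = class_ids[cl],
    nt_class = nt[cl],
    stringsAsFactors = FALSE))
}

# planted expected-CPM profile per gene x type, plus the gene design table
.plant_truth <- function(config, tax) {
  n_types <- nrow(tax)
  high <- config$marker_fold * config$baseline_mean
  low <- config$marker_baseline
  supertypes <- unique(tax$supertype_id)
  classes <- unique(tax$class_id)

  rows <- list()
  profiles <- list()
  add <- function(symbol, spec_class, target_ids, profile) {
    rows[[length(rows) + 1]] <<- data.frame(
      symbol = symbol, specificity_class = spec_class,
      target_taxa = paste(target_ids, collapse = ";"),
      stringsAsFactors = FALSE)
    profiles[[length(profiles) + 1]] <<- profile
  }
  ng <- config$n_genes
  for (i in seq_len(ng[["one_type_marker"]])) {
    tgt <- ((i - 1) %% n_types) + 1
    p <- rep(low, n_types)
    p[tgt] <- high
    add(sprintf("Otm%03d", i), "one_type_marker", tax$type_id[tgt], p)
  }
  for (i in seq_len(ng[["supertype_program"]])) {
    tgt <- supertypes[((i - 1) %% length(supertypes)) + 1]
    p <- ifelse(tax$supertype_id == tgt, high, low)
    add(sprintf("Stp%03d", i), "supertype_program", tgt, p)
  }
  for (i in seq_len(ng[["class_restricted"]])) {
    tgt <- classes[((i - 1) %% length(classes)) + 1]
    p <- ifelse(tax$class_id == tgt, high, low)
    add(sprintf("Clr%03d", i), "class_restricted", tgt, p)
  }
  for (i in seq_len(ng[["ubiquitous"]])) {
    add(sprintf("Ubi%03d", i), "ubiquitous", character(0),
        rep(config$baseline_mean, n_types))
  }
  genes <- do.call(rbind, rows)
  profile <- do.call(rbind, profiles)
  dimnames(profile) <- list(genes$symbol, tax$type_id)
  structure(list(genes = genes, profile = profile), class = "ground_truth")
}

#' Simulate single cells over a planted taxonomy
#'
#' Draws cells per leaf type uniformly from the configured range, plants
#' true expected-CPM profiles per gene (see [sim_config()]), and samples
#' counts per gene x cell from a negative binomial with mean
#' `true_cpm x library_size / 1e6`, followed by independent dropout. Every
#' cell is annotated with region `"CA1"` and its full taxonomy path.
#'
#' @param config A [sim_config()].
#' @param tax A taxonomy, normally [simulate_taxonomy()]`(config)`.
#' @return List with `matrix` (counts [expression_matrix()]), `annotation`
#'   (`cell_annotation`), `truth` (`ground_truth`: design table plus the
#'   planted expected-CPM profile matrix) and `taxonomy`.
#' @export
simulate_cells <- function(config, tax = simulate_taxonomy(config)) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(tax) != config$n_types) {
    stop("taxonomy has ", nrow(tax), " leaves but config expects ",
         config$n_types, call. = FALSE)
  }
  truth <- .plant_truth(config, tax)
  n_genes <- nrow(truth$profile)

  set.seed(config$seed)
  rng <- config$cells_per_type
  n_per_type <- if (rng[1] == rng[2]) rep(rng[1], config$n_types) else
    sample(seq(rng[1], rng[2]), config$n_types, replace = TRUE)
  type_of_cell <- rep(seq_len(config$n_types), times = n_per_type)
  n_cells <- length(type_of_cell)
  cell_id <- sprintf("C%05d", seq_len(n_cells))

  lib <- stats::rlnorm(n_cells, config$library_size_meanlog,
                       config$library_size_sdlog)
  mu <- truth$profile[, type_of_cell, drop = FALSE] *
    rep(lib / 1e6, each = n_genes)
  counts <- if (config$dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  if (config$dropout_rate > 0) {
    counts[stats::runif(length(counts)) < config$dropout_rate] <- 0L
  }
  counts <- matrix(counts, nrow = n_genes,
                   dimnames = list(rownames(truth$profile), cell_id))

  idx <- type_of_cell
  ann <- cell_annotation(data.frame(
    cell_id = cell_id, region = "CA1",
    type_id = tax$type_id[idx], supertype_id = tax$supertype_id[idx],
    subclass_id = tax$subclass_id[idx], class_id = tax$class_id[idx],
    stringsAsFactors = FALSE), tax)

  list(matrix = expression_matrix(counts, unit = "counts"),
       annotation = ann, truth = truth, taxonomy = tax)
}

#' Expected realized CPM of the planted design
#'
#' The planted profile is specified on a nominal CPM scale, but since the
#' simulated genes make up the whole measured transcriptome, CPM
#' normalization rescales each type by `1e6 / sum(planted CPM in that type)`.
#' This accessor applies that rescaling, giving the expectation of the
#' realized type-mean CPM (under no dropout). With the default round-robin
#' target assignment the per-type totals are equal, so the rescaling is a
#' single global factor and planted profile shapes (and hence delta) are
#' preserved exactly.
#'
#' @param truth A `ground_truth` from [simulate_cells()].
#' @return Matrix of expected CPM, same shape as `truth$profile`.
#' @export
expected_cpm <- function(truth) {
  sweep(truth$profile, 2, colSums(truth$profile), "/") * 1e6
}

#' A gene panel describing simulated genes
#'
#' Maps the simulator's specificity classes onto panel categories so that
#' downstream panel-based stages (gene filtering, co-expression, figures) can
#' run end-to-end on synthetic data. The mapping is arbitrary but fixed:
#' one-type markers become NPPs, supertype programs NP-GPCRs, class-restricted
#' genes K channels and ubiquitous genes G proteins.
#'
#' @param truth A `ground_truth` from [simulate_cells()].
#' @return A [gene_panel()] covering every simulated gene.
#' @export
simulated_panel <- function(truth) {
  map <- c(one_type_marker = "NPP", supertype_program = "NP_GPCR",
           class_restricted = "K_channel", ubiquitous = "G_protein")
  g <- truth$genes
  gene_panel(data.frame(
    symbol = g$symbol, category = unname(map[g$specificity_class]),
    subcategory = g$specificity_class,
    transduction = NA_character_, cognate_group = NA_character_,
    stringsAsFactors = FALSE))
}

#' Write / read simulator configuration as YAML (or JSON)
#'
#' @param config A [sim_config()].
#' @param path Output path; `.yaml`/`.yml` or `.json`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$n_genes <- as.list(x$n_genes)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  x$n_genes <- unlist(x$n_genes)
  do.call(sim_config, x)
}
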