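# Shared fixtures: all synthetic data is generated in code at test time.

# small balanced world: 4 types under 2 supertypes, 20 genes, no dropout
tiny_config <- function(...) {
  args <- list(n_classes = 1, n_subclasses = 1, n_supertypes = 2,
               n_types = 4, cells_per_type = c(20, 20),
               n_genes = c(one_type_marker = 4, supertype_program = 2,
                           class_restricted = 1, ubiquitous = 13),
               dropout_rate = 0, seed = 11)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# a bare expression matrix with explicit values
make_matrix <- function(values, unit = "counts",
                        genes = sprintf("g%d", seq_len(nrow(values))),
                        cells = sprintf("c%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, cells)
  expression_matrix(values, unit = unit)
}

# single-class taxonomy over the given leaf types
flat_taxonomy <- function(types) {
  taxonomy(data.frame(type_id = types, supertype_id = "ST1",
                      subclass_id = "SC1", class_id = "GABAergic",
                      stringsAsFactors = FALSE))
}

flat_annotation <- function(cells, types, tax, region = "CA1") {
  i <- match(types, tax$type_id)
  cell_annotation(data.frame(cell_id = cells, region = region,
                             type_id = types,
                             supertype_id = tax$supertype_id[i],
                             subclass_id = tax$subclass_id[i],
                             class_id = tax$class_id[i],
                             stringsAsFactors = FALSE), tax)
}

# independent linear-interpolation quantile (oracle for flag_outliers)
q_interp <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# panel + delta tables planting n expressed NPPs with one expressed cognate
pairing_fixture <- function(n = 18, receptor_mu = 50, npp_mu = 50) {
  groups <- sprintf("G%02d", seq_len(n))
  panel <- gene_panel(data.frame(
    symbol = c(sprintf("Npp%02d", seq_len(n)), sprintf("Rec%02d", seq_len(n))),
    category = rep(c("NPP", "NP_GPCR"), each = n),
    cognate_group = c(groups, groups), stringsAsFactors = FALSE))
  npp <- data.frame(symbol = sprintf("Npp%02d", seq_len(n)), mu_max = npp_mu)
  rec <- data.frame(symbol = sprintf("Rec%02d", seq_len(n)), mu_max = receptor_mu)
  list(panel = panel, npp = npp, rec = rec)
}
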