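test_that("to_cpm scales every cell to one million", {
  x <- make_matrix(matrix(c(90, 10, 1, 1), nrow = 2))
  y <- to_cpm(x)
  expect_equal(unname(y$values[, 1]), c(900000, 100000))
  expect_equal(y$unit, "CPM")

  x3 <- make_matrix(matrix(c(1, 1, 2), nrow = 3))
  expect_equal(unname(to_cpm(x3)$values[, 1]), c(250000, 250000, 500000))

  # idempotent on CPM input
  expect_identical(to_cpm(y), y)

  # column-sum invariant on simulated data
  sim <- simulate_cells(tiny_config())
  cs <- colSums(to_cpm(sim$matrix)$values)
  expect_equal(unname(cs), rep(1e6, length(cs)), tolerance = 1e-9)

  bad <- make_matrix(matrix(c(1, 2, 0, 0), nrow = 2))
  expect_error(to_cpm(bad), "zero total")
})

test_that("select_cells keeps types at the inclusive 16-cell boundary", {
  tax <- flat_taxonomy(c("A", "B", "C"))
  n <- c(A = 20, B = 16, C = 15)
  cells <- sprintf("c%02d", seq_len(sum(n)))
  types <- rep(names(n), n)
  ann <- flat_annotation(cells, types, tax)
  x <- make_matrix(matrix(1, nrow = 2, ncol = sum(n)), cells = cells)

  sel <- select_cells(x, ann, tax, filter_spec(min_cells_per_type = 16))
  expect_equal(sel$retained_types, c("A", "B"))
  expect_equal(ncol(sel$matrix), 36)

  all_types <- select_cells(x, ann, tax, filter_spec(min_cells_per_type = 1))
  expect_equal(all_types$retained_types, c("A", "B", "C"))

  # non-CA1 cells never count toward the minimum
  ann2 <- ann
  ann2$region[ann2$type_id == "A"] <- "DG"
  sel2 <- select_cells(x, ann2, tax, filter_spec(min_cells_per_type = 16))
  expect_equal(sel2$retained_types, "B")

  expect_error(select_cells(x, ann, tax, filter_spec(min_cells_per_type = 99)),
               "no type")

  sim <- simulate_cells(sim_config(seed = 2))
  sel42 <- select_cells(sim$matrix, sim$annotation, sim$taxonomy)
  expect_equal(length(sel42$retained_types), 42)
})

test_that("type_means is the untrimmed group-by mean, exactly", {
  tax <- flat_taxonomy(c("A", "B"))
  x <- make_matrix(matrix(c(10, 20, 0), nrow = 1, ncol = 3), unit = "CPM",
                   genes = "g")
  ann <- flat_annotation(colnames(x$values), c("A", "A", "B"), tax)
  sig <- type_means(x, ann, c("A", "B"))
  expect_equal(unname(sig$means["g", ]), c(15, 0))
  expect_equal(unname(sig$cells_per_type), c(2L, 1L))

  # single cell per type: signature equals the cell's CPM row
  x1 <- make_matrix(matrix(c(3, 7), nrow = 1), unit = "CPM", genes = "g")
  ann1 <- flat_annotation(colnames(x1$values), c("A", "B"), tax)
  expect_equal(unname(type_means(x1, ann1, c("A", "B"))$means["g", ]),
               c(3, 7))

  # random fixture vs naive double-loop oracle, full precision
  set.seed(81)
  v <- matrix(round(stats::rexp(50 * 200) * 100, 3), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%03d", 1:200)))
  types <- sample(LETTERS[1:8], 200, replace = TRUE)
  taxr <- flat_taxonomy(LETTERS[1:8])
  annr <- flat_annotation(colnames(v), types, taxr)
  sig <- type_means(expression_matrix(v, "CPM"), annr, LETTERS[1:8])
  oracle <- matrix(NA_real_, 50, 8, dimnames = list(rownames(v), LETTERS[1:8]))
  for (g in 1:50) for (ty in LETTERS[1:8]) {
    oracle[g, ty] <- mean(v[g, types == ty])
  }
  expect_identical(unname(sig$means), unname(oracle))

  expect_error(type_means(expression_matrix(v, "CPM"), annr, LETTERS[1:9]),
               "zero cells|outside")
})

test_that("delta matches its closed forms and hand evaluations", {
  expect_identical(delta(rep(5, 5)), 0)
  expect_identical(delta(c(0, 0, 7, 0)), 1)
  expect_equal(delta(c(10, 5, 0, 0)), 2.5 / 3)
  expect_true(is.na(delta(c(0, 0, 0))))
  expect_error(delta(5), "at least 2")
  expect_error(delta(c(-1, 2)), "non-negative")
})

test_that("delta is scale- and permutation-invariant, bounded, monotone", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    mu <- stats::rexp(n) * 10
    mu[sample(n, sample(0:(n - 1), 1))] <- 0
    if (max(mu) == 0) mu[1] <- 1
    d <- delta(mu)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(delta(mu * 17.3), d)
    expect_equal(delta(sample(mu)), d)
    # diluting with a duplicate of the max strictly decreases delta
    # for non-uniform profiles
    if (stats::sd(mu) > 0) {
      expect_lt(delta(c(mu, max(mu))), d)
    }
  }
})

test_that("delta_table flags undetected genes and keeps them out of ordering", {
  m <- matrix(c(10, 5, 0, 0,
                0, 0, 0, 0,
                2, 2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "zero", "flat"), paste0("T", 1:4)))
  sig <- structure(list(means = m, cells_per_type = c(T1 = 5L, T2 = 5L,
                                                      T3 = 5L, T4 = 5L)),
                   class = "signature_matrix")
  dt <- delta_table(sig)
  expect_equal(dt$delta[dt$symbol == "a"], 2.5 / 3)
  expect_true(is.na(dt$delta[dt$symbol == "zero"]))
  expect_true(is.na(dt$log10_rowmax[dt$symbol == "zero"]))
  expect_equal(dt$delta[dt$symbol == "flat"], 0)
  ord <- order_by_delta(dt)
  expect_equal(dt$symbol[ord], c("a", "flat"))  # "zero" excluded
})

test_that("gene filter is strictly greater-than at the threshold", {
  m <- matrix(c(10.5, 1, 10.0, 1, 3.0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("hi", "boundary", "lo"), c("T1", "T2")))
  sig <- structure(list(means = m, cells_per_type = c(T1 = 20L, T2 = 20L)),
                   class = "signature_matrix")
  flt <- filter_genes(sig, spec = filter_spec(expression_threshold = 10))
  expect_equal(rownames(flt$signature$means), "hi")
  expect_equal(unname(flt$cascade), c(3L, 3L, 1L))

  all_in <- filter_genes(sig, spec = filter_spec(expression_threshold = 1e-9))
  expect_equal(nrow(all_in$signature$means), 3)

  # missing panel symbols are reported, not fatal
  pan <- gene_panel(data.frame(symbol = c("hi", "ghost"),
                               category = "other"))
  expect_message(flt2 <- filter_genes(sig, panel = pan,
                                      spec = filter_spec()),
                 "ghost")
  expect_equal(flt2$missing_symbols, "ghost")
  expect_equal(unname(flt2$cascade), c(2L, 1L, 1L))

  hi_spec <- filter_spec(expression_threshold = 1e6)
  expect_warning(empty <- filter_genes(sig, spec = hi_spec), "no gene")
  expect_equal(nrow(empty$signature$means), 0)
})

test_that("display order: descending delta, mu_max then symbol break ties", {
  dt <- data.frame(symbol = c("a", "b", "c"), delta = c(0.2, 0.9, 0.5),
                   mu_max = c(1, 1, 1), stringsAsFactors = FALSE)
  expect_equal(dt$symbol[order_by_delta(dt)], c("b", "c", "a"))

  tie <- data.frame(symbol = c("b", "a"), delta = c(0.5, 0.5),
                    mu_max = c(10, 100), stringsAsFactors = FALSE)
  expect_equal(tie$symbol[order_by_delta(tie)], c("a", "b"))

  tie2 <- data.frame(symbol = c("b", "a"), delta = 0.5, mu_max = 10,
                     stringsAsFactors = FALSE)
  expect_equal(tie2$symbol[order_by_delta(tie2)], c("a", "b"))

  sorted <- data.frame(symbol = c("a", "b"), delta = c(0.9, 0.1),
                       mu_max = c(5, 5), stringsAsFactors = FALSE)
  expect_equal(order_by_delta(sorted), c(1L, 2L))
})

test_that("planted specificity is recovered by delta on a simulated world", {
  sim <- simulate_cells(tiny_config(cells_per_type = c(100, 100), seed = 8))
  sel <- select_cells(sim$matrix, sim$annotation, sim$taxonomy)
  sig <- type_means(to_cpm(sel$matrix), sel$annotation, sel$retained_types)
  dt <- delta_table(sig)
  cls <- sim$truth$genes$specificity_class[match(dt$symbol,
                                                 sim$truth$genes$symbol)]
  expect_true(all(dt$delta[cls == "one_type_marker"] > 0.95))
  expect_true(all(dt$delta[cls == "ubiquitous"] < 0.3))
})
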