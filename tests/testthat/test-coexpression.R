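panel4 <- gene_panel(data.frame(symbol = c("g1", "g2", "g3", "g4"),
                                category = "NP_GPCR"))

test_that("per-cell counts use the strict > threshold", {
  v <- matrix(c(12, 10, 10.1, 9.9), ncol = 1,
              dimnames = list(c("g1", "g2", "g3", "g4"), "c1"))
  x <- expression_matrix(v, "CPM")
  expect_equal(unname(coexpression_counts(x, panel4, threshold = 10)), 2)

  zero <- expression_matrix(v * 0, "CPM")
  expect_equal(unname(coexpression_counts(zero, panel4)), 0)

  # threshold below every nonzero value: count = number of nonzero genes
  expect_equal(unname(coexpression_counts(x, panel4, threshold = 1e-9)), 4)

  expect_error(coexpression_counts(x, panel4[0, ]), "empty")
  expect_error(coexpression_counts(expression_matrix(v, "counts"), panel4),
               "CPM")
})

test_that("counts are monotone non-increasing in the threshold", {
  set.seed(7)
  v <- matrix(stats::rexp(4 * 50) * 20, nrow = 4,
              dimnames = list(c("g1", "g2", "g3", "g4"),
                              sprintf("c%02d", 1:50)))
  x <- expression_matrix(v, "CPM")
  prev <- coexpression_counts(x, panel4, threshold = 0)
  for (th in c(1, 5, 10, 20, 50)) {
    cur <- coexpression_counts(x, panel4, threshold = th)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("histograms bin by unit width, split by class, mode ties -> smallest", {
  h <- count_histogram(c(2, 2, 3))
  expect_equal(h$all$histogram, c(`0` = 0L, `1` = 0L, `2` = 2L, `3` = 1L))
  expect_equal(h$all$mode, 2L)

  tie <- count_histogram(rep(c(1, 4), each = 5))
  expect_equal(tie$all$mode, 1L)

  # degenerate planted design: every cell expresses exactly k genes
  k <- count_histogram(rep(7L, 30))
  expect_equal(unname(k$all$histogram["7"]), 30L)
  expect_equal(k$all$mode, 7L)

  # class split partitions the all-cells histogram cell-wise
  set.seed(1)
  counts <- sample(0:6, 200, replace = TRUE)
  classes <- factor(sample(c("GABAergic", "glutamatergic"), 200,
                           replace = TRUE))
  res <- count_histogram(counts, classes)
  expect_equal(res$GABAergic$histogram + res$glutamatergic$histogram,
               res$all$histogram)
  expect_equal(sum(res$all$histogram), 200)
  expect_equal(sum(res$GABAergic$histogram), sum(classes == "GABAergic"))
})

test_that("panel merging unions symbols and rejects category conflicts", {
  mk <- function(prefix, n, category) {
    gene_panel(data.frame(symbol = sprintf("%s%03d", prefix, seq_len(n)),
                          category = category))
  }
  gpcr <- list(mk("Ma", 24, "monoamine_GPCR"), mk("Sm", 17, "small_molecule_GPCR"),
               mk("Np", 43, "NP_GPCR"))
  expect_equal(nrow(merge_panels(gpcr)), 84)
  chan <- list(mk("Na", 12, "Na_channel"), mk("Ca", 20, "Ca_channel"),
               mk("Kc", 60, "K_channel"), mk("Lg", 41, "ligand_gated_channel"))
  expect_equal(nrow(merge_panels(chan)), 133)

  a <- gene_panel(data.frame(symbol = c("x", "y"), category = "K_channel"))
  b <- gene_panel(data.frame(symbol = c("y", "z"), category = "K_channel"))
  expect_equal(sort(merge_panels(a, b)$symbol), c("x", "y", "z"))

  conflict <- gene_panel(data.frame(symbol = "y", category = "Na_channel"))
  expect_error(merge_panels(a, conflict), "conflicting")
})

test_that("merged-panel counts equal sums over disjoint sub-panels", {
  sim <- simulate_cells(tiny_config())
  cpm <- to_cpm(sim$matrix)
  panel <- simulated_panel(sim$truth)
  parts <- lapply(unique(panel$category), panel_subset, panel = panel)
  merged <- merge_panels(parts)
  per_part <- Reduce(`+`, lapply(parts, function(p) {
    coexpression_counts(cpm, p, threshold = 10)
  }))
  expect_equal(coexpression_counts(cpm, merged, threshold = 10), per_part)
})
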