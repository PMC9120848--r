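test_that("simulated taxonomy has the configured nested structure", {
  tax <- simulate_taxonomy(sim_config())
  expect_equal(nrow(tax), 42)
  expect_equal(length(unique(tax$supertype_id)), 14)
  expect_equal(length(unique(tax$subclass_id)), 6)
  expect_equal(length(unique(tax$class_id)), 2)
  expect_setequal(unique(tax$nt_class), c("GABAergic", "glutamatergic"))
  # every leaf has exactly one ancestor per level by construction/validation
  expect_s3_class(tax, "taxonomy")

  one <- simulate_taxonomy(sim_config(n_classes = 1, n_subclasses = 1,
                                      n_supertypes = 1, n_types = 1))
  expect_equal(nrow(one), 1)

  expect_error(sim_config(n_classes = 3, n_subclasses = 2),
               "nest")
})

test_that("simulation is seed-deterministic and shape-correct", {
  cfg <- tiny_config(n_genes = c(one_type_marker = 4, supertype_program = 0,
                                 class_restricted = 0, ubiquitous = 96))
  a <- simulate_cells(cfg)
  b <- simulate_cells(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$annotation, b$annotation)
  expect_equal(dim(a$matrix), c(100, 80))  # 100 genes x 4 types * 20 cells

  c2 <- simulate_cells(tiny_config(seed = 99,
                                   n_genes = c(one_type_marker = 4,
                                               supertype_program = 0,
                                               class_restricted = 0,
                                               ubiquitous = 96)))
  expect_false(identical(a$matrix$values, c2$matrix$values))

  expect_true(all(a$matrix$values >= 0))
  expect_true(all(a$matrix$values == floor(a$matrix$values)))
  expect_setequal(a$annotation$cell_id, colnames(a$matrix$values))
  expect_false(anyDuplicated(a$annotation$cell_id) > 0)
})

test_that("planted profiles follow the design", {
  cfg <- tiny_config(marker_baseline = 50)
  sim <- simulate_cells(cfg)
  truth <- sim$truth
  otm <- truth$genes$specificity_class == "one_type_marker"
  for (g in which(otm)) {
    p <- truth$profile[g, ]
    tgt <- truth$genes$target_taxa[g]
    expect_equal(unname(p[tgt]), cfg$marker_fold * cfg$baseline_mean)
    expect_true(all(p[names(p) != tgt] == cfg$marker_baseline))
  }
  ubi <- truth$profile[truth$genes$specificity_class == "ubiquitous", ,
                       drop = FALSE]
  expect_true(all(ubi == cfg$baseline_mean))
})

test_that("delta on noiseless expected profiles hits its endpoints", {
  sim <- simulate_cells(tiny_config())   # marker_baseline = 0
  truth <- sim$truth
  spec_class <- truth$genes$specificity_class
  d <- apply(truth$profile, 1, delta)
  expect_true(all(d[spec_class == "one_type_marker"] == 1))
  expect_true(all(d[spec_class == "ubiquitous"] == 0))
})

test_that("empirical type means converge to the planted truth", {
  # noise-free regime: Poisson counts, fixed library size, no dropout
  cfg <- tiny_config(cells_per_type = c(500, 500), dispersion = 0,
                     library_size_sdlog = 0, dropout_rate = 0, seed = 3)
  sim <- simulate_cells(cfg)
  cpm <- to_cpm(sim$matrix)
  sig <- type_means(cpm, sim$annotation, taxonomy_leaves(sim$taxonomy))
  truth <- expected_cpm(sim$truth)[rownames(sig$means), colnames(sig$means)]
  nz <- truth > 0
  rel_err <- abs(sig$means[nz] - truth[nz]) / truth[nz]
  expect_lt(max(rel_err), 0.05)
})

test_that("counts are overdispersed when dispersion > 0", {
  cfg <- tiny_config(cells_per_type = c(300, 300), dropout_rate = 0,
                     library_size_sdlog = 0, dispersion = 0.5, seed = 5)
  sim <- simulate_cells(cfg)
  v <- sim$matrix$values
  m <- rowMeans(v)
  s2 <- apply(v, 1, stats::var)
  hi <- m >= 10
  expect_gte(mean(s2[hi] > m[hi]), 0.95)
})
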