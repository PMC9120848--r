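test_that("high-CPM outliers are flagged by the Q3 + 3*IQR rule", {
  v <- stats::setNames(c(rep(100, 19), 10000), sprintf("c%02d", 1:20))
  fl <- flag_outliers(v)
  expect_equal(fl$high_outlier_cells, "c20")
  expect_false(fl$low_anomaly)

  # excess zeros against a clearly expressing type
  v2 <- c(rep(0, 8), rep(200, 12))
  fl2 <- flag_outliers(v2)
  expect_equal(fl2$zero_fraction, 0.4)
  expect_true(fl2$low_anomaly)
  expect_length(fl2$high_outlier_cells, 0)

  # tight unimodal subset: no flags
  fl3 <- flag_outliers(seq(95, 105, length.out = 20))
  expect_false(fl3$low_anomaly)
  expect_length(fl3$high_outlier_cells, 0)

  expect_error(flag_outliers(rep(1, 10)), "minimum")
})

test_that("flag_outliers matches a brute-force quantile oracle", {
  set.seed(19)
  for (i in 1:100) {
    v <- round(stats::rexp(sample(16:60, 1)) * 50, 2)
    v[sample(length(v), sample(0:3, 1))] <- 0
    fl <- flag_outliers(v, min_cells = 16)
    lg <- log2(v + 1)
    fence <- q_interp(lg, 0.75) + 3 * (q_interp(lg, 0.75) - q_interp(lg, 0.25))
    expect_equal(fl$high_outlier_cells, as.character(which(lg > fence)))
    nz_med <- if (any(v > 0)) stats::median(v[v > 0]) else 0
    expect_identical(fl$low_anomaly, mean(v == 0) > 0.25 && nz_med > 10)
  }
})

test_that("outlier flags survive relabeling and proportional rescaling", {
  set.seed(23)
  v <- stats::setNames(c(rep(0, 5), stats::rexp(25) * 100),
                       sprintf("c%02d", 1:30))
  fl <- flag_outliers(v, expression_threshold = 10)
  shuffled <- v[sample(length(v))]
  fl_sh <- flag_outliers(shuffled, expression_threshold = 10)
  expect_setequal(fl_sh$high_outlier_cells, fl$high_outlier_cells)
  expect_identical(fl_sh$low_anomaly, fl$low_anomaly)

  # global CPM rescale + proportional threshold rescale: same zero/low calls;
  # the high fence is computed on log2(x+1) so only zero/low invariance is
  # exact under rescaling
  fl_sc <- flag_outliers(v * 10, expression_threshold = 100)
  expect_identical(fl_sc$low_anomaly, fl$low_anomaly)
  expect_identical(fl_sc$zero_fraction, fl$zero_fraction)
})

test_that("display-type selection picks the max and ~25% mid-range types", {
  m <- matrix(c(100, 27, 60, 5), nrow = 1,
              dimnames = list("g", paste0("T", 1:4)))
  sig <- structure(list(means = m,
                        cells_per_type = stats::setNames(rep(20L, 4),
                                                         paste0("T", 1:4))),
                   class = "signature_matrix")
  expect_equal(select_display_types(sig, "g"), c("T1", "T2"))  # 27 ~ 25
})

test_that("within_type_histograms returns the raw per-cell vectors", {
  tax <- flat_taxonomy(c("A", "B"))
  v <- matrix(c(0, 10, 20, 5), nrow = 1,
              dimnames = list("g", sprintf("c%d", 1:4)))
  ann <- flat_annotation(colnames(v), c("A", "A", "A", "B"), tax)
  x <- expression_matrix(v, "CPM")
  h <- within_type_histograms(x, ann, "g", types = c("A", "B"))
  expect_equal(unname(h$A), c(0, 10, 20))
  expect_equal(unname(h$B), 5)   # single-cell type: one value
  expect_error(within_type_histograms(x, ann, "nope", types = "A"),
               "not in matrix")
})

test_that("half-splits of within-type-identical data correlate exactly 1", {
  # every cell of a type is an identical copy, so the two halves always
  # produce identical signatures
  tax <- flat_taxonomy(paste0("T", 1:6))
  set.seed(4)
  proto <- matrix(stats::rexp(30 * 6) * 50, nrow = 30,
                  dimnames = list(sprintf("g%02d", 1:30), NULL))
  v <- proto[, rep(1:6, each = 10)]
  colnames(v) <- sprintf("c%02d", 1:60)
  v <- rbind(v, constant = 7)  # zero variance across types
  ann <- flat_annotation(colnames(v), rep(paste0("T", 1:6), each = 10), tax)
  st <- subsample_stability(expression_matrix(v, "CPM"), ann, n_reps = 5,
                            seed = 2)
  pg <- st$per_gene
  expect_true(all(pg$median_cor[pg$symbol != "constant"] == 1))
  expect_true(is.na(pg$median_cor[pg$symbol == "constant"]))
  expect_equal(pg$n_defined[pg$symbol == "constant"], 0)
})

test_that("stability is reproducible by seed and grows with sampling depth", {
  # intermediate-specificity markers (baseline 200, peak 1000) over 8 types:
  # half-split correlations are clearly below 1 at 20 cells/type and must
  # move up at 200 cells/type
  mk <- function(cells) {
    sim <- simulate_cells(tiny_config(n_types = 8,
                                      cells_per_type = c(cells, cells),
                                      n_genes = c(one_type_marker = 16,
                                                  supertype_program = 0,
                                                  class_restricted = 0,
                                                  ubiquitous = 4),
                                      marker_baseline = 200,
                                      dispersion = 1.5, seed = 31))
    sel <- select_cells(sim$matrix, sim$annotation, sim$taxonomy,
                        filter_spec(min_cells_per_type = 2))
    subsample_stability(to_cpm(sel$matrix), sel$annotation, n_reps = 15,
                        seed = 9)
  }
  shallow <- mk(20)
  deep <- mk(200)
  expect_gt(stats::median(deep$per_gene$median_cor, na.rm = TRUE),
            stats::median(shallow$per_gene$median_cor, na.rm = TRUE))

  again <- mk(20)
  expect_identical(shallow$per_gene, again$per_gene)
})

test_that("types below two cells are excluded with a warning", {
  tax <- flat_taxonomy(c("A", "B"))
  v <- matrix(stats::rexp(3 * 5), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), sprintf("c%d", 1:5)))
  ann <- flat_annotation(colnames(v), c("A", "A", "A", "A", "B"), tax)
  expect_warning(
    expect_error(subsample_stability(expression_matrix(v, "CPM"), ann),
                 ">= 2 usable types"),
    "excluded")
})
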