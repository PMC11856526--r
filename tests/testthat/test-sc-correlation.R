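test_that("QC removes low-prevalence features, empty cells, and low-complexity cells", {
  # hand-built 5 cells x 6 genes; scaled thresholds (2 cells/feature,
  # 3 features/cell); survivors enumerated by hand: gene g6 is seen in one
  # cell only; cell4 keeps two expressed features; cell5 is empty
  counts <- rbind(
    cell1 = c(1, 2, 3, 0, 0, 1),
    cell2 = c(1, 1, 0, 2, 1, 0),
    cell3 = c(0, 1, 1, 1, 0, 0),
    cell4 = c(5, 0, 0, 0, 7, 0),
    cell5 = c(0, 0, 0, 0, 0, 0))
  colnames(counts) <- paste0("g", 1:6)
  m <- toy_cell_matrix(counts,
                       mito = setNames(c(rep(FALSE, 4), TRUE, FALSE),
                                       paste0("g", 1:6)))
  out <- qc_filter(m, qc_config(min_cells_per_feature = 2,
                                min_features_per_cell = 3,
                                mito_percentile_cutoff = 100))
  expect_setequal(rownames(out$counts), c("cell1", "cell2", "cell3"))
  expect_setequal(colnames(out$counts), paste0("g", 1:5))
  log <- attr(out, "qc_log")
  expect_equal(log$removed, c(1L, 2L, 0L))
})

test_that("a cell with zero total count is removed at the cell stage", {
  counts <- rbind(cell1 = c(3, 2), cell2 = c(0, 0), cell3 = c(1, 4))
  m <- toy_cell_matrix(counts)
  out <- qc_filter(m, qc_config(min_cells_per_feature = 1,
                                min_features_per_cell = 1))
  expect_false("cell2" %in% rownames(out$counts))
})

test_that("the extreme-mito cell falls above the 99th percentile and is removed", {
  counts <- matrix(5, nrow = 10, ncol = 4)
  counts[10, ] <- c(0, 0, 0, 20)  # cell10: 100% mitochondrial
  m <- toy_cell_matrix(counts, mito = setNames(c(FALSE, FALSE, FALSE, TRUE),
                                               paste0("g", 1:4)))
  out <- qc_filter(m, qc_config(min_cells_per_feature = 1,
                                min_features_per_cell = 1))
  expect_false("cell10" %in% rownames(out$counts))
  expect_equal(nrow(out$counts), 9)
})

test_that("QC on empty results names the responsible stage", {
  counts <- rbind(cell1 = c(1, 0), cell2 = c(0, 1))
  m <- toy_cell_matrix(counts)
  err <- tryCatch(qc_filter(m, qc_config(min_cells_per_feature = 1,
                                         min_features_per_cell = 2)),
                  error = identity)
  expect_s3_class(err, "surfrank_qc_error")
  expect_match(conditionMessage(err), "cell-complexity")
})

test_that("log-normalization follows the library-size closed form", {
  counts <- rbind(cell1 = c(0, 4), cell2 = c(1, 0))
  m <- log_normalize(toy_cell_matrix(counts))
  expect_equal(as.numeric(m$normalized["cell1", "g1"]), 0)  # zero stays zero
  # a cell whose whole library is one gene: ln(1 + scale)
  expect_equal(as.numeric(m$normalized["cell2", "g1"]), log(10001))
  expect_equal(as.numeric(m$normalized["cell1", "g2"]), log(1 + 1e4))
})

test_that("exp(normalized) - 1 sums back to the scale factor per cell", {
  m <- simulate_single_cell(seed = 3, n_genes = 60, n_case_cells = 40,
                            n_control_cells = 20, n_module_genes = 5)
  m <- log_normalize(m)
  sums <- Matrix::rowSums(exp(as.matrix(m$normalized)) - 1)
  expect_equal(unname(sums), rep(1e4, nrow(m$counts)), tolerance = 1e-8)
})

test_that("correlations are invariant to positive affine transforms", {
  m <- simulate_single_cell(seed = 8, n_genes = 50, n_case_cells = 60,
                            n_control_cells = 30, n_module_genes = 5)
  m <- log_normalize(m)
  target <- attr(m, "target")
  g <- setdiff(colnames(m$counts), target)[1]
  norm <- as.matrix(m$normalized)
  norm[, g] <- 2 * norm[, target] + 1   # exact affine copy of the target
  m$normalized <- Matrix::Matrix(norm, sparse = TRUE)
  r <- target_correlations(m, target, "case")
  expect_equal(unname(r[g]), 1)

  # scaling another gene's normalized vector leaves its r unchanged
  g2 <- setdiff(colnames(m$counts), c(target, g))[1]
  r0 <- r[g2]
  norm[, g2] <- 0.3 * norm[, g2] + 7
  m$normalized <- Matrix::Matrix(norm, sparse = TRUE)
  r1 <- target_correlations(m, target, "case")[g2]
  expect_equal(unname(r1), unname(r0))
})

test_that("independent genes stay far below the module cutoff", {
  for (seed in 1:3) {
    m <- simulate_single_cell(seed = seed, n_genes = 20, n_case_cells = 2000,
                              n_control_cells = 10, n_module_genes = 2,
                              module_rho = 0, zero_target_fraction = 0)
    m <- log_normalize(m)
    r <- target_correlations(m, attr(m, "target"), "case")
    expect_true(all(abs(r) < 0.1))
  }
})

test_that("a planted module gene at generative correlation 0.8 clears 0.6", {
  m <- simulate_single_cell(seed = 14, n_genes = 500, n_case_cells = 2000,
                            n_control_cells = 50, n_module_genes = 3,
                            module_rho = 0.8)
  m <- log_normalize(m)
  r <- target_correlations(m, attr(m, "target"), "case")
  expect_true(all(r[attr(m, "module_genes")] >= 0.6))
})

test_that("cells not expressing the target are excluded per group", {
  m <- simulate_single_cell(seed = 6, n_genes = 40, n_case_cells = 200,
                            n_control_cells = 100, n_module_genes = 4,
                            zero_target_fraction = 0.25)
  m <- log_normalize(m)
  target <- attr(m, "target")
  r <- target_correlations(m, target, "case")
  eligible <- sum(m$cell_groups == "case" &
                    as.vector(m$counts[, target]) > 0)
  expect_equal(attr(r, "n_cells_used"), eligible)
  expect_true(all(attr(m, "zero_target_cells") %in%
                    rownames(m$counts)[as.vector(m$counts[, target]) == 0]))
})

test_that("too few target-expressing cells is an explicit error", {
  counts <- rbind(cell1 = c(1, 2), cell2 = c(0, 3), cell3 = c(0, 1),
                  cell4 = c(1, 0))
  m <- log_normalize(toy_cell_matrix(counts))
  expect_error(target_correlations(m, "g1", "case"),
               class = "surfrank_insufficient_data")
})

test_that("zero-variance genes are omitted from the correlation map", {
  # equal cell totals, so the constant-count gene is constant after
  # normalization too
  counts <- cbind(tg = c(1, 2, 3, 4), flat = c(2, 2, 2, 2),
                  ok = c(7, 6, 5, 4))
  rownames(counts) <- paste0("cell", 1:4)
  m <- log_normalize(toy_cell_matrix(counts))
  r <- target_correlations(m, "tg", "case")
  expect_false("flat" %in% names(r))
  expect_true("ok" %in% names(r))
})

test_that("the overlap rule assigns shared genes to the higher-r group", {
  # the published ANPEP case: above cutoff in both groups, higher in
  # control (0.630) than case (0.602) -> control module only
  mods <- resolve_modules(c(ANPEP = 0.602), c(ANPEP = 0.630), cutoff = 0.6)
  expect_equal(mods$module_control, "ANPEP")
  expect_equal(mods$module_case, character())

  mods2 <- resolve_modules(c(g = 0.9), c(g = 0.1), cutoff = 0.6)
  expect_equal(mods2$module_case, "g")
  expect_equal(mods2$module_control, character())

  expect_warning(
    mods3 <- resolve_modules(c(g = 0.7), c(g = 0.7), cutoff = 0.6),
    "tied")
  expect_equal(mods3$module_case, character())
  expect_equal(mods3$module_control, character())
})

test_that("resolved modules are disjoint for arbitrary correlation maps", {
  set.seed(55)
  for (i in 1:25) {
    genes <- paste0("g", 1:40)
    rc <- setNames(runif(40, -1, 1), genes)
    rn <- setNames(runif(40, -1, 1), genes)
    # plant exact ties on a few genes
    rn[1:3] <- rc[1:3]
    mods <- suppressWarnings(resolve_modules(rc, rn, cutoff = 0.3))
    expect_length(intersect(mods$module_case, mods$module_control), 0)
    expect_true(all(rc[mods$module_case] >= 0.3))
    expect_true(all(rn[mods$module_control] >= 0.3))
  }
})

test_that("correlate_target returns disjoint modules and audit counts", {
  m <- simulate_single_cell(seed = 10, n_genes = 300, n_case_cells = 1500,
                            n_control_cells = 500, n_module_genes = 6)
  res <- correlate_target(m, attr(m, "target"),
                          qc = qc_config(min_cells_per_feature = 30,
                                         min_features_per_cell = 100))
  expect_s3_class(res, "correlation_result")
  expect_length(intersect(res$module_case, res$module_control), 0)
  expect_false(res$target_gene %in% c(res$module_case, res$module_control))
  expect_setequal(attr(m, "module_genes"), res$module_case)
  df <- as.data.frame(res)
  expect_true(all(c("gene", "r_case", "r_control", "assigned_module")
                  %in% names(df)))
})
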