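# Rank scores from Table-1-shaped inputs: the eight candidate surface genes
# with their per-dataset rank scores (three transcript cohorts + one protein
# cohort). Used across several blocks below.
tbl1_rs <- list(
  A = c(TM4SF4 = 0.7, SLC2A2 = 0.6, TFR2 = 0.8, TM4SF5 = 0.2, SLC38A4 = 0.5,
        SLC22A7 = 0.4, SLC10A1 = 0.1, SLCO1B1 = 0.3),
  C = c(TM4SF4 = 0.8, SLC2A2 = 0.6, TFR2 = 0.7, TM4SF5 = 0.5, SLC38A4 = 0.3,
        SLC22A7 = 0.4, SLC10A1 = 0.1, SLCO1B1 = 0.2),
  G = c(TM4SF4 = 0.8, SLC2A2 = 0.7, TFR2 = 0.2, TM4SF5 = 0.4, SLC38A4 = 0.6,
        SLC22A7 = 0.1, SLC10A1 = 0.5, SLCO1B1 = 0.3),
  H = c(TM4SF4 = 0.7, SLC2A2 = 0.5, TFR2 = 0.6, TM4SF5 = 0.8, SLC38A4 = 0.4,
        SLC22A7 = 0.3, SLC10A1 = 0.2, SLCO1B1 = 0.1))
tbl1_modalities <- c("transcript", "transcript", "transcript", "protein")

test_that("medians follow the order-statistic rules", {
  vals <- matrix(c(1, 3, 100, 1, 3, 2), nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("odd", "even")))
  d <- expression_dataset(vals, c(s1 = "case", s2 = "case", s3 = "case"),
                          "D", "transcript")
  med <- median_expression(d, c("odd", "even"))
  expect_equal(med[["odd"]], 3)       # odd count: central value
  vals2 <- vals[1:2, , drop = FALSE]
  d2 <- expression_dataset(vals2, c(s1 = "case", s2 = "case"),
                           "D", "transcript")
  expect_equal(median_expression(d2, "odd")[["odd"]], 2)  # mean of central two
})

test_that("medians agree with a sort-based oracle on a random 35x8 matrix", {
  set.seed(31)
  vals <- matrix(rlnorm(35 * 8, 3, 1), 35, 8,
                 dimnames = list(sprintf("s%02d", 1:35), paste0("g", 1:8)))
  d <- expression_dataset(vals, setNames(rep("case", 35), rownames(vals)),
                          "D", "transcript")
  med <- median_expression(d, paste0("g", 1:8))
  expect_equal(med, apply(vals, 2, oracle_median))
})

test_that("genes absent from a dataset are excluded with a warning", {
  vals <- matrix(1:4, 2, 2, dimnames = list(c("s1", "s2"), c("g1", "g2")))
  d <- expression_dataset(vals, c(s1 = "case", s2 = "case"), "D", "transcript")
  expect_warning(med <- median_expression(d, c("g1", "g2", "CD24")),
                 "CD24")
  expect_equal(names(med), c("g1", "g2"))
})

test_that("rank scores climb in 0.1 steps with tied medians averaged", {
  med <- c(a = 5, b = 50, c = 1, d = 8, e = 20, f = 3, g = 100, h = 12)
  rs <- assign_rank_scores(med)
  expect_setequal(round(rs, 10), round(seq(0.1, 0.8, by = 0.1), 10))
  expect_equal(rs[["g"]], 0.8)  # highest median gets the top score
  expect_equal(assign_rank_scores(c(x = 7))[["x"]], 0.1)

  # two genes tied for top among four: both get (0.3 + 0.4) / 2
  rs_tied <- assign_rank_scores(c(a = 1, b = 2, c = 9, d = 9))
  expect_equal(rs_tied[["c"]], 0.35)
  expect_equal(rs_tied[["d"]], 0.35)
  # and that value equals the mean over the two possible strict orderings
  o1 <- c(a = 0.1, b = 0.2, c = 0.3, d = 0.4)
  o2 <- c(a = 0.1, b = 0.2, c = 0.4, d = 0.3)
  expect_equal(rs_tied[c("c", "d")], (o1[c("c", "d")] + o2[c("c", "d")]) / 2)
})

test_that("normalized scores divide by the dataset maximum", {
  expect_equal(normalize_scores(c(x = 0.7, y = 0.8))[["x"]], 0.875)
  expect_equal(normalize_scores(c(solo = 0.4))[["solo"]], 1)
  set.seed(5)
  for (i in 1:20) {
    rs <- setNames(runif(sample(1:9, 1), 0.05, 1), NULL)
    names(rs) <- paste0("g", seq_along(rs))
    ns <- normalize_scores(rs)
    expect_equal(max(ns), 1)
    expect_equal(ns * max(rs), rs)  # algebraic inverse
  }
})

test_that("aggregation reproduces the published-style weighted means", {
  ns <- lapply(tbl1_rs, normalize_scores)
  rt <- aggregate_scores(ns, tbl1_modalities)
  # the top row: transcript NS (0.875, 1, 1), protein NS 0.875
  expect_equal(round_half_away(rt$xbar_T[["TM4SF4"]]), 0.958)
  expect_equal(round_half_away(rt$xbar_TP[["TM4SF4"]]), 0.938)
  # weights with 3 transcript + 1 protein datasets are exactly 3/4 and 1/4
  expect_equal(rt$xbar_TP[["TM4SF4"]],
               3 / 4 * rt$xbar_T[["TM4SF4"]] + 1 / 4 * rt$xbar_P[["TM4SF4"]])
})

test_that("aggregation handles degenerate weightings", {
  ns <- list(d1 = c(a = 0.5, b = 1), d2 = c(a = 0.5, b = 1))
  # equal transcript and protein means collapse to the common value
  rt <- aggregate_scores(ns, c("transcript", "protein"))
  expect_equal(rt$xbar_TP, rt$xbar_T)
  expect_equal(rt$xbar_TP, rt$xbar_P)
  # no protein datasets: the combined score is the transcript mean
  rt_t <- aggregate_scores(ns, c("transcript", "transcript"))
  expect_null(rt_t$xbar_P)
  expect_equal(rt_t$xbar_TP, rt_t$xbar_T)
  expect_error(aggregate_scores(list(), character()), "at least one")
})

test_that("genes missing from any dataset are dropped before aggregation", {
  ns <- list(d1 = c(a = 0.5, b = 1), d2 = c(a = 1))
  expect_warning(rt <- aggregate_scores(ns, c("transcript", "protein")),
                 "b")
  expect_equal(rt$genes, "a")
})

test_that("a single dataset with a single gene scores exactly 1", {
  vals <- matrix(c(5, 7, 9), 3, 1,
                 dimnames = list(c("s1", "s2", "s3"), "g1"))
  d <- expression_dataset(vals, setNames(rep("case", 3), rownames(vals)),
                          "D", "transcript")
  rt <- rank_targets(list(d), list(), "g1")
  expect_equal(unname(rt$xbar_TP), 1)
})

test_that("simulated cohorts planted with the published rank pattern give the published final scores", {
  # ascending median orders implied by each dataset's rank scores
  orders <- lapply(tbl1_rs, function(rs) names(sort(rs)))
  genes <- names(tbl1_rs$A)
  sim <- simulate_bulk(genes, seed = 13, datasets = list(
    list(dataset_id = "A", modality = "transcript", n_case = 60,
         n_control = 20, median_order = orders$A),
    list(dataset_id = "C", modality = "transcript", n_case = 35,
         n_control = 20, median_order = orders$C),
    list(dataset_id = "G", modality = "transcript", n_case = 60,
         n_control = 20, median_order = orders$G),
    list(dataset_id = "H", modality = "protein", n_case = 60,
         n_control = 20, median_order = orders$H)))
  rt <- rank_targets(sim$transcript, sim$protein, genes)
  expect_equal(
    round_half_away(unname(rt$xbar_TP[rt$genes])),
    c(0.938, 0.750, 0.719, 0.594, 0.563, 0.375, 0.281, 0.281))
  expect_equal(rt$genes[1], "TM4SF4")
})

test_that("rank_targets agrees with the brute-force oracle on random instances", {
  set.seed(77)
  for (i in 1:60) {
    inst <- random_rank_instance()
    rt <- rank_targets(
      inst$datasets[inst$modalities == "transcript"],
      inst$datasets[inst$modalities == "protein"], inst$genes)
    case_vals <- lapply(inst$datasets, function(d)
      d$values[d$sample_groups == "case", , drop = FALSE])
    names(case_vals) <- vapply(inst$datasets, `[[`, character(1),
                               "dataset_id")
    oracle <- oracle_rank_aggregate(case_vals, inst$modalities)
    expect_equal(rt$xbar_TP[inst$genes], oracle$xbar_TP[inst$genes],
                 tolerance = 1e-12)
    expect_equal(
      rt$normalized_scores[inst$genes, colnames(rt$normalized_scores),
                           drop = FALSE],
      oracle$ns[inst$genes, colnames(rt$normalized_scores), drop = FALSE],
      tolerance = 1e-12)
  }
})

test_that("raising one gene's median never lowers its scores", {
  set.seed(42)
  for (i in 1:15) {
    inst <- random_rank_instance(tie_prob = 0)
    if (length(inst$genes) < 2) next
    rt0 <- rank_targets(inst$datasets[inst$modalities == "transcript"],
                        inst$datasets[inst$modalities == "protein"],
                        inst$genes)
    g <- sample(inst$genes, 1)
    bumped <- inst$datasets
    bumped[[1]]$values[, g] <- bumped[[1]]$values[, g] * 10
    rt1 <- rank_targets(bumped[inst$modalities == "transcript"],
                        bumped[inst$modalities == "protein"], inst$genes)
    expect_gte(rt1$rank_scores[[1]][[g]], rt0$rank_scores[[1]][[g]])
    expect_gte(rt1$xbar_TP[[g]], rt0$xbar_TP[[g]] - 1e-12)
  }
})

test_that("rescaling a dataset's expression leaves the rank table unchanged", {
  set.seed(43)
  inst <- random_rank_instance(tie_prob = 0)
  rt0 <- rank_targets(inst$datasets[inst$modalities == "transcript"],
                      inst$datasets[inst$modalities == "protein"], inst$genes)
  scaled <- inst$datasets
  scaled[[1]]$values <- scaled[[1]]$values * 3.7
  rt1 <- rank_targets(scaled[inst$modalities == "transcript"],
                      scaled[inst$modalities == "protein"], inst$genes)
  expect_equal(rt0$normalized_scores, rt1$normalized_scores)
  expect_equal(rt0$xbar_TP, rt1$xbar_TP)
  expect_equal(rt0$genes, rt1$genes)
})

test_that("display rounding is half away from zero at three decimals", {
  expect_equal(round_half_away(0.5625), 0.563)
  expect_equal(round_half_away(-0.5625), -0.563)
  expect_equal(round_half_away(0.2915), 0.292)  # note round(0.5625,3) == 0.562
})
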