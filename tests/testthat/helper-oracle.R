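# Independent brute-force implementation of the rank-aggregation statistic,
# kept deliberately free of the package's code paths: medians by explicit
# sort, ranks by pairwise comparison counting, aggregation by spelled-out
# arithmetic.

oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# ascending rank with tied ranks averaged, via comparison counting
oracle_rank <- function(m) {
  vapply(seq_along(m), function(i) {
    1 + sum(m < m[i]) + sum(m[-i] == m[i]) / 2
  }, numeric(1))
}

# case_values: named list of samples x genes matrices (case samples only)
oracle_rank_aggregate <- function(case_values, modalities, rs_step = 0.1) {
  genes <- colnames(case_values[[1]])
  ns <- sapply(case_values, function(vals) {
    med <- apply(vals, 2, oracle_median)
    rs <- oracle_rank(med) * rs_step
    rs / max(rs)
  })
  ns <- matrix(ns, nrow = length(genes),
               dimnames = list(genes, names(case_values)))
  m <- sum(modalities == "transcript")
  n <- sum(modalities == "protein")
  xt <- if (m > 0) apply(ns[, modalities == "transcript", drop = FALSE],
                         1, function(r) sum(r) / m) else rep(0, length(genes))
  xp <- if (n > 0) apply(ns[, modalities == "protein", drop = FALSE],
                         1, function(r) sum(r) / n) else rep(0, length(genes))
  list(ns = ns, xbar_T = if (m > 0) xt else NULL,
       xbar_P = if (n > 0) xp else NULL,
       xbar_TP = (m * xt + n * xp) / (m + n))
}

# random ranking instance: <= max_genes genes, <= max_datasets datasets,
# ties planted with probability tie_prob by duplicating values
random_rank_instance <- function(max_genes = 6, max_datasets = 4,
                                 tie_prob = 0.3) {
  n_genes <- sample(1:max_genes, 1)
  n_ds <- sample(1:max_datasets, 1)
  genes <- paste0("g", seq_len(n_genes))
  modalities <- sample(c("transcript", "protein"), n_ds, replace = TRUE)
  datasets <- lapply(seq_len(n_ds), function(j) {
    n_case <- sample(3:9, 1)
    n_ctrl <- sample(2:5, 1)
    vals <- matrix(round(stats::rlnorm(n_case * n_genes, 3, 1), 1),
                   n_case, n_genes)
    if (stats::runif(1) < tie_prob && n_genes > 1)
      vals[, 1] <- vals[, n_genes]  # force tied medians
    vals <- rbind(vals, matrix(stats::rlnorm(n_ctrl * n_genes, 2, 1),
                               n_ctrl, n_genes))
    rownames(vals) <- c(sprintf("c%d", seq_len(n_case)),
                        sprintf("n%d", seq_len(n_ctrl)))
    colnames(vals) <- genes
    expression_dataset(
      vals,
      stats::setNames(rep(c("case", "control"), c(n_case, n_ctrl)),
                      rownames(vals)),
      paste0("D", j), modalities[j])
  })
  list(genes = genes, datasets = datasets, modalities = modalities)
}
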