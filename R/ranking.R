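## Multi-dataset rank-score aggregation.
##
## Per dataset: median case expression per gene -> ascending rank score
## RS = k * 0.1 (k = 1 for the lowest median) -> normalized score
## NS = RS / max(RS), so the top gene in each dataset scores exactly 1.
## Across datasets: x̄_T = mean transcript NS, x̄_P = mean protein NS, and
## the final statistic x̄_TP = (m·x̄_T + n·x̄_P) / (m + n), weighting by the
## number of datasets of each modality.

#' Ranking configuration
#'
#' @param rs_step Rank-score increment per ascending rank position (default
#'   0.1, so eight genes span 0.1 to 0.8).
#' @param rounding_decimals Decimals used for reported (display) values;
#'   ordering always uses unrounded scores.
#' @return Object of class `ranking_config`.
#' @export
ranking_config <- function(rs_step = 0.1, rounding_decimals = 3) {
  stopifnot(rs_step > 0, rounding_decimals >= 0)
  structure(list(rs_step = rs_step, rounding_decimals = rounding_decimals),
            class = "ranking_config")
}

#' Per-gene median expression in one group
#'
#' @param d An [expression_dataset()].
#' @param genes Gene symbols to evaluate; genes absent from the dataset are
#'   dropped with a warning (they simply do not contribute to that dataset's
#'   ranking).
#' @param group `"case"` or `"control"`.
#' @return Named numeric vector of medians over the group's samples (even
#'   sample counts use the mean of the two central order statistics).
#' @export
median_expression <- function(d, genes, group = "case") {
  stopifnot(inherits(d, "expression_dataset"), group %in% c("case", "control"))
  missing <- setdiff(genes, colnames(d$values))
  if (length(missing))
    warn("dataset ", d$dataset_id, ": gene(s) not on platform, excluded: ",
         paste(missing, collapse = ", "))
  genes <- setdiff(genes, missing)
  rows <- d$sample_groups == group
  if (!any(rows)) abort("dataset ", d$dataset_id, " has no ", group, " samples")
  apply(d$values[rows, genes, drop = FALSE], 2, stats::median)
}

#' Assign rank scores from medians
#'
#' Genes are ranked ascending by median; the gene ranked `k` receives
#' `RS = k * rs_step`, so with eight genes the highest median earns 0.8.
#' Tied medians share the mean of their tied ranks' scores, which conserves
#' the total score and makes the result independent of input order.
#'
#' @param medians Named numeric vector, gene -> median expression.
#' @param cfg A [ranking_config()].
#' @return Named numeric vector of rank scores.
#' @export
assign_rank_scores <- function(medians, cfg = ranking_config()) {
  if (length(medians) == 0) abort("no genes to rank")
  rank(medians, ties.method = "average") * cfg$rs_step
}

#' Normalize rank scores within a dataset
#'
#' Divides each rank score by the dataset's maximum rank score, so NS lies
#' in (0, 1] with the top-ranked gene at exactly 1.
#'
#' @param rs Named numeric vector of positive rank scores.
#' @return Named numeric vector of normalized scores.
#' @export
normalize_scores <- function(rs) {
  if (length(rs) == 0) abort("no rank scores to normalize")
  if (any(rs <= 0)) abort("rank scores must be positive")
  rs / max(rs)
}

#' Aggregate per-dataset normalized scores into the final rank table
#'
#' Combines the per-dataset NS maps into the transcript mean `xbar_T`, the
#' protein mean `xbar_P` and the dataset-count-weighted final statistic
#' `xbar_TP = (m * xbar_T + n * xbar_P) / (m + n)` with `m` transcript and
#' `n` protein datasets. With a single protein dataset `xbar_P` equals that
#' dataset's NS; with `n = 0` the statistic reduces to `xbar_T` (and
#' symmetrically for `m = 0`). Genes missing from any dataset's NS map are
#' dropped with a warning before aggregation.
#'
#' @param ns_by_dataset Named list of NS maps (named numeric vectors), one
#'   per dataset.
#' @param modalities Character vector (`"transcript"`/`"protein"`), one per
#'   dataset, aligned with `ns_by_dataset`.
#' @param cfg A [ranking_config()].
#' @param medians Optional named list of the per-dataset median maps, stored
#'   in the result for reporting.
#' @param rank_scores Optional named list of per-dataset RS maps, stored in
#'   the result for reporting.
#' @return Object of class `rank_table`; see [rank_targets()].
#' @export
aggregate_scores <- function(ns_by_dataset, modalities,
                             cfg = ranking_config(),
                             medians = NULL, rank_scores = NULL) {
  stopifnot(length(ns_by_dataset) == length(modalities),
            all(modalities %in% c("transcript", "protein")))
  m <- sum(modalities == "transcript")
  n <- sum(modalities == "protein")
  if (m + n == 0) abort("need at least one dataset")

  common <- Reduce(intersect, lapply(ns_by_dataset, names))
  everything <- unique(unlist(lapply(ns_by_dataset, names)))
  dropped <- setdiff(everything, common)
  if (length(dropped))
    warn("gene(s) missing from at least one dataset, dropped from aggregation: ",
         paste(dropped, collapse = ", "))
  if (length(common) == 0) abort("no gene is present in every dataset")
  ns <- vapply(ns_by_dataset, function(v) v[common],
               numeric(length(common)))
  ns <- matrix(ns, nrow = length(common),
               dimnames = list(common, names(ns_by_dataset)))

  xbar_T <- if (m > 0)
    rowMeans(ns[, modalities == "transcript", drop = FALSE]) else NULL
  xbar_P <- if (n > 0)
    rowMeans(ns[, modalities == "protein", drop = FALSE]) else NULL
  xbar_TP <- (m * (xbar_T %||% 0) + n * (xbar_P %||% 0)) / (m + n)

  structure(
    list(genes = common[order(-xbar_TP, common)],
         medians = medians,
         rank_scores = rank_scores,
         normalized_scores = ns,
         modalities = stats::setNames(modalities, names(ns_by_dataset)),
         m = m, n = n,
         xbar_T = xbar_T, xbar_P = xbar_P, xbar_TP = xbar_TP,
         rounding_decimals = cfg$rounding_decimals),
    class = "rank_table"
  )
}

#' Rank candidate targets across transcript and protein datasets
#'
#' The end-to-end aggregation: per dataset, case-group medians are converted
#' to rank scores and normalized scores; the per-dataset NS maps are then
#' combined into the weighted `xbar_TP` statistic and the candidates sorted
#' by it. The top-ranked gene is the prioritised target.
#'
#' @param transcript,protein Lists of [expression_dataset()] objects (either
#'   may be empty, not both).
#' @param genes Gene symbols to rank.
#' @param cfg A [ranking_config()].
#' @return Object of class `rank_table` with per-dataset medians, RS and NS
#'   matrices, the aggregate columns `xbar_T`, `xbar_P`, `xbar_TP`, and
#'   `genes` ordered by descending unrounded `xbar_TP`.
#' @examples
#' sim <- simulate_bulk(genes = paste0("G", 1:5), seed = 1)
#' rt <- rank_targets(sim$transcript, sim$protein, paste0("G", 1:5))
#' rt$genes[1]  # top-ranked candidate
#' @export
rank_targets <- function(transcript, protein, genes, cfg = ranking_config()) {
  if (length(genes) == 0) abort("no genes to rank")
  datasets <- c(transcript, protein)
  if (length(datasets) == 0) abort("need at least one dataset")
  modalities <- c(rep("transcript", length(transcript)),
                  rep("protein", length(protein)))
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  if (anyDuplicated(ids)) abort("duplicate dataset ids")

  medians <- lapply(datasets, median_expression, genes = genes, group = "case")
  rs <- lapply(medians, assign_rank_scores, cfg = cfg)
  ns <- lapply(rs, normalize_scores)
  names(medians) <- names(rs) <- names(ns) <- ids
  aggregate_scores(ns, modalities, cfg, medians = medians, rank_scores = rs)
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("<rank_table> %d genes, %d transcript + %d protein dataset(s)\n",
              length(x$genes), x$m, x$n))
  cat(sprintf("  top-ranked: %s (xbar_TP = %s)\n", x$genes[1],
              format(round_half_away(x$xbar_TP[[x$genes[1]]],
                                     x$rounding_decimals))))
  print(utils::head(as.data.frame(x), 8))
  invisible(x)
}

#' @export
summary.rank_table <- function(object, ...) as.data.frame(object)

#' Rank table as a data.frame
#'
#' One row per gene in final rank order, with per-dataset RS and NS columns
#' and the rounded aggregate scores (half away from zero at the configured
#' number of decimals; ordering uses the unrounded values).
#'
#' @param x A `rank_table`.
#' @param ... Unused.
#' @return A data.frame.
#' @export
as.data.frame.rank_table <- function(x, ...) {
  g <- x$genes
  d <- data.frame(gene = g, rank = seq_along(g), stringsAsFactors = FALSE)
  for (id in colnames(x$normalized_scores)) {
    if (!is.null(x$rank_scores))
      d[[paste0("RS_", id)]] <- unname(x$rank_scores[[id]][g])
    d[[paste0("NS_", id)]] <-
      round_half_away(x$normalized_scores[g, id], x$rounding_decimals)
  }
  rd <- x$rounding_decimals
  if (!is.null(x$xbar_T)) d$xbar_T <- round_half_away(x$xbar_T[g], rd)
  if (!is.null(x$xbar_P)) d$xbar_P <- round_half_away(x$xbar_P[g], rd)
  d$xbar_TP <- round_half_away(x$xbar_TP[g], rd)
  rownames(d) <- NULL
  d
}

#' Write a rank table to TSV
#'
#' @param x A `rank_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rank_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
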