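## Single-cell QC, log-normalization, and per-group correlation-module
## extraction around a target gene. The module gene sets (one per group) are
## what feeds downstream ontology enrichment.

#' Single-cell QC and normalization configuration
#'
#' @param min_cells_per_feature Features present (count > 0) in fewer cells
#'   than this are removed (default 200).
#' @param min_features_per_cell Cells with fewer expressed features, or zero
#'   total count, are removed (default 500).
#' @param mito_percentile_cutoff Cells whose mitochondrial-count percentage
#'   lies strictly above this percentile (computed over all remaining cells
#'   pooled) are removed (default 99), excluding cells likely affected by
#'   apoptosis or stress.
#' @param normalization_scale Per-cell library-size scale factor for
#'   log-normalization (default 10000).
#' @return Object of class `qc_config`.
#' @export
qc_config <- function(min_cells_per_feature = 200,
                      min_features_per_cell = 500,
                      mito_percentile_cutoff = 99,
                      normalization_scale = 10000) {
  stopifnot(min_cells_per_feature > 0, min_features_per_cell > 0,
            mito_percentile_cutoff > 0, mito_percentile_cutoff <= 100,
            normalization_scale > 0)
  structure(list(min_cells_per_feature = min_cells_per_feature,
                 min_features_per_cell = min_features_per_cell,
                 mito_percentile_cutoff = mito_percentile_cutoff,
                 normalization_scale = normalization_scale),
            class = "qc_config")
}

#' Single-pass quality-control filtering
#'
#' Three stages applied once, in fixed order, without iteration:
#' 1. drop features present in fewer than `min_cells_per_feature` cells;
#' 2. drop cells with fewer than `min_features_per_cell` expressed features
#'    or a total count of zero;
#' 3. compute each remaining cell's mitochondrial-count percentage (over the
#'    remaining genes) and drop cells strictly above the
#'    `mito_percentile_cutoff` percentile of that distribution.
#'
#' Because stage 2 removes cells after stage 1 counted them, a surviving
#' feature is not guaranteed to still be present in `min_cells_per_feature`
#' of the surviving cells; each stage's rule held at the time it ran. This
#' single-pass semantics matches common practice in single-cell toolkits.
#'
#' @param m A [cell_matrix()].
#' @param cfg A [qc_config()].
#' @return A filtered `cell_matrix` with attribute `qc_log` (per-stage
#'   removal counts).
#' @export
qc_filter <- function(m, cfg = qc_config()) {
  stopifnot(inherits(m, "cell_matrix"))
  counts <- m$counts

  cells_per_feature <- Matrix::colSums(counts > 0)
  keep_genes <- cells_per_feature >= cfg$min_cells_per_feature
  counts <- counts[, keep_genes, drop = FALSE]
  if (ncol(counts) == 0)
    abort("QC removed every feature at stage 'feature-prevalence'",
          class = "surfrank_qc_error")

  feats_per_cell <- Matrix::rowSums(counts > 0)
  totals <- Matrix::rowSums(counts)
  keep_cells <- feats_per_cell >= cfg$min_features_per_cell & totals > 0
  counts <- counts[keep_cells, , drop = FALSE]
  n_cell_stage2 <- sum(!keep_cells)
  if (nrow(counts) == 0)
    abort("QC removed every cell at stage 'cell-complexity'",
          class = "surfrank_qc_error")

  mito <- m$mito_flags[colnames(counts)]
  mito_pct <- if (any(mito)) {
    100 * Matrix::rowSums(counts[, mito, drop = FALSE]) /
      Matrix::rowSums(counts)
  } else {
    rep(0, nrow(counts))
  }
  cutoff <- stats::quantile(mito_pct, cfg$mito_percentile_cutoff / 100,
                            names = FALSE)
  keep_mito <- mito_pct <= cutoff
  counts <- counts[keep_mito, , drop = FALSE]
  if (nrow(counts) == 0)
    abort("QC removed every cell at stage 'mito-content'",
          class = "surfrank_qc_error")

  out <- cell_matrix(counts, m$cell_groups[rownames(counts)],
                     m$mito_flags[colnames(counts)])
  attr(out, "qc_log") <- data.frame(
    stage = c("feature-prevalence", "cell-complexity", "mito-content"),
    removed = c(sum(!keep_genes), n_cell_stage2, sum(!keep_mito)),
    unit = c("features", "cells", "cells")
  )
  out
}

#' Log-normalize single-cell counts
#'
#' Standard library-size log-normalization:
#' `normalized[c, g] = ln(1 + counts[c, g] * scale / total(c))`. Cell totals
#' are strictly positive after [qc_filter()], so the transform is defined
#' everywhere; zero counts stay exactly zero and sparsity is preserved.
#'
#' @param m A QC-filtered [cell_matrix()].
#' @param cfg A [qc_config()] supplying `normalization_scale`.
#' @return The `cell_matrix` with its `normalized` slot filled in.
#' @export
log_normalize <- function(m, cfg = qc_config()) {
  stopifnot(inherits(m, "cell_matrix"))
  totals <- Matrix::rowSums(m$counts)
  if (any(totals == 0))
    abort("cells with zero total count present; run qc_filter() first")
  ## triplet form gives direct access to each entry's cell index
  tm <- methods::as(m$counts, "TsparseMatrix")
  tm@x <- log1p(tm@x * cfg$normalization_scale / totals[tm@i + 1L])
  m$normalized <- methods::as(tm, "CsparseMatrix")
  dimnames(m$normalized) <- dimnames(m$counts)
  m
}

#' Per-group Pearson correlations with a target gene
#'
#' Restricts to cells of the requested group whose *raw* target-gene count
#' is positive (cells not expressing the target carry no information about
#' co-expression with it), then computes the Pearson correlation of every
#' other gene's log-normalized vector against the target's. Genes with zero
#' variance across the eligible cells have no defined correlation and are
#' omitted from the result.
#'
#' @param m A log-normalized [cell_matrix()].
#' @param target Target gene symbol.
#' @param group `"case"` or `"control"`.
#' @return Named numeric vector of correlations with attribute
#'   `n_cells_used`.
#' @export
target_correlations <- function(m, target, group = c("case", "control")) {
  group <- match.arg(group)
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$normalized))
    abort("run log_normalize() before target_correlations()")
  if (!(target %in% colnames(m$counts)))
    abort("target gene not in matrix: ", target)
  cells <- rownames(m$counts)[m$cell_groups == group &
                                as.vector(m$counts[, target]) > 0]
  if (length(cells) < 3)
    abort("fewer than 3 ", group, " cells express ", target,
          class = "surfrank_insufficient_data")
  x <- as.matrix(m$normalized[cells, , drop = FALSE])
  tv <- x[, target]
  others <- setdiff(colnames(x), target)
  sds <- apply(x[, others, drop = FALSE], 2, stats::sd)
  informative <- others[sds > 0]
  r <- as.vector(stats::cor(x[, informative, drop = FALSE], tv))
  names(r) <- informative
  attr(r, "n_cells_used") <- length(cells)
  r
}

#' Resolve disjoint case/control correlation modules
#'
#' A gene joins the case module when its case correlation clears the cutoff
#' and either its control correlation does not, or the case correlation is
#' strictly larger (and symmetrically for the control module). A gene above
#' the cutoff in both groups is thus assigned to the group where it
#' correlates more strongly, keeping the two modules disjoint; an exact tie
#' above the cutoff in both groups is excluded from both with a warning.
#' Genes missing from one map (zero variance there) are treated as below
#' the cutoff in that group.
#'
#' @param r_case,r_control Named numeric correlation maps over a shared gene
#'   universe (the target excluded).
#' @param cutoff Correlation threshold (default 0.6).
#' @param comparison `">="` (default) or `">"`: how a correlation is tested
#'   against the cutoff.
#' @return List with elements `module_case` and `module_control` (character
#'   vectors, always disjoint).
#' @export
resolve_modules <- function(r_case, r_control, cutoff = 0.6,
                            comparison = c(">=", ">")) {
  comparison <- match.arg(comparison)
  clears <- function(r) !is.na(r) &
    (if (comparison == ">=") r >= cutoff else r > cutoff)
  universe <- union(names(r_case), names(r_control))
  rc <- stats::setNames(r_case[universe], universe)
  rn <- stats::setNames(r_control[universe], universe)
  case_ok <- clears(rc)
  ctrl_ok <- clears(rn)
  tie <- case_ok & ctrl_ok & rc == rn
  if (any(tie))
    warn("gene(s) tied above cutoff in both groups, excluded from both: ",
         paste(universe[tie], collapse = ", "))
  in_case <- case_ok & !tie & (!ctrl_ok | rc > rn)
  in_ctrl <- ctrl_ok & !tie & (!case_ok | rn > rc)
  list(module_case = universe[in_case], module_control = universe[in_ctrl])
}

#' Extract target-correlated modules from a single-cell matrix
#'
#' Convenience wrapper: QC, log-normalization, per-group target correlations
#' (each group restricted independently to its target-expressing cells) and
#' module resolution, returning everything downstream enrichment needs.
#'
#' @param m A raw [cell_matrix()].
#' @param target Target gene symbol.
#' @param cutoff Correlation threshold (default 0.6).
#' @param qc A [qc_config()].
#' @param comparison Cutoff comparison mode, see [resolve_modules()].
#' @param apply_qc Set `FALSE` if `m` is already QC-filtered.
#' @return Object of class `correlation_result` with the target, per-group
#'   correlation maps (`r_case`, `r_control`), eligible-cell counts
#'   (`n_cells_used`), the cutoff, and the disjoint `module_case` /
#'   `module_control` gene sets.
#' @export
correlate_target <- function(m, target, cutoff = 0.6, qc = qc_config(),
                             comparison = c(">=", ">"), apply_qc = TRUE) {
  comparison <- match.arg(comparison)
  if (apply_qc) m <- qc_filter(m, qc)
  m <- log_normalize(m, qc)
  r_case <- target_correlations(m, target, "case")
  r_control <- target_correlations(m, target, "control")
  mods <- resolve_modules(r_case, r_control, cutoff, comparison)
  structure(
    list(target_gene = target,
         r_case = r_case, r_control = r_control,
         n_cells_used = c(case = attr(r_case, "n_cells_used"),
                          control = attr(r_control, "n_cells_used")),
         cutoff = cutoff, comparison = comparison,
         module_case = mods$module_case,
         module_control = mods$module_control),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> target %s (cutoff r %s %s)\n",
              x$target_gene, x$comparison, format(x$cutoff)))
  cat(sprintf("  cells used: %d case, %d control\n",
              x$n_cells_used[["case"]], x$n_cells_used[["control"]]))
  cat(sprintf("  modules: %d case gene(s), %d control gene(s)\n",
              length(x$module_case), length(x$module_control)))
  invisible(x)
}

#' Correlation result as a per-gene data.frame
#'
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @return Data.frame with columns `gene`, `r_case`, `r_control`,
#'   `assigned_module` (`"case"`, `"control"` or `"none"`).
#' @export
as.data.frame.correlation_result <- function(x, ...) {
  universe <- sort(union(names(x$r_case), names(x$r_control)))
  module <- rep("none", length(universe))
  module[universe %in% x$module_case] <- "case"
  module[universe %in% x$module_control] <- "control"
  data.frame(gene = universe,
             r_case = unname(x$r_case[universe]),
             r_control = unname(x$r_control[universe]),
             assigned_module = module,
             stringsAsFactors = FALSE)
}

#' Write a correlation result to TSV
#'
#' @param x A `correlation_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_correlation_result <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
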