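## Sparse single-cell count matrices with cell group labels and
## mitochondrial gene flags. Storage is MatrixMarket coordinate format plus
## two row-aligned TSV sidecars (cells.tsv, genes.tsv).

#' Construct a single-cell count matrix
#'
#' @param counts Sparse (or dense) cells x genes matrix of non-negative
#'   integer counts, with cell row names and gene column names.
#' @param cell_groups Named character vector mapping every cell to `"case"`
#'   or `"control"`.
#' @param mito_flags Named logical vector, one flag per gene: is the gene
#'   mitochondrial.
#' @param normalized Optional cells x genes matrix of log-normalised values
#'   with the same dimensions as `counts` (filled in by [log_normalize()]).
#' @return Object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_groups, mito_flags, normalized = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("counts must have cell row names and gene column names")
  v <- counts@x
  if (any(v < 0) || any(v != round(v)))
    abort("counts must be non-negative integers",
          class = "surfrank_validation_error")
  missing_grp <- setdiff(rownames(counts), names(cell_groups))
  if (length(missing_grp))
    abort("cells without a group label: ",
          paste(utils::head(missing_grp, 5), collapse = ", "),
          class = "surfrank_validation_error")
  cell_groups <- cell_groups[rownames(counts)]
  missing_flag <- setdiff(colnames(counts), names(mito_flags))
  if (length(missing_flag))
    abort("genes without a mito flag: ",
          paste(utils::head(missing_flag, 5), collapse = ", "),
          class = "surfrank_validation_error")
  mito_flags <- mito_flags[colnames(counts)]
  if (!is.null(normalized) && !identical(dim(normalized), dim(counts)))
    abort("normalized matrix dimensions must equal counts",
          class = "surfrank_validation_error")
  structure(
    list(counts = counts, cell_groups = cell_groups,
         mito_flags = mito_flags, normalized = normalized),
    class = "cell_matrix"
  )
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes (%d case / %d control cells, %d mito genes)%s\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$cell_groups == "case"), sum(x$cell_groups == "control"),
              sum(x$mito_flags),
              if (is.null(x$normalized)) "" else ", log-normalized"))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Read a single-cell count matrix from MTX + sidecars
#'
#' The MTX file is MatrixMarket coordinate format (1-based, cells as rows).
#' `cells.tsv` must carry columns `cell` and `group`, row-aligned with the
#' matrix rows; `genes.tsv` carries `gene` and, optionally, a logical `mito`
#' column. When the `mito` column is absent, flags are derived from a
#' gene-name prefix (default `"MT-"`), the usual convention for human
#' mitochondrial genes.
#'
#' @param mtx_path Path to the MatrixMarket file.
#' @param cells_path,genes_path Paths to the TSV sidecars.
#' @param mito_prefix Gene-name prefix marking mitochondrial genes when the
#'   sidecar has no `mito` column.
#' @return A `cell_matrix`.
#' @export
read_cell_matrix <- function(mtx_path, cells_path, genes_path,
                             mito_prefix = "MT-") {
  for (p in c(mtx_path, cells_path, genes_path))
    if (!file.exists(p)) abort("file not found: ", p)
  counts <- Matrix::readMM(mtx_path)
  cells <- utils::read.delim(cells_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  genes <- utils::read.delim(genes_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  if (!("cell" %in% names(cells)) || !("group" %in% names(cells)))
    abort("cells sidecar needs 'cell' and 'group' columns",
          class = "surfrank_format_error")
  if (!("gene" %in% names(genes)))
    abort("genes sidecar needs a 'gene' column",
          class = "surfrank_format_error")
  if (nrow(cells) != nrow(counts) || nrow(genes) != ncol(counts))
    abort(sprintf(
      "dimension mismatch: matrix is %d x %d but sidecars have %d cells and %d genes",
      nrow(counts), ncol(counts), nrow(cells), nrow(genes)),
      class = "surfrank_format_error")
  dimnames(counts) <- list(cells$cell, genes$gene)
  mito <- if ("mito" %in% names(genes)) {
    as.logical(genes$mito) | tolower(as.character(genes$mito)) %in%
      c("true", "1", "yes")
  } else {
    startsWith(genes$gene, mito_prefix)
  }
  cell_matrix(counts,
              stats::setNames(cells$group, cells$cell),
              stats::setNames(mito, genes$gene))
}

#' Write a single-cell count matrix to MTX + sidecars
#'
#' Inverse of [read_cell_matrix()]; only raw counts are written (the
#' normalised layer, if any, is recomputable).
#'
#' @param m A `cell_matrix`.
#' @param mtx_path,cells_path,genes_path Output paths.
#' @return `mtx_path`, invisibly.
#' @export
write_cell_matrix <- function(m, mtx_path, cells_path, genes_path) {
  stopifnot(inherits(m, "cell_matrix"))
  Matrix::writeMM(m$counts, mtx_path)
  utils::write.table(
    data.frame(cell = rownames(m$counts), group = unname(m$cell_groups)),
    cells_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = colnames(m$counts),
               mito = ifelse(unname(m$mito_flags), "true", "false")),
    genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mtx_path)
}
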