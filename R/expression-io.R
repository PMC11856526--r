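## Bulk expression datasets (samples x genes, transcript or protein).

#' Construct a bulk expression dataset
#'
#' @param values Numeric matrix, samples in rows, genes in columns; both
#'   dimensions named. Values are non-negative expression in platform units
#'   (FPKM, TPM, normalised protein intensity, ...).
#' @param sample_groups Named character vector mapping every sample to
#'   `"case"` or `"control"`.
#' @param dataset_id Identifier used in reports and rank tables.
#' @param modality `"transcript"` or `"protein"`.
#' @return Object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, sample_groups, dataset_id,
                               modality = c("transcript", "protein")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("expression matrix must have sample row names and gene column names")
  if (anyDuplicated(colnames(values)))
    abort("duplicate gene columns", class = "surfrank_validation_error")
  missing_grp <- setdiff(rownames(values), names(sample_groups))
  if (length(missing_grp))
    abort("samples without a group label: ",
          paste(utils::head(missing_grp, 5), collapse = ", "),
          class = "surfrank_validation_error")
  sample_groups <- sample_groups[rownames(values)]
  if (!all(sample_groups %in% c("case", "control")))
    abort("group labels must be 'case' or 'control'",
          class = "surfrank_validation_error")
  if (!any(sample_groups == "case"))
    abort("dataset has no case samples", class = "surfrank_validation_error")
  structure(
    list(dataset_id = dataset_id, modality = modality,
         values = values, sample_groups = sample_groups),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s (%s): %d samples (%d case / %d control) x %d genes\n",
              x$dataset_id, x$modality, nrow(x$values),
              sum(x$sample_groups == "case"),
              sum(x$sample_groups == "control"), ncol(x$values)))
  invisible(x)
}

#' Read a bulk expression dataset from TSV
#'
#' Expects a header row; the first column holds sample ids, a `group` column
#' holds `case`/`control`, and every remaining column is one gene.
#'
#' @param path TSV file path.
#' @param dataset_id Identifier for the dataset (defaults to the file name
#'   without extension).
#' @param modality `"transcript"` or `"protein"`.
#' @return An `expression_dataset`.
#' @export
read_expression_dataset <- function(path, dataset_id = NULL,
                                    modality = c("transcript", "protein")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) abort("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!("group" %in% names(tab)))
    abort("expression table is missing required column: group",
          class = "surfrank_format_error")
  samples <- as.character(tab[[1]])
  groups <- stats::setNames(tab$group, samples)
  gene_cols <- setdiff(names(tab), c(names(tab)[1], "group"))
  values <- as.matrix(tab[, gene_cols, drop = FALSE])
  rownames(values) <- samples
  expression_dataset(values, groups,
                     dataset_id %||% tools::file_path_sans_ext(basename(path)),
                     modality)
}

#' Write a bulk expression dataset to TSV
#'
#' Inverse of [read_expression_dataset()]: first column `sample`, then
#' `group`, then one column per gene, full numeric precision.
#'
#' @param d An `expression_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_dataset <- function(d, path) {
  stopifnot(inherits(d, "expression_dataset"))
  flat <- data.frame(sample = rownames(d$values),
                     group = unname(d$sample_groups),
                     stringsAsFactors = FALSE, check.names = FALSE)
  for (g in colnames(d$values)) flat[[g]] <- num_to_chr(d$values[, g])
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
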