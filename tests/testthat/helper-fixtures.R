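# Small constructors used across test files.

# one gene's annotation as the list the shortlist predicates consume;
# defaults pass every filter
g_ann <- function(gene = "G1",
                  brain_distribution = "not_detected",
                  tissue_distribution = "detected_in_some",
                  tissue_nx = c(lung = 1.0),
                  cancer_fpkm = c("liver cancer" = 60),
                  subcellular = data.frame(
                    location = c("plasma membrane", "cytosol"),
                    confidence = c(5, 3)),
                  blood_detected = FALSE) {
  list(gene = gene, brain_distribution = brain_distribution,
       tissue_distribution = tissue_distribution, tissue_nx = tissue_nx,
       cancer_fpkm = cancer_fpkm, subcellular = subcellular,
       blood_detected = blood_detected)
}

# a single-gene annotation table built from g_ann-style arguments
ann_table <- function(...) {
  rows <- list(...)
  gene_annotation(
    gene = vapply(rows, `[[`, character(1), "gene"),
    brain_distribution = vapply(rows, `[[`, character(1),
                                "brain_distribution"),
    tissue_distribution = vapply(rows, `[[`, character(1),
                                 "tissue_distribution"),
    tissue_nx = lapply(rows, `[[`, "tissue_nx"),
    cancer_fpkm = lapply(rows, `[[`, "cancer_fpkm"),
    subcellular = lapply(rows, `[[`, "subcellular"),
    blood_detected = vapply(rows, `[[`, logical(1), "blood_detected")
  )
}

# dense cells x genes matrix -> cell_matrix (all case unless groups given)
toy_cell_matrix <- function(counts, groups = NULL, mito = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  if (is.null(groups))
    groups <- stats::setNames(rep("case", nrow(counts)), rownames(counts))
  if (is.null(mito))
    mito <- stats::setNames(rep(FALSE, ncol(counts)), colnames(counts))
  cell_matrix(Matrix::Matrix(counts, sparse = TRUE), groups, mito)
}
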