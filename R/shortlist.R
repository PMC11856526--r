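## The sequential shortlisting chain for cell-surface target candidates.
##
## Six per-gene predicates applied in order: absence from normal brain,
## absence from normal lung, restricted tissue distribution, high tumour
## expression, plasma-membrane localisation, and no shedding into blood.
## Every excluded gene is recorded with the first stage that rejected it.

#' Shortlisting filter configuration
#'
#' Defaults encode the screen for a liver-cancer surface target: genes must
#' be undetected in normal brain, at most marginally expressed in lung
#' (NX <= 1.5), not broadly expressed across tissues, highly expressed in
#' the tumour (> 50 FPKM), localised to the plasma membrane as the unique
#' top-confidence site (a tie with "extracellular" suggests a secreted
#' protein in transit and fails), and undetectable in blood by mass
#' spectrometry (a shed antigen would decoy antibody or CAR binding).
#'
#' @param brain_excluded_categories Brain distribution categories that fail
#'   the brain stage; under the default only `not_detected` passes.
#' @param lung_nx_threshold Lung NX above which a gene fails (strict `>`).
#' @param lung_tissue_key Name of the lung tissue in the NX map.
#' @param tissue_excluded_categories Tissue distribution categories that fail.
#' @param fpkm_threshold Tumour FPKM the gene must strictly exceed.
#' @param cancer_key Name of the cancer in the FPKM map.
#' @param pm_label Subcellular label for the plasma membrane.
#' @param extracellular_label Subcellular label for extracellular/secreted.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(brain_excluded_categories = c(
                            "detected_in_all", "detected_in_many",
                            "detected_in_some", "detected_in_single",
                            "unknown"),
                          lung_nx_threshold = 1.5,
                          lung_tissue_key = "lung",
                          tissue_excluded_categories = c(
                            "detected_in_all", "detected_in_many"),
                          fpkm_threshold = 50,
                          cancer_key = "liver cancer",
                          pm_label = "plasma membrane",
                          extracellular_label = "extracellular") {
  stopifnot(lung_nx_threshold >= 0, fpkm_threshold >= 0,
            all(brain_excluded_categories %in% DISTRIBUTION_CATEGORIES),
            all(tissue_excluded_categories %in% DISTRIBUTION_CATEGORIES))
  structure(
    list(brain_excluded_categories = brain_excluded_categories,
         lung_nx_threshold = lung_nx_threshold,
         lung_tissue_key = lung_tissue_key,
         tissue_excluded_categories = tissue_excluded_categories,
         fpkm_threshold = fpkm_threshold,
         cancer_key = cancer_key,
         pm_label = pm_label,
         extracellular_label = extracellular_label),
    class = "filter_config"
  )
}

## annotation accessor: one gene's row as a list
annotation_row <- function(genes, i) {
  list(gene = genes$gene[i],
       brain_distribution = genes$brain_distribution[i],
       tissue_distribution = genes$tissue_distribution[i],
       tissue_nx = genes$tissue_nx[[i]],
       cancer_fpkm = genes$cancer_fpkm[[i]],
       subcellular = genes$subcellular[[i]],
       blood_detected = genes$blood_detected[i])
}

#' Shortlisting predicates
#'
#' Each predicate takes one gene's annotation (a row of a `gene_annotation`
#' table, as a list) and the filter configuration, and returns `TRUE` if the
#' gene survives that stage:
#'
#' * `passes_brain_filter()` — brain distribution not in the excluded set;
#'   under defaults only `not_detected` passes, and `unknown` fails.
#' * `passes_lung_filter()` — lung NX at or below the threshold ("above 1.5"
#'   is read strictly, so NX exactly 1.5 passes). A gene with no lung entry
#'   is treated as NX 0 with a warning: absence of evidence does not exclude.
#' * `passes_tissue_distribution_filter()` — tissue distribution not broadly
#'   detected.
#' * `passes_hcc_expression_filter()` — tumour FPKM strictly above the
#'   threshold; a missing FPKM entry counts as 0 and fails.
#' * `passes_surface_filter()` — the plasma membrane is the unique
#'   top-confidence subcellular site: an empty annotation fails, a tie of the
#'   top confidence with the extracellular label fails (likely secreted), and
#'   any other tie at the top fails because the membrane is then not the
#'   unambiguous primary site.
#' * `passes_blood_filter()` — protein not detected in blood by mass
#'   spectrometry.
#'
#' @param g One gene's annotation as a named list (see [annotation_row]
#'   internally; `run_shortlist()` builds these for you).
#' @param c A [filter_config()].
#' @return `TRUE` or `FALSE`.
#' @name shortlist-predicates
NULL

#' @rdname shortlist-predicates
#' @export
passes_brain_filter <- function(g, c = filter_config()) {
  !(g$brain_distribution %in% c$brain_excluded_categories)
}

#' @rdname shortlist-predicates
#' @export
passes_lung_filter <- function(g, c = filter_config()) {
  nx <- g$tissue_nx
  if (!(c$lung_tissue_key %in% names(nx))) {
    warn("gene ", g$gene, ": no '", c$lung_tissue_key,
         "' NX entry; treated as 0")
    return(TRUE)
  }
  nx[[c$lung_tissue_key]] <= c$lung_nx_threshold
}

#' @rdname shortlist-predicates
#' @export
passes_tissue_distribution_filter <- function(g, c = filter_config()) {
  !(g$tissue_distribution %in% c$tissue_excluded_categories)
}

#' @rdname shortlist-predicates
#' @export
passes_hcc_expression_filter <- function(g, c = filter_config()) {
  fpkm <- g$cancer_fpkm
  val <- if (c$cancer_key %in% names(fpkm)) fpkm[[c$cancer_key]] else 0
  val > c$fpkm_threshold
}

#' @rdname shortlist-predicates
#' @export
passes_surface_filter <- function(g, c = filter_config()) {
  s <- g$subcellular
  if (nrow(s) == 0) return(FALSE)
  top_conf <- max(s$confidence)
  top_sites <- s$location[s$confidence == top_conf]
  length(top_sites) == 1 && top_sites == c$pm_label
}

#' @rdname shortlist-predicates
#' @export
passes_blood_filter <- function(g, c = filter_config()) {
  !g$blood_detected
}

#' Shortlisting stage names, in application order
#' @format Character vector of six stage names.
#' @export
SHORTLIST_STAGES <- c("brain", "lung", "tissue_distribution",
                      "tumor_fpkm", "surface", "blood")

stage_predicates <- function() {
  list(brain = passes_brain_filter,
       lung = passes_lung_filter,
       tissue_distribution = passes_tissue_distribution_filter,
       tumor_fpkm = passes_hcc_expression_filter,
       surface = passes_surface_filter,
       blood = passes_blood_filter)
}

#' Run the sequential shortlisting chain
#'
#' Applies the six stage predicates in order (brain, lung, tissue
#' distribution, tumour FPKM, surface localisation, blood detectability) and
#' records, for every gene, either survival through all stages or the first
#' stage at which it was excluded. Because each predicate is a pure per-gene
#' function, the final survivor set is the intersection of the per-stage pass
#' sets and does not depend on stage order; only the audit's intermediate
#' counts and exclusion reasons do.
#'
#' @param genes A `gene_annotation` table.
#' @param c A [filter_config()].
#' @param stages Stage names in application order; reordering is exposed for
#'   auditing purposes.
#' @return Object of class `shortlist_audit` with elements `stage_names`,
#'   `survivors_per_stage` (list of gene-symbol vectors, one per stage),
#'   `survivors` (the final set), and `exclusion_reason` (data.frame with
#'   columns `gene`, `stage`, `reason`).
#' @examples
#' ann <- simulate_annotations(n_genes = 20, seed = 1)
#' run_shortlist(ann)
#' @export
run_shortlist <- function(genes, c = filter_config(),
                          stages = SHORTLIST_STAGES) {
  stopifnot(inherits(genes, "gene_annotation"),
            all(stages %in% SHORTLIST_STAGES))
  preds <- stage_predicates()[stages]
  if (nrow(genes) == 0) {
    warn("empty annotation table: empty shortlist audit")
    return(structure(
      list(stage_names = stages,
           survivors_per_stage =
             stats::setNames(rep(list(character()), length(stages)), stages),
           survivors = character(),
           exclusion_reason = data.frame(gene = character(),
                                         stage = character(),
                                         reason = character())),
      class = "shortlist_audit"))
  }

  alive <- genes$gene
  survivors_per_stage <- stats::setNames(vector("list", length(stages)), stages)
  excl_gene <- character(); excl_stage <- character(); excl_reason <- character()
  for (s in stages) {
    pred <- preds[[s]]
    idx <- match(alive, genes$gene)
    pass <- vapply(idx, function(i) pred(annotation_row(genes, i), c),
                   logical(1))
    dropped <- alive[!pass]
    if (length(dropped)) {
      excl_gene <- c(excl_gene, dropped)
      excl_stage <- c(excl_stage, rep(s, length(dropped)))
      excl_reason <- c(excl_reason, rep(paste0("failed ", s, " filter"),
                                        length(dropped)))
    }
    alive <- alive[pass]
    survivors_per_stage[[s]] <- alive
  }
  structure(
    list(stage_names = stages,
         survivors_per_stage = survivors_per_stage,
         survivors = alive,
         exclusion_reason = data.frame(gene = excl_gene, stage = excl_stage,
                                       reason = excl_reason,
                                       stringsAsFactors = FALSE)),
    class = "shortlist_audit"
  )
}

#' @export
print.shortlist_audit <- function(x, ...) {
  n_in <- length(x$survivors) + nrow(x$exclusion_reason)
  cat(sprintf("<shortlist_audit> %d genes in -> %d survivors\n",
              n_in, length(x$survivors)))
  counts <- vapply(x$survivors_per_stage, length, integer(1))
  cat("  ", paste(c(n_in, counts), collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.shortlist_audit <- function(object, ...) {
  n_in <- length(object$survivors) + nrow(object$exclusion_reason)
  data.frame(
    stage = c("input", object$stage_names),
    survivors = c(n_in,
                  vapply(object$survivors_per_stage, length, integer(1))),
    excluded_here = c(0L, vapply(object$stage_names, function(s)
      sum(object$exclusion_reason$stage == s), integer(1))),
    row.names = NULL
  )
}

#' Write a shortlist audit to TSV files
#'
#' @param audit A `shortlist_audit`.
#' @param audit_path TSV of per-gene outcomes (gene, outcome, stage, reason).
#' @param survivors_path Optional plain-text file of surviving gene symbols,
#'   one per line.
#' @return `audit_path`, invisibly.
#' @export
write_shortlist_audit <- function(audit, audit_path, survivors_path = NULL) {
  stopifnot(inherits(audit, "shortlist_audit"))
  per_gene <- rbind(
    data.frame(gene = audit$survivors, outcome = "survivor",
               stage = "", reason = "", stringsAsFactors = FALSE),
    data.frame(gene = audit$exclusion_reason$gene, outcome = "excluded",
               stage = audit$exclusion_reason$stage,
               reason = audit$exclusion_reason$reason,
               stringsAsFactors = FALSE)
  )
  utils::write.table(per_gene, audit_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(survivors_path))
    writeLines(audit$survivors, survivors_path)
  invisible(audit_path)
}
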