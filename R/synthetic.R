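## Seed-reproducible synthetic inputs with planted ground truth for every
## pipeline stage: annotation tables whose genes pass or fail each filter by
## design, bulk datasets whose median ordering is planted, and single-cell
## count matrices with a planted correlation module around the target gene.
## Each generator is a pure function of its arguments including the seed.

#' Simulate a gene annotation table with planted filter outcomes
#'
#' Every gene's annotation fields are drawn so that each shortlisting
#' predicate evaluates exactly to its planted pass/fail label: a gene
#' labelled to fail the lung stage gets a lung NX strictly above the
#' threshold, a gene labelled to fail the surface stage gets (at random) a
#' plasma-membrane/extracellular confidence tie, a different top site, or no
#' localisation at all, and so on.
#'
#' @param n_genes Number of genes (ignored when `planted_pass_labels` is
#'   given).
#' @param seed Integer seed; the table is a pure function of the arguments.
#' @param planted_pass_labels Logical matrix, genes x 6 stages (columns
#'   `brain`, `lung`, `tissue_distribution`, `tumor_fpkm`, `surface`,
#'   `blood`), with gene symbols as row names. Defaults to independent
#'   per-stage draws at `pass_prob`.
#' @param pass_prob Per-stage pass probability for randomly drawn labels.
#' @param cfg The [filter_config()] whose thresholds the planted fields must
#'   respect.
#' @return A `gene_annotation` table with attribute `planted_labels` (the
#'   label matrix) and `planted_survivors` (genes labelled pass at all six
#'   stages).
#' @export
simulate_annotations <- function(n_genes = 1000, seed = 1,
                                 planted_pass_labels = NULL,
                                 pass_prob = 0.7,
                                 cfg = filter_config()) {
  set.seed(seed)
  if (is.null(planted_pass_labels)) {
    planted_pass_labels <- matrix(
      stats::runif(n_genes * 6) < pass_prob, nrow = n_genes,
      dimnames = list(sprintf("GENE%04d", seq_len(n_genes)),
                      SHORTLIST_STAGES))
  }
  lab <- planted_pass_labels
  if (is.null(rownames(lab)) || !is.logical(lab) || anyNA(lab) ||
      ncol(lab) != 6 || !identical(colnames(lab), SHORTLIST_STAGES))
    abort("planted_pass_labels must be a complete logical gene x stage ",
          "matrix with columns ", paste(SHORTLIST_STAGES, collapse = ", "),
          class = "surfrank_config_error")
  n <- nrow(lab)
  genes <- rownames(lab)

  brain_fail_pool <- cfg$brain_excluded_categories
  brain <- ifelse(lab[, "brain"], "not_detected",
                  sample(brain_fail_pool, n, replace = TRUE))
  tissue_pass_pool <- setdiff(DISTRIBUTION_CATEGORIES,
                              c(cfg$tissue_excluded_categories, "unknown"))
  tissue <- ifelse(lab[, "tissue_distribution"],
                   sample(tissue_pass_pool, n, replace = TRUE),
                   sample(cfg$tissue_excluded_categories, n, replace = TRUE))

  lung_nx <- ifelse(lab[, "lung"],
                    stats::runif(n, 0, cfg$lung_nx_threshold),
                    stats::runif(n, cfg$lung_nx_threshold * 1.001,
                                 cfg$lung_nx_threshold + 10))
  fpkm <- ifelse(lab[, "tumor_fpkm"],
                 stats::runif(n, cfg$fpkm_threshold * 1.001,
                              cfg$fpkm_threshold * 10),
                 stats::runif(n, 0, cfg$fpkm_threshold))

  surface_fail_mode <- sample(c("tie_extracellular", "other_top", "empty"),
                              n, replace = TRUE)
  subcellular <- lapply(seq_len(n), function(i) {
    hi <- stats::runif(1, 4, 5)
    lo <- stats::runif(1, 1, 3)
    if (lab[i, "surface"])
      return(data.frame(location = c(cfg$pm_label, "cytosol"),
                        confidence = c(hi, lo)))
    switch(surface_fail_mode[i],
      tie_extracellular = data.frame(
        location = c(cfg$pm_label, cfg$extracellular_label),
        confidence = c(hi, hi)),
      other_top = data.frame(
        location = c("nucleus", cfg$pm_label),
        confidence = c(hi, lo)),
      empty = data.frame(location = character(), confidence = numeric()))
  })

  ## decoy annotations so tables look like multi-tissue exports
  extra_nx <- stats::runif(n, 0, 30)
  extra_fpkm <- stats::runif(n, 0, 200)

  ann <- gene_annotation(
    gene = genes,
    brain_distribution = brain,
    tissue_distribution = tissue,
    tissue_nx = lapply(seq_len(n), function(i)
      c(stats::setNames(lung_nx[i], cfg$lung_tissue_key),
        liver = extra_nx[i])),
    cancer_fpkm = lapply(seq_len(n), function(i)
      c(stats::setNames(fpkm[i], cfg$cancer_key),
        "lung cancer" = extra_fpkm[i])),
    subcellular = subcellular,
    blood_detected = !lab[, "blood"]
  )
  attr(ann, "planted_labels") <- lab
  attr(ann, "planted_survivors") <- genes[rowSums(lab) == 6]
  ann
}

#' Simulate bulk expression datasets with planted median orderings
#'
#' Case-group values are drawn log-normally with per-gene log-locations
#' spaced along the planted median order, so the empirical case medians
#' reproduce that order with overwhelming probability at realistic sample
#' sizes; control samples are drawn at a uniformly lower location,
#' emulating tumour-over-normal overexpression. With `noise_sd = 0` every
#' sample equals its gene's location parameter exactly.
#'
#' @param genes Gene symbols.
#' @param seed Integer seed.
#' @param datasets List of per-dataset specs, each a list with
#'   `dataset_id`, `modality`, `n_case`, `n_control`, and optionally
#'   `median_order` (gene symbols, ascending target median; default a
#'   seeded random permutation) and `noise_sd`. The default emulates the
#'   shapes of three transcript cohorts (366, 35 and 225 cases) and one
#'   protein cohort (165 cases).
#' @param noise_sd Log-scale noise SD used where a dataset does not set its
#'   own (default 0.25).
#' @param spacing Log-scale gap between adjacent genes in the planted order
#'   (default 0.5).
#' @param control_shift Log-scale amount by which control samples sit below
#'   cases (default 1).
#' @return List with elements `transcript` and `protein` (lists of
#'   [expression_dataset()]), and attribute `planted_orders` (named list of
#'   each dataset's ascending median order).
#' @export
simulate_bulk <- function(genes, seed = 1, datasets = NULL,
                          noise_sd = 0.25, spacing = 0.5,
                          control_shift = 1) {
  set.seed(seed)
  if (is.null(datasets)) {
    datasets <- list(
      list(dataset_id = "T1", modality = "transcript",
           n_case = 366, n_control = 50),
      list(dataset_id = "T2", modality = "transcript",
           n_case = 35, n_control = 35),
      list(dataset_id = "T3", modality = "transcript",
           n_case = 225, n_control = 220),
      list(dataset_id = "P1", modality = "protein",
           n_case = 165, n_control = 165)
    )
  }
  out <- list(transcript = list(), protein = list())
  orders <- list()
  for (spec in datasets) {
    ord <- spec$median_order %||% sample(genes)
    sdv <- spec$noise_sd %||% noise_sd
    mu <- stats::setNames(log(50) + (match(genes, ord) - 1) * spacing, genes)
    n_case <- spec$n_case; n_ctrl <- spec$n_control
    draw <- function(n, loc) {
      if (sdv == 0) rep(exp(loc), n) else stats::rlnorm(n, loc, sdv)
    }
    vals <- rbind(
      vapply(genes, function(g) draw(n_case, mu[[g]]), numeric(n_case)),
      vapply(genes, function(g) draw(n_ctrl, mu[[g]] - control_shift),
             numeric(n_ctrl))
    )
    samples <- c(sprintf("%s_case_%03d", spec$dataset_id, seq_len(n_case)),
                 sprintf("%s_ctrl_%03d", spec$dataset_id, seq_len(n_ctrl)))
    rownames(vals) <- samples
    d <- expression_dataset(
      vals,
      stats::setNames(rep(c("case", "control"), c(n_case, n_ctrl)), samples),
      spec$dataset_id, spec$modality)
    out[[spec$modality]] <- c(out[[spec$modality]], list(d))
    orders[[spec$dataset_id]] <- ord
  }
  attr(out, "planted_orders") <- orders
  out
}

## empirical correlation between two NB genes sharing a latent factor with
## loadings beta_a / beta_b, measured on log-normalized pilot counts among
## cells where gene A (the target) is detected -- the same restriction and
## transform the pipeline applies. The rest of the transcriptome enters as
## a Poisson background so library-size normalization is mimicked.
latent_pair_r <- function(beta_a, beta_b, lambda_a, lambda_b, size,
                          background_mean, scale = 10000, n = 2000) {
  f <- stats::rnorm(n)
  ca <- stats::rnbinom(n, size = size,
                       mu = lambda_a * exp(beta_a * f - beta_a^2 / 2))
  cb <- stats::rnbinom(n, size = size,
                       mu = lambda_b * exp(beta_b * f - beta_b^2 / 2))
  totals <- ca + cb + stats::rpois(n, background_mean)
  keep <- ca > 0
  if (sum(keep) < 30 || stats::sd(cb[keep]) == 0) return(NA_real_)
  stats::cor(log1p(ca[keep] * scale / totals[keep]),
             log1p(cb[keep] * scale / totals[keep]))
}

## binary search for the loading that achieves the requested correlation;
## calibrated empirically (the NB + normalization + log1p chain has no
## convenient closed form). With fix_a = NULL both loadings move together.
calibrate_loading <- function(rho, lambda_a, lambda_b, size,
                              background_mean, fix_a = NULL, iters = 12) {
  lo <- 0.05; hi <- 4
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    r <- latent_pair_r(fix_a %||% mid, mid, lambda_a, lambda_b, size,
                       background_mean)
    if (is.na(r) || r < rho) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a single-cell count matrix with a planted correlation module
#'
#' Counts follow a negative-binomial observation model on per-gene baseline
#' means. In case cells, the target gene and the planted module genes share
#' a per-cell latent factor whose loading is calibrated empirically (by
#' binary search on small pilot simulations) so that the Pearson
#' correlation between the target and each module gene, measured on
#' log1p counts among target-expressing cells, is approximately
#' `module_rho`. Control cells have no shared factor, so module genes are
#' uncorrelated with the target there. A configurable fraction of case
#' cells is forced to zero target count to exercise the zero-target
#' exclusion rule, and a `mito_fraction` of genes carries the `MT-` prefix
#' and the mitochondrial flag.
#'
#' Optionally a single extra gene (`SHAREDBOTH`) is planted that correlates
#' with the target in *both* groups at specified levels, to exercise the
#' overlap-resolution rule that assigns such genes to the group with the
#' higher correlation.
#'
#' @param seed Integer seed.
#' @param n_genes Size of the gene universe (module genes and target
#'   included).
#' @param n_case_cells,n_control_cells Cells per group.
#' @param n_module_genes Number of planted module genes.
#' @param module_rho Target correlation between the target gene and each
#'   module gene in case cells, in (0, 1).
#' @param target Target gene symbol.
#' @param baseline_mean Median of the per-gene baseline NB means.
#' @param dispersion NB size parameter (smaller = more overdispersed).
#' @param mito_fraction Fraction of genes flagged mitochondrial.
#' @param zero_target_fraction Fraction of case cells forced to zero target
#'   count.
#' @param shared_gene_rho Optional numeric `c(case = ..., control = ...)`;
#'   when given, plants the `SHAREDBOTH` gene at those correlations.
#' @return A `cell_matrix` with attributes `module_genes`, `target`,
#'   `zero_target_cells` and (if planted) `shared_gene`.
#' @export
simulate_single_cell <- function(seed = 1, n_genes = 1000,
                                 n_case_cells = 2000, n_control_cells = 1000,
                                 n_module_genes = 20, module_rho = 0.8,
                                 target = "TARGET1",
                                 baseline_mean = 2, dispersion = 2,
                                 mito_fraction = 0.05,
                                 zero_target_fraction = 0.1,
                                 shared_gene_rho = NULL) {
  stopifnot(module_rho >= 0, module_rho < 1,
            n_module_genes + 2 < n_genes)
  set.seed(seed)
  n_mito <- max(1L, round(n_genes * mito_fraction))
  plain <- sprintf("G%04d", seq_len(n_genes - n_mito - 1 -
                                      as.integer(!is.null(shared_gene_rho))))
  mito_genes <- sprintf("MT-%02d", seq_len(n_mito))
  genes <- c(target, if (!is.null(shared_gene_rho)) "SHAREDBOTH",
             plain, mito_genes)
  module_genes <- plain[seq_len(n_module_genes)]

  lambda <- stats::setNames(
    stats::rlnorm(length(genes), log(baseline_mean), 0.5), genes)
  lambda[target] <- max(lambda[target], 5)  # target detected in most cells
  lambda[mito_genes] <- lambda[mito_genes] * 2

  bg <- sum(lambda) - lambda[[target]] - lambda[[module_genes[1]]]
  beta <- if (module_rho > 0)
    calibrate_loading(module_rho, lambda[[target]],
                      lambda[[module_genes[1]]], dispersion, bg)
  else 0

  n_cells <- n_case_cells + n_control_cells
  cells <- c(sprintf("case_%04d", seq_len(n_case_cells)),
             sprintf("ctrl_%04d", seq_len(n_control_cells)))
  groups <- stats::setNames(rep(c("case", "control"),
                                c(n_case_cells, n_control_cells)), cells)

  counts <- matrix(0L, n_cells, length(genes), dimnames = list(cells, genes))
  f_case <- stats::rnorm(n_case_cells)
  loaded <- c(target, module_genes)
  for (g in genes) {
    mu <- rep(lambda[[g]], n_cells)
    if (beta > 0 && g %in% loaded)
      mu[seq_len(n_case_cells)] <-
        lambda[[g]] * exp(beta * f_case - beta^2 / 2)
    counts[, g] <- stats::rnbinom(n_cells, size = dispersion, mu = mu)
  }

  if (!is.null(shared_gene_rho)) {
    ## case side: loading on the case factor, calibrated with the target's
    ## loading held fixed; control side: its own factor shared with the
    ## target's control counts
    g_case <- calibrate_loading(shared_gene_rho[["case"]],
                                lambda[[target]], lambda[["SHAREDBOTH"]],
                                dispersion, bg, fix_a = beta)
    counts[seq_len(n_case_cells), "SHAREDBOTH"] <-
      stats::rnbinom(n_case_cells, size = dispersion,
                     mu = lambda[["SHAREDBOTH"]] *
                       exp(g_case * f_case - g_case^2 / 2))
    g_ctrl <- calibrate_loading(shared_gene_rho[["control"]],
                                lambda[[target]], lambda[["SHAREDBOTH"]],
                                dispersion, bg)
    h <- stats::rnorm(n_control_cells)
    ctrl_idx <- n_case_cells + seq_len(n_control_cells)
    counts[ctrl_idx, target] <-
      stats::rnbinom(n_control_cells, size = dispersion,
                     mu = lambda[[target]] * exp(g_ctrl * h - g_ctrl^2 / 2))
    counts[ctrl_idx, "SHAREDBOTH"] <-
      stats::rnbinom(n_control_cells, size = dispersion,
                     mu = lambda[["SHAREDBOTH"]] *
                       exp(g_ctrl * h - g_ctrl^2 / 2))
  }

  zero_cells <- sample(cells[seq_len(n_case_cells)],
                       round(n_case_cells * zero_target_fraction))
  counts[zero_cells, target] <- 0L

  m <- cell_matrix(
    Matrix::Matrix(counts, sparse = TRUE), groups,
    stats::setNames(genes %in% mito_genes, genes))
  attr(m, "module_genes") <- module_genes
  attr(m, "target") <- target
  attr(m, "zero_target_cells") <- zero_cells
  if (!is.null(shared_gene_rho)) attr(m, "shared_gene") <- "SHAREDBOTH"
  m
}
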