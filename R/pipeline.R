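## End-to-end orchestration: shortlist -> rank -> correlate, driven by one
## YAML config, with provenance sufficient to re-run deterministically.

REPORT_SCHEMA_VERSION <- 1L

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    abort("pipeline stage '", stage, "' failed: ", conditionMessage(e),
          class = "surfrank_pipeline_error"))
}

#' Run the full target-discovery pipeline
#'
#' Executes the stages in workflow order — shortlist the annotation table,
#' rank the surviving candidates across the bulk datasets, and (optionally)
#' extract the single-cell correlation modules around the top-ranked gene —
#' and collects the results with provenance (config snapshot, seed, input
#' checksums). Any stage failure aborts with the stage named.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognised top-level keys:
#' \describe{
#'   \item{`seed`}{root seed for all randomness (default 1).}
#'   \item{`annotations`}{path to an annotation TSV, or a list
#'     `list(simulate = TRUE, n_genes = ...)` to generate one.}
#'   \item{`filter`, `ranking`, `qc`}{argument lists for [filter_config()],
#'     [ranking_config()] and [qc_config()].}
#'   \item{`bulk`}{`list(transcript = list(<path or spec>, ...), protein =
#'     list(...))`, each entry either a TSV path or a named list with
#'     `path`, `dataset_id`; or `list(simulate = TRUE)`.}
#'   \item{`single_cell`}{optional: `list(mtx = , cells = , genes = ,
#'     target = , cutoff = )` or `list(simulate = TRUE, ...)`. `target`
#'     defaults to the top-ranked gene.}
#'   \item{`output_dir`}{optional directory for TSV/JSON reports.}
#' }
#' @return Object of class `pipeline_report` with elements `audit`
#'   (`shortlist_audit`), `rank_table`, `correlation` (or `NULL`),
#'   `candidate_target` (the top-ranked gene) and `provenance`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- cfg$seed %||% 1
  fc <- do.call(filter_config, cfg$filter %||% list())
  rc <- do.call(ranking_config, cfg$ranking %||% list())
  qc <- do.call(qc_config, cfg$qc %||% list())
  input_files <- character()

  ann <- stage_try("shortlist", {
    a <- cfg$annotations
    if (is.list(a) && isTRUE(a$simulate)) {
      do.call(simulate_annotations,
              c(list(seed = seed, cfg = fc),
                a[setdiff(names(a), "simulate")]))
    } else {
      input_files <- c(input_files, a)
      read_annotation_table(a)
    }
  })
  audit <- stage_try("shortlist", run_shortlist(ann, fc))
  survivors <- audit$survivors
  if (length(survivors) == 0)
    abort("pipeline stage 'shortlist' left no surviving genes",
          class = "surfrank_pipeline_error")

  load_bulk <- function(entries, modality) {
    lapply(entries, function(e) {
      if (is.character(e)) e <- list(path = e)
      input_files <<- c(input_files, e$path)
      read_expression_dataset(e$path, e$dataset_id, modality)
    })
  }
  rank_table <- stage_try("rank", {
    b <- cfg$bulk
    if (is.list(b) && isTRUE(b$simulate)) {
      sim <- do.call(simulate_bulk,
                     c(list(genes = survivors, seed = seed),
                       b[setdiff(names(b), "simulate")]))
      rank_targets(sim$transcript, sim$protein, survivors, rc)
    } else {
      rank_targets(load_bulk(b$transcript %||% list(), "transcript"),
                   load_bulk(b$protein %||% list(), "protein"),
                   survivors, rc)
    }
  })
  candidate <- rank_table$genes[1]

  correlation <- NULL
  if (!is.null(cfg$single_cell)) {
    correlation <- stage_try("correlate", {
      sc <- cfg$single_cell
      target <- sc$target %||% candidate
      m <- if (isTRUE(sc$simulate)) {
        do.call(simulate_single_cell,
                c(list(seed = seed, target = target),
                  sc[setdiff(names(sc), c("simulate", "target", "cutoff"))]))
      } else {
        input_files <- c(input_files, sc$mtx, sc$cells, sc$genes)
        read_cell_matrix(sc$mtx, sc$cells, sc$genes)
      }
      correlate_target(m, target, cutoff = sc$cutoff %||% 0.6, qc = qc)
    })
  }

  report <- structure(
    list(audit = audit, rank_table = rank_table, correlation = correlation,
         candidate_target = candidate,
         provenance = list(
           schema_version = REPORT_SCHEMA_VERSION,
           package_version = as.character(utils::packageVersion("surfrank")),
           seed = seed,
           config = cfg,
           filter_config = unclass(fc),
           ranking_config = unclass(rc),
           qc_config = unclass(qc),
           input_checksums = if (length(input_files))
             as.list(tools::md5sum(input_files)) else list())),
    class = "pipeline_report"
  )
  if (!is.null(cfg$output_dir)) write_pipeline_report(report, cfg$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  candidate target: %s\n", x$candidate_target))
  print(x$audit)
  print(x$rank_table)
  if (!is.null(x$correlation)) print(x$correlation)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `shortlist_audit.tsv`, `survivors.txt`, `rank_table.tsv`,
#' `modules.tsv` (when the correlation stage ran) and `report.json`
#' (summary plus provenance). Outputs are deterministic given the same
#' config and inputs.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_shortlist_audit(report$audit, file.path(dir, "shortlist_audit.tsv"),
                        file.path(dir, "survivors.txt"))
  write_rank_table(report$rank_table, file.path(dir, "rank_table.tsv"))
  if (!is.null(report$correlation))
    write_correlation_result(report$correlation, file.path(dir, "modules.tsv"))
  summary_json <- list(
    schema_version = report$provenance$schema_version,
    candidate_target = report$candidate_target,
    shortlist_counts = vapply(report$audit$survivors_per_stage, length,
                              integer(1)),
    top_scores = stats::setNames(
      as.numeric(report$rank_table$xbar_TP[report$rank_table$genes]),
      report$rank_table$genes),
    modules = if (!is.null(report$correlation)) list(
      case = report$correlation$module_case,
      control = report$correlation$module_control) else NULL,
    provenance = report$provenance[c("package_version", "seed",
                                     "filter_config", "ranking_config",
                                     "qc_config", "input_checksums")]
  )
  jsonlite::write_json(summary_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
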