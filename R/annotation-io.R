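## Gene annotation tables: the data model behind the shortlisting chain.
##
## A `gene_annotation` table is a base data.frame, one row per gene, with
## list-columns for the per-tissue NX map, the per-cancer FPKM map and the
## ranked subcellular localisation, mirroring what a Human Protein Atlas
## export carries for each gene.

#' Recognised expression-distribution categories
#'
#' The controlled vocabulary used by the brain and tissue distribution
#' annotations. Any string that does not normalise to one of the first five
#' values is mapped to `"unknown"`.
#'
#' @format Character vector of six category names.
#' @export
DISTRIBUTION_CATEGORIES <- c(
  "detected_in_all", "detected_in_many", "detected_in_some",
  "detected_in_single", "not_detected", "unknown"
)

#' Normalise a distribution category string
#'
#' Trims whitespace, lower-cases and converts separators so that e.g.
#' `"Detected in all"` becomes `"detected_in_all"`. Anything that does not
#' match the controlled vocabulary (including `NA` and the empty string)
#' becomes `"unknown"`.
#'
#' @param x Character vector of raw category strings.
#' @return Character vector of canonical categories.
#' @export
normalize_category <- function(x) {
  y <- tolower(trimws(as.character(x)))
  y <- gsub("[ \\-]+", "_", y)
  y[!(y %in% DISTRIBUTION_CATEGORIES)] <- "unknown"
  y[is.na(x)] <- "unknown"
  y
}

#' Construct a gene annotation table
#'
#' @param gene Character vector of unique gene symbols.
#' @param brain_distribution,tissue_distribution Character vectors of
#'   distribution categories (normalised via [normalize_category()]).
#' @param tissue_nx List of named non-negative numeric vectors, one per gene:
#'   tissue name -> consensus normalized expression (NX).
#' @param cancer_fpkm List of named non-negative numeric vectors, one per
#'   gene: cancer type -> FPKM.
#' @param subcellular List of data.frames with columns `location` and
#'   `confidence`, each sorted by non-increasing confidence. An empty (0-row)
#'   data.frame means the gene has no localisation annotation.
#' @param blood_detected Logical vector: was the encoded protein detected in
#'   blood by mass spectrometry.
#' @return A data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene, brain_distribution, tissue_distribution,
                            tissue_nx, cancer_fpkm, subcellular,
                            blood_detected) {
  n <- length(gene)
  stopifnot(
    length(brain_distribution) == n, length(tissue_distribution) == n,
    length(tissue_nx) == n, length(cancer_fpkm) == n,
    length(subcellular) == n, length(blood_detected) == n
  )
  if (anyDuplicated(gene))
    abort("duplicate gene symbol(s): ",
          paste(unique(gene[duplicated(gene)]), collapse = ", "),
          class = "surfrank_validation_error")
  bad_nx <- vapply(tissue_nx, function(v) any(v < 0, na.rm = TRUE), logical(1))
  bad_fp <- vapply(cancer_fpkm, function(v) any(v < 0, na.rm = TRUE), logical(1))
  if (any(bad_nx) || any(bad_fp))
    abort("negative NX or FPKM values are not allowed",
          class = "surfrank_validation_error")
  subcellular <- lapply(subcellular, function(s) {
    s <- as.data.frame(s)
    if (nrow(s) == 0)
      return(data.frame(location = character(), confidence = numeric()))
    s[order(-s$confidence), c("location", "confidence"), drop = FALSE]
  })
  out <- data.frame(
    gene = as.character(gene),
    brain_distribution = normalize_category(brain_distribution),
    tissue_distribution = normalize_category(tissue_distribution),
    blood_detected = as.logical(blood_detected),
    stringsAsFactors = FALSE
  )
  out$tissue_nx <- tissue_nx
  out$cancer_fpkm <- cancer_fpkm
  out$subcellular <- subcellular
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes\n", nrow(x)))
  tissues <- unique(unlist(lapply(x$tissue_nx, names)))
  cancers <- unique(unlist(lapply(x$cancer_fpkm, names)))
  cat(sprintf("  NX tissues: %s\n",
              paste(utils::head(tissues, 6), collapse = ", ")))
  cat(sprintf("  FPKM cancers: %s\n",
              paste(utils::head(cancers, 6), collapse = ", ")))
  invisible(x)
}

## ---- header aliasing ------------------------------------------------------

#' Default header aliases for annotation TSVs
#'
#' Maps recognised column headers (including Human Protein Atlas export
#' headers such as `"RNA brain regional distribution"` or
#' `"Tissue RNA - lung [NX]"`) onto the package's canonical column names.
#' Users can extend the mapping by passing additional `alias = canonical`
#' pairs to [read_annotation_table()].
#'
#' Canonical names: `gene`, `brain_distribution`, `tissue_distribution`,
#' `blood_detected`, `subcellular`, `nx_<tissue>` and `fpkm_<cancer>`.
#'
#' @return Named character vector `c(alias = canonical)`.
#' @export
default_header_aliases <- function() {
  c(
    "Gene"                            = "gene",
    "RNA brain regional distribution" = "brain_distribution",
    "RNA tissue distribution"         = "tissue_distribution",
    "Blood detected by MS"            = "blood_detected",
    "Subcellular location"            = "subcellular"
  )
}

## "Tissue RNA - lung [NX]" -> "nx_lung"; "RNA cancer specific FPKM - liver
## cancer" -> "fpkm_liver cancer"; otherwise the alias table or the header
## itself (lower-cased) is used.
normalize_header <- function(h, aliases) {
  h0 <- trimws(h)
  if (h0 %in% names(aliases)) return(unname(aliases[h0]))
  m <- regmatches(h0, regexec("^Tissue RNA - (.+) \\[NX\\]$", h0))[[1]]
  if (length(m) == 2) return(paste0("nx_", m[2]))
  m <- regmatches(h0, regexec("^RNA cancer specific FPKM - (.+)$", h0))[[1]]
  if (length(m) == 2) return(paste0("fpkm_", m[2]))
  tolower(h0)
}

## ---- subcellular encoding -------------------------------------------------

## "plasma membrane:5;cytosol:3" <-> data.frame(location, confidence)
encode_subcellular <- function(s) {
  if (nrow(s) == 0) return("")
  paste(sprintf("%s:%s", s$location, num_to_chr(s$confidence)), collapse = ";")
}

decode_subcellular <- function(txt) {
  txt <- trimws(txt %||% "")
  if (is.na(txt) || txt == "")
    return(data.frame(location = character(), confidence = numeric()))
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  loc <- sub(":[^:]*$", "", parts)
  conf <- as.numeric(sub("^.*:", "", parts))
  data.frame(location = trimws(loc), confidence = conf)
}

## ---- reader / writer ------------------------------------------------------

#' Read a gene annotation table from TSV
#'
#' One row per gene. Headers are mapped to canonical names through the alias
#' table, so both the package's own dialect and HPA-style exports load
#' without editing. `nx_*` and `fpkm_*` columns are gathered into the
#' per-gene NX and FPKM maps. Rows with a missing gene symbol are rejected
#' (counted in the `rejects` attribute), never silently dropped.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param aliases Extra header aliases, `c("My Header" = "canonical")`,
#'   consulted before the defaults.
#' @return A `gene_annotation` table with attribute `rejects` (number of
#'   rejected rows).
#' @seealso [write_annotation_table()], [default_header_aliases()]
#' @export
read_annotation_table <- function(path, aliases = character()) {
  if (!file.exists(path)) abort("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = character())
  alias_tab <- c(aliases, default_header_aliases())
  names(raw) <- vapply(names(raw), normalize_header, character(1),
                       aliases = alias_tab)
  required <- c("gene", "brain_distribution", "tissue_distribution",
                "blood_detected")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    abort("annotation table is missing required column(s): ",
          paste(missing_cols, collapse = ", "),
          class = "surfrank_format_error")

  keep <- !is.na(raw$gene) & trimws(raw$gene) != ""
  rejects <- sum(!keep)
  if (rejects > 0)
    warn(rejects, " row(s) without a gene symbol rejected")
  raw <- raw[keep, , drop = FALSE]
  if (anyDuplicated(raw$gene))
    abort("duplicate gene symbol(s): ",
          paste(unique(raw$gene[duplicated(raw$gene)]), collapse = ", "),
          class = "surfrank_validation_error")

  nx_cols <- grep("^nx_", names(raw), value = TRUE)
  fpkm_cols <- grep("^fpkm_", names(raw), value = TRUE)
  parse_map <- function(row_vals, keys) {
    v <- suppressWarnings(as.numeric(row_vals))
    names(v) <- keys
    v[!is.na(v)]
  }
  n <- nrow(raw)
  tissue_nx <- lapply(seq_len(n), function(i)
    parse_map(unlist(raw[i, nx_cols]), sub("^nx_", "", nx_cols)))
  cancer_fpkm <- lapply(seq_len(n), function(i)
    parse_map(unlist(raw[i, fpkm_cols]), sub("^fpkm_", "", fpkm_cols)))
  subcellular <- lapply(
    if (n > 0 && "subcellular" %in% names(raw)) raw$subcellular
    else rep("", n),
    decode_subcellular
  )
  out <- gene_annotation(
    gene = raw$gene,
    brain_distribution = raw$brain_distribution,
    tissue_distribution = raw$tissue_distribution,
    tissue_nx = tissue_nx,
    cancer_fpkm = cancer_fpkm,
    subcellular = subcellular,
    blood_detected = tolower(trimws(raw$blood_detected)) %in%
      c("true", "t", "yes", "1")
  )
  attr(out, "rejects") <- rejects
  out
}

#' Write a gene annotation table to TSV
#'
#' Emits the package's canonical dialect (`gene`, `brain_distribution`,
#' `tissue_distribution`, `blood_detected`, `nx_<tissue>`, `fpkm_<cancer>`,
#' `subcellular`), which [read_annotation_table()] reads back field-for-field.
#' Numeric values are written at full precision so round trips are exact.
#'
#' @param x A `gene_annotation` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(x, path) {
  stopifnot(inherits(x, "gene_annotation"))
  tissues <- unique(unlist(lapply(x$tissue_nx, names)))
  cancers <- unique(unlist(lapply(x$cancer_fpkm, names)))
  flat <- data.frame(
    gene = x$gene,
    brain_distribution = x$brain_distribution,
    tissue_distribution = x$tissue_distribution,
    blood_detected = ifelse(x$blood_detected, "true", "false"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (t in tissues)
    flat[[paste0("nx_", t)]] <-
      vapply(x$tissue_nx, function(v)
        if (t %in% names(v)) num_to_chr(v[[t]]) else "", character(1))
  for (cc in cancers)
    flat[[paste0("fpkm_", cc)]] <-
      vapply(x$cancer_fpkm, function(v)
        if (cc %in% names(v)) num_to_chr(v[[cc]]) else "", character(1))
  flat$subcellular <- vapply(x$subcellular, encode_subcellular, character(1))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
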