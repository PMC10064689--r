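# Core data containers. Plain S3 wrappers around base matrices/data.frames:
# the package follows the vegan/edgeR style of matrix-in, data.frame-out.

#' Construct a taxa count table
#'
#' The substrate of all microbiome stages: an integer sample x taxon count
#' matrix tagged with the anatomical site it was sampled from.
#'
#' @param counts Integer matrix, samples as rows, taxa as columns, with
#'   unique row (sample) and column (taxon) names.
#' @param site Either `"luminal"` or `"tissue"`.
#' @return An object of class `taxa_table` with elements `counts` and `site`.
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 20L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("Gardnerella", "Prevotella")))
#' taxa_table(m, "luminal")
#' @export
taxa_table <- function(counts, site = c("luminal", "tissue")) {
  site <- match.arg(site)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    ct_format_error("`counts` must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    ct_format_error("`counts` must have sample row names and taxon column names")
  }
  if (anyDuplicated(rownames(counts))) {
    ct_format_error("duplicate sample identifiers in taxa table")
  }
  if (anyDuplicated(colnames(counts))) {
    ct_format_error("duplicate taxon identifiers in taxa table")
  }
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    ct_format_error("empty taxa table")
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    ct_format_error(sprintf(
      "counts must be non-negative integers; offending cell sample '%s', taxon '%s' (value %s)",
      rownames(counts)[i[1L]], colnames(counts)[i[2L]], format(counts[bad[1L]])))
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, site = site), class = "taxa_table")
}

#' @export
print.taxa_table <- function(x, ...) {
  cat(sprintf("taxa_table: %d samples x %d taxa, site = %s\n",
              nrow(x$counts), ncol(x$counts), x$site))
  invisible(x)
}

#' @export
dim.taxa_table <- function(x) dim(x$counts)

#' Per-sample sequencing depths of a taxa table
#' @param table A [taxa_table()].
#' @return Named numeric vector of per-sample total counts.
#' @export
sample_depths <- function(table) {
  stopifnot(inherits(table, "taxa_table"))
  rowSums(table$counts)
}

#' Construct a sample metadata table
#'
#' @param df Data frame with one row per sample; must contain a `sample`
#'   column and may contain `nugent` (one of `"negative"`, `"intermediate"`,
#'   `"positive"`, `"missing"`), `hiv` and `dmpa` logicals, plus arbitrary
#'   continuous covariates.
#' @return A `sample_metadata` data frame.
#' @export
sample_metadata <- function(df) {
  if (!is.data.frame(df) || !"sample" %in% names(df)) {
    ct_format_error("metadata must be a data frame with a `sample` column")
  }
  if (anyDuplicated(df$sample)) ct_format_error("duplicate sample identifiers in metadata")
  if ("nugent" %in% names(df)) {
    allowed <- c("negative", "intermediate", "positive", "missing")
    bad <- setdiff(unique(as.character(df$nugent)), allowed)
    if (length(bad)) {
      ct_format_error(sprintf("invalid Nugent category '%s' (allowed: %s)",
                              bad[1L], paste(allowed, collapse = ", ")))
    }
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Construct an expression count/value matrix
#'
#' @param values Numeric gene x sample matrix (transcriptomics convention:
#'   genes as rows) with unique gene and sample names.
#' @param normalized Logical flag: `FALSE` for raw counts (default), `TRUE`
#'   for already-normalized values.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    ct_format_error("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    ct_format_error("expression matrix must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) ct_format_error("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) ct_format_error("duplicate sample identifiers")
  if (any(!is.finite(values)) || any(values < 0)) {
    ct_format_error("expression values must be finite and non-negative")
  }
  structure(list(values = values, normalized = isTRUE(normalized)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "counts"))
  invisible(x)
}

#' Construct a gene-set library
#'
#' @param sets Named list of character vectors (GO-, KEGG-, or TF-PPI-style
#'   gene sets). Members are deduplicated; empty sets and duplicate set
#'   names are rejected.
#' @return A `gene_set_library` (named list).
#' @export
gene_set_library <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    ct_format_error("gene-set library must be a named list")
  }
  if (anyDuplicated(names(sets))) ct_format_error("duplicate gene-set names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) ct_format_error("gene sets must be nonempty")
  structure(sets, class = c("gene_set_library", "list"))
}

#' Construct a protein level table
#'
#' @param values Numeric analyte x sample matrix of log10-normalized
#'   intensities.
#' @return A `protein_table` object.
#' @export
protein_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values) ||
      is.null(rownames(values)) || is.null(colnames(values))) {
    ct_format_error("protein table must be a named numeric analyte x sample matrix")
  }
  structure(list(values = values), class = "protein_table")
}

#' Construct a cytokine level table with LOD censoring
#'
#' @param values Numeric analyte x sample matrix of concentrations (pg/mL).
#' @param lod Named numeric vector of per-analyte limits of detection
#'   (pg/mL, > 0).
#' @param censored Logical matrix of the same shape flagging entries below
#'   the LOD.
#' @return A `cytokine_table` object.
#' @export
cytokine_table <- function(values, lod, censored) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values))) {
    ct_format_error("cytokine table must be a named analyte x sample matrix")
  }
  if (any(values < 0, na.rm = TRUE)) ct_format_error("negative cytokine concentrations")
  if (!all(rownames(values) %in% names(lod))) {
    ct_format_error("every cytokine needs a limit of detection")
  }
  if (any(lod <= 0)) ct_format_error("LOD must be > 0")
  if (!is.matrix(censored) || !identical(dim(censored), dim(values))) {
    ct_format_error("censoring flags must match the value matrix")
  }
  structure(list(values = values, lod = lod[rownames(values)],
                 censored = censored),
            class = "cytokine_table")
}
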