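# Readers and writers for every on-disk format the pipeline touches.
# Canonical orientations: taxa tables are samples-as-rows; expression is
# genes-as-rows. All TSVs are UTF-8, tab-separated, '.' decimal. Writers are
# bit-deterministic given fixed inputs; every reader validates strictly and
# raises a typed format error naming the offending cell, never coercing.

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) ct_format_error(sprintf("empty table in '%s'", path))
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Read a taxa count table (TSV or BIOM)
#'
#' TSV dialect: header row of taxon names, first column sample identifiers,
#' integer counts. A path ending in `.biom` is read with the biomformat
#' package (sample x taxon orientation is taken from the BIOM observation/
#' sample axes and transposed to samples-as-rows).
#'
#' @param path File path.
#' @param site `"luminal"` or `"tissue"` tag to attach.
#' @return A validated [taxa_table()]. Fractional or negative entries are
#'   rejected with the offending cell named.
#' @export
read_taxa_table <- function(path, site = c("luminal", "tissue")) {
  site <- match.arg(site)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      ct_input_error("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))  # observations x samples -> samples x taxa
  } else {
    m <- read_tsv_matrix(path)
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m))
      i <- if (length(bad)) arrayInd(bad[1L], dim(m)) else c(1L, 1L)
      ct_format_error(sprintf("non-numeric count at sample '%s', taxon '%s'",
                              rownames(m)[i[1L]], colnames(m)[i[2L]]))
    }
  }
  taxa_table(m, site)
}

#' Write a taxa count table as TSV (samples as rows)
#' @param table A [taxa_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxa_table <- function(table, path) {
  stopifnot(inherits(table, "taxa_table"))
  df <- data.frame(sample = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' Standard GMT dialect: one set per line, fields `name`, `description`,
#' then members, tab-separated. Members are deduplicated per set.
#'
#' @param path GMT file path.
#' @return A [gene_set_library()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) ct_format_error(sprintf("empty GMT file '%s'", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    ct_format_error(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_library(sets)
}

#' Write a gene-set library in GMT format
#' @param library A [gene_set_library()].
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path, descriptions = names(library)) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(seq_along(library), function(i) {
    paste(c(names(library)[i], descriptions[i], library[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene x sample expression matrix from TSV
#' @param path TSV with gene identifiers in the first column, sample names
#'   in the header.
#' @param normalized Whether values are normalized rather than raw counts;
#'   never guessed from the data.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, normalized = FALSE) {
  m <- read_tsv_matrix(path)
  if (!is.numeric(m)) ct_format_error("non-numeric expression values")
  expression_matrix(m, normalized = normalized)
}

#' Write an expression matrix as TSV (genes as rows)
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene = rownames(expr$values), expr$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata TSV
#' @param path TSV with a `sample` column; a `nugent` column, if present, is
#'   validated against the negative/intermediate/positive/missing enumeration.
#' @return A [sample_metadata()] data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Write a sample metadata table as TSV
#' @param meta A [sample_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein table (analyte x sample TSV of log10 intensities)
#' @param path TSV path, analytes in the first column.
#' @return A [protein_table()].
#' @export
read_protein_table <- function(path) {
  m <- read_tsv_matrix(path)
  if (!is.numeric(m)) ct_format_error("non-numeric protein values")
  protein_table(m)
}

#' Write a protein table as TSV
#' @param proteins A [protein_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(proteins, path) {
  df <- data.frame(protein = rownames(proteins$values), proteins$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cytokine table with per-analyte LOD and censoring flags
#'
#' Long TSV with columns `cytokine`, `sample`, `value` (pg/mL), `lod`
#' (pg/mL) and logical `censored`.
#'
#' @param path TSV path.
#' @return A [cytokine_table()].
#' @export
read_cytokine_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cytokine", "sample", "value", "lod", "censored")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    ct_format_error(sprintf("cytokine table missing column(s): %s",
                            paste(miss, collapse = ", ")))
  }
  cyt <- unique(df$cytokine); smp <- unique(df$sample)
  values <- matrix(NA_real_, length(cyt), length(smp), dimnames = list(cyt, smp))
  censored <- matrix(FALSE, length(cyt), length(smp), dimnames = list(cyt, smp))
  values[cbind(df$cytokine, df$sample)] <- df$value
  censored[cbind(df$cytokine, df$sample)] <- as.logical(df$censored)
  lod <- stats::setNames(
    as.numeric(tapply(df$lod, df$cytokine, function(x) x[1L])[cyt]), cyt)
  cytokine_table(values, lod, censored)
}

#' Write a cytokine table as long TSV
#' @param cytokines A [cytokine_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytokine_table <- function(cytokines, path) {
  stopifnot(inherits(cytokines, "cytokine_table"))
  v <- cytokines$values
  df <- data.frame(
    cytokine = rep(rownames(v), times = ncol(v)),
    sample = rep(colnames(v), each = nrow(v)),
    value = as.vector(v),
    lod = rep(cytokines$lod, times = ncol(v)),
    censored = as.vector(cytokines$censored)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
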