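#' Construct a validated expression matrix
#'
#' An `expr_matrix` is a plain numeric matrix of non-negative expression
#' values (counts, TPM, or any unitless scale) with unique gene identifiers
#' as row names and unique sample identifiers as column names.  All
#' downstream stages (normalization, filtering, network construction)
#' operate on this type.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: `rownames(values)`).
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: `colnames(values)`).
#' @return A numeric matrix of class `expr_matrix` with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    gcoex_error("expression values must be a numeric matrix")
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    gcoex_error("gene and sample identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) == 0L) gcoex_error("at least one gene is required")
  if (length(sample_ids) == 0L) gcoex_error("at least one sample is required")
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    gcoex_error(sprintf("duplicate gene ID: '%s'", dup))
  }
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1L]
    gcoex_error(sprintf("duplicate sample ID: '%s'", dup))
  }
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids)) {
    gcoex_error("matrix shape does not match identifier lengths")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    gcoex_error("expression values must be finite with no missing entries")
  }
  if (any(values < 0)) {
    gcoex_error("expression values must be non-negative")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples\n", nrow(x), ncol(x)))
  cat("genes:  ", paste(utils::head(rownames(x), 5L), collapse = ", "),
      if (nrow(x) > 5L) ", ..." else "", "\n", sep = "")
  cat("samples: ", paste(utils::head(colnames(x), 5L), collapse = ", "),
      if (ncol(x) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Re-validate and re-class a matrix produced by matrix arithmetic.
as_expr_matrix <- function(values) {
  class(values) <- setdiff(class(values), "expr_matrix")
  expression_matrix(values)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' The expected format is a tab-delimited file with a header row (first
#' token arbitrary, remaining tokens sample IDs) and one row per gene:
#' gene ID followed by one numeric value per sample.  Validation is strict:
#' ragged rows, duplicate gene IDs, missing (`NA`/empty) or negative cells
#' are load errors that name the offending line, row, or column.  Both Unix
#' and Windows line endings are accepted.
#'
#' @param path Path to a TSV file.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    gcoex_error(sprintf("'%s': need a header line and at least one gene row",
                        path), "gcoex_io_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) {
    gcoex_error(sprintf("'%s': header must name at least one sample", path),
                "gcoex_io_error")
  }
  sample_ids <- header[-1L]
  n_fields <- 1L + length(sample_ids)
  body <- fields[-1L]

  widths <- lengths(body)
  if (any(widths != n_fields)) {
    bad <- which(widths != n_fields)[1L]
    gcoex_error(sprintf(
      "'%s' line %d: expected %d fields, found %d (ragged row)",
      path, bad + 1L, n_fields, widths[bad]), "gcoex_io_error")
  }

  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    line <- which(gene_ids == dup)[2L] + 1L
    gcoex_error(sprintf("'%s' line %d: duplicate gene ID '%s'",
                        path, line, dup), "gcoex_io_error")
  }

  raw <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  vals <- parse_numeric_cells(raw)
  bad <- which(is.na(vals))
  if (length(bad)) {
    i <- bad[1L]
    row <- (i - 1L) %/% length(sample_ids) + 1L
    col <- (i - 1L) %% length(sample_ids) + 1L
    gcoex_error(sprintf(
      "'%s': non-numeric or missing value '%s' at gene '%s' (row %d), sample '%s' (column %d)",
      path, raw[i], gene_ids[row], row, sample_ids[col], col),
      "gcoex_io_error")
  }
  bad <- which(vals < 0)
  if (length(bad)) {
    i <- bad[1L]
    row <- (i - 1L) %/% length(sample_ids) + 1L
    col <- (i - 1L) %% length(sample_ids) + 1L
    gcoex_error(sprintf(
      "'%s': negative value %s at gene '%s' (row %d), sample '%s' (column %d)",
      path, raw[i], gene_ids[row], row, sample_ids[col], col),
      "gcoex_io_error")
  }

  m <- matrix(vals, nrow = length(gene_ids), ncol = length(sample_ids),
              byrow = TRUE)
  expression_matrix(m, gene_ids, sample_ids)
}

#' Write an expression matrix to TSV
#'
#' Values are printed with 6 significant digits; reading the file back
#' reproduces the matrix to within that precision (integers round-trip
#' exactly).  Output is UTF-8 with Unix line endings.
#'
#' @param m An [expression_matrix()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  if (!inherits(m, "expr_matrix")) m <- as_expr_matrix(m)
  if (nrow(m) == 0L) gcoex_error("nothing to write: matrix has no genes")
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
  }, character(1L))
  write_text_lines(c(header, rows), path)
}
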