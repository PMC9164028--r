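#' Construct a bidirectional gene-to-term annotation map
#'
#' Functional annotations (GO/KEGG-style, but term IDs are opaque strings)
#' are held as two exactly inverse indices: `gene_to_terms` and
#' `term_to_genes`.  Repeated pairs are deduplicated; no empty term or gene
#' set is ever stored.
#'
#' @param genes,terms Character vectors of equal length, one gene-term pair
#'   per element.
#' @return A list of class `annotation_map` with elements `gene_to_terms`
#'   and `term_to_genes` (named lists of sorted character vectors).
#' @export
annotation_map <- function(genes, terms) {
  genes <- as.character(genes)
  terms <- as.character(terms)
  if (length(genes) != length(terms)) {
    gcoex_error("genes and terms must have equal length")
  }
  keep <- !duplicated(paste(genes, terms, sep = "\t"))
  genes <- genes[keep]; terms <- terms[keep]
  g2t <- lapply(split(terms, factor(genes, levels = lex_sort(unique(genes)))),
                lex_sort)
  t2g <- lapply(split(genes, factor(terms, levels = lex_sort(unique(terms)))),
                lex_sort)
  structure(list(gene_to_terms = g2t, term_to_genes = t2g),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d genes, %d terms, %d pairs\n",
              length(x$gene_to_terms), length(x$term_to_genes),
              sum(lengths(x$gene_to_terms))))
  invisible(x)
}

#' Genes carrying at least one annotation
#' @param ann An [annotation_map()].
#' @return Sorted character vector of annotated gene IDs.
#' @export
annotated_genes <- function(ann) {
  names(ann$gene_to_terms)
}

# Remove one gene's annotations (used by leave-one-out evaluation).
drop_gene_annotation <- function(ann, gene) {
  g2t <- ann$gene_to_terms
  if (!gene %in% names(g2t)) return(ann)
  terms <- g2t[[gene]]
  g2t[[gene]] <- NULL
  t2g <- ann$term_to_genes
  for (t in terms) {
    t2g[[t]] <- setdiff(t2g[[t]], gene)
    if (length(t2g[[t]]) == 0L) t2g[[t]] <- NULL
  }
  structure(list(gene_to_terms = g2t, term_to_genes = t2g),
            class = "annotation_map")
}

#' Read a gene-term annotation file
#'
#' Two-column TSV, one `gene<TAB>term` pair per line; repeated pairs are
#' allowed and deduplicated.  An empty file yields an empty map.
#'
#' @param path Path to the annotation TSV.
#' @return An [annotation_map()].
#' @export
read_annotation <- function(path) {
  lines <- read_text_lines(path)
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0L) return(annotation_map(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != 2L)) {
    bad <- which(widths != 2L)[1L]
    gcoex_error(sprintf("'%s' line %d: expected 2 tab-separated fields, found %d",
                        path, which(keep)[bad], widths[bad]), "gcoex_io_error")
  }
  annotation_map(vapply(fields, `[[`, character(1L), 1L),
                 vapply(fields, `[[`, character(1L), 2L))
}

#' Write an annotation map to two-column TSV
#' @param ann An [annotation_map()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_annotation <- function(ann, path) {
  genes <- rep(names(ann$gene_to_terms), lengths(ann$gene_to_terms))
  terms <- unlist(ann$gene_to_terms, use.names = FALSE)
  write_text_lines(sprintf("%s\t%s", genes, terms), path)
}

#' Read a gene list (one ID per line)
#'
#' Lines starting with `#` and blank lines are ignored.  Duplicates are
#' dropped, preserving first occurrence, with a warning.  Used e.g. for
#' housekeeping-gene lists and RWR seed sets, which must be non-empty.
#'
#' @param path Path to the list file.
#' @return Character vector of unique gene IDs in file order.
#' @export
read_gene_list <- function(path) {
  lines <- read_text_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    gcoex_error(sprintf("'%s': gene list is empty", path), "gcoex_io_error")
  }
  if (anyDuplicated(lines)) {
    gcoex_warning(sprintf("'%s': %d duplicate gene IDs dropped",
                          path, sum(duplicated(lines))))
    lines <- lines[!duplicated(lines)]
  }
  lines
}
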