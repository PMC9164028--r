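#' Construct a co-expression network from an edge table
#'
#' A `coex_network` is an undirected weighted graph stored as an edge-list
#' data frame with columns `gene_a`, `gene_b`, `rho` (the correlation, in
#' \[-1, 1\]), `pvalue`, and `fdr` (both optionally `NA` when statistics
#' were not computed, e.g. after a merge).  Each unordered pair is stored
#' once in canonical order (`gene_a` lexicographically before `gene_b`,
#' C collation), self-edges are forbidden, and rows are sorted by
#' (`gene_a`, `gene_b`) so that equal networks are byte-identical on disk.
#'
#' @param gene_a,gene_b Character vectors of gene identifiers.
#' @param rho Numeric edge weights (correlations) in \[-1, 1\].
#' @param pvalue,fdr Optional numeric vectors in \[0, 1\] (`NA` = absent).
#' @return A data frame of class `coex_network`; the incident gene set is
#'   available via [network_nodes()].
#' @export
coex_network <- function(gene_a, gene_b, rho,
                         pvalue = rep(NA_real_, length(rho)),
                         fdr = rep(NA_real_, length(rho))) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  n <- length(gene_a)
  if (length(gene_b) != n || length(rho) != n ||
      length(pvalue) != n || length(fdr) != n) {
    gcoex_error("edge columns must have equal length")
  }
  if (any(gene_a == gene_b)) {
    bad <- gene_a[gene_a == gene_b][1L]
    gcoex_error(sprintf("self-edge on gene '%s' is not allowed", bad))
  }
  if (n > 0L) {
    if (anyNA(rho) || any(!is.finite(rho)) || any(abs(rho) > 1)) {
      gcoex_error("edge weights must be finite correlations in [-1, 1]")
    }
    ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
    if (!ok(pvalue) || !ok(fdr)) {
      gcoex_error("p-values and FDR values must lie in [0, 1] or be NA")
    }
    # canonical order within each pair
    swap <- lex_lt(gene_b, gene_a)
    tmp <- gene_a[swap]
    gene_a[swap] <- gene_b[swap]
    gene_b[swap] <- tmp
    # collapse duplicate pairs; conflicting weights are an error
    key <- paste(gene_a, gene_b, sep = "\t")
    if (anyDuplicated(key)) {
      first <- match(key, key)
      conflict <- which(rho != rho[first] |
                          !identical_na(pvalue, pvalue[first]) |
                          !identical_na(fdr, fdr[first]))
      if (length(conflict)) {
        i <- conflict[1L]
        gcoex_error(sprintf(
          "duplicate edge %s -- %s with conflicting values",
          gene_a[i], gene_b[i]))
      }
      keep <- !duplicated(key)
      gene_a <- gene_a[keep]; gene_b <- gene_b[keep]
      rho <- rho[keep]; pvalue <- pvalue[keep]; fdr <- fdr[keep]
    }
    o <- lex_order(gene_a, gene_b)
    gene_a <- gene_a[o]; gene_b <- gene_b[o]
    rho <- rho[o]; pvalue <- pvalue[o]; fdr <- fdr[o]
  }
  net <- data.frame(gene_a = gene_a, gene_b = gene_b, rho = as.numeric(rho),
                    pvalue = as.numeric(pvalue), fdr = as.numeric(fdr),
                    stringsAsFactors = FALSE)
  class(net) <- c("coex_network", "data.frame")
  net
}

# elementwise "equal, treating NA == NA as TRUE"
identical_na <- function(x, y) {
  (is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) & x == y)
}

#' Genes incident to at least one edge of a network
#' @param net A [coex_network()].
#' @return Character vector of node names, lexicographically sorted.
#' @export
network_nodes <- function(net) {
  lex_sort(unique(c(net$gene_a, net$gene_b)))
}

#' @export
print.coex_network <- function(x, ...) {
  cat(sprintf("<coex_network> %d nodes, %d edges\n",
              length(network_nodes(x)), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 6L))
  invisible(x)
}

# adjacency list: named list gene -> character vector of neighbours
adjacency_list <- function(net) {
  nodes <- network_nodes(net)
  adj <- split(c(net$gene_b, net$gene_a),
               factor(c(net$gene_a, net$gene_b), levels = nodes))
  lapply(adj, function(v) lex_sort(unique(v)))
}

#' Read a weighted edge list from TSV
#'
#' Expected columns (no header): `gene_a`, `gene_b`, `correlation`
#' \[, `pvalue` \[, `fdr`\]\].  Missing statistical columns (or empty
#' fields) are stored as absent (`NA`).  Pairs are canonicalized on read;
#' duplicate rows carrying identical values collapse silently, while
#' conflicting duplicates and self-edges are errors.
#'
#' @param path Path to an edge-list TSV.
#' @return A [coex_network()].
#' @export
read_network <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(coex_network(character(), character(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths < 3L)) {
    bad <- which(widths < 3L)[1L]
    gcoex_error(sprintf("'%s' line %d: need at least 3 fields (gene_a, gene_b, correlation)",
                        path, bad), "gcoex_io_error")
  }
  get_col <- function(k) {
    vapply(fields, function(f) if (length(f) >= k) f[[k]] else "", character(1L))
  }
  num_col <- function(k, what) {
    raw <- get_col(k)
    out <- rep(NA_real_, length(raw))
    has <- nzchar(raw)
    out[has] <- parse_numeric_cells(raw[has])
    bad <- which(has & is.na(out))
    if (length(bad)) {
      gcoex_error(sprintf("'%s' line %d: non-numeric %s '%s'",
                          path, bad[1L], what, raw[bad[1L]]), "gcoex_io_error")
    }
    out
  }
  rho <- num_col(3L, "correlation")
  if (anyNA(rho)) {
    gcoex_error(sprintf("'%s' line %d: missing correlation", path,
                        which(is.na(rho))[1L]), "gcoex_io_error")
  }
  coex_network(get_col(1L), get_col(2L), rho,
               pvalue = num_col(4L, "p-value"), fdr = num_col(5L, "FDR"))
}

#' Write a network edge list to TSV
#'
#' Emits five tab-delimited columns (`gene_a`, `gene_b`, `correlation`,
#' `pvalue`, `fdr`) with the empty string for absent statistics; numeric
#' values use 6 significant digits.  A write-read-write cycle is
#' byte-stable.
#'
#' @param net A [coex_network()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_network <- function(net, path) {
  rows <- sprintf("%s\t%s\t%s\t%s\t%s", net$gene_a, net$gene_b,
                  fmt_num(net$rho), fmt_num(net$pvalue), fmt_num(net$fdr))
  write_text_lines(rows, path)
}
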