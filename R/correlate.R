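#' Pearson correlation of two expression vectors
#'
#' The product-moment correlation
#' \deqn{\rho = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
#'   {\sqrt{\sum_i (x_i-\bar x)^2}\sqrt{\sum_i (y_i-\bar y)^2}}}
#' applied to raw values.  Constant vectors have no defined correlation
#' and raise an error of class `gcoex_constant_error` (at the network
#' level such genes are skipped, not fatal).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  check_cor_input(x, y)
  r <- stats::cor(x, y, method = "pearson")
  min(1, max(-1, r))
}

#' Spearman correlation of two expression vectors
#'
#' Values are replaced by their ranks (average ranks on ties) and the
#' product-moment formula is applied to the ranks, making the coefficient
#' invariant under strictly monotone transforms and robust to outliers —
#' the recommended choice for RNA-Seq.
#'
#' @inheritParams pearson_cor
#' @return The rank correlation in \[-1, 1\].
#' @export
spearman_cor <- function(x, y) {
  check_cor_input(x, y)
  r <- stats::cor(x, y, method = "spearman")
  if (is.na(r)) {
    gcoex_error("constant ranks: correlation undefined", "gcoex_constant_error")
  }
  min(1, max(-1, r))
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) gcoex_error("vectors must have equal length")
  if (length(x) < 3L) gcoex_error("correlation needs >= 3 observations")
  if (anyNA(x) || anyNA(y)) gcoex_error("missing values are not allowed")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    gcoex_error("constant vector: correlation undefined",
                "gcoex_constant_error")
  }
  invisible(TRUE)
}

#' Two-sided correlation p-value
#'
#' Classical t approximation: `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom; `|rho| = 1` maps to p = 0 by convention.
#'
#' @param rho Correlation(s) in \[-1, 1\].
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value(s) in \[0, 1\].
#' @export
correlation_pvalue <- function(rho, n) {
  if (any(n < 3L)) gcoex_error("p-value needs n >= 3")
  if (any(abs(rho) > 1 + 1e-12)) gcoex_error("|rho| must be <= 1")
  rho <- pmin(1, pmax(-1, rho))
  p <- rep(0, length(rho))
  ok <- abs(rho) < 1
  t <- abs(rho[ok]) * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(-t, df = n - 2)
  pmin(1, p)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (monotone, clipped at 1) over one family of
#' tests; thin wrapper over `stats::p.adjust(method = "BH")` so every
#' module shares a single adjustment path.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) && (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))) {
    gcoex_error("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Build a co-expression network from an expression matrix
#'
#' Every unordered gene pair is scored by Spearman (default) or Pearson
#' correlation; an edge is kept iff `|rho| >= min_abs_rho`, its BH-FDR
#' (computed over all evaluated pairs) is `<= max_fdr`, and, when
#' `positive_only`, `rho > 0`.  Genes with constant expression cannot be
#' correlated and are skipped with a message giving their count.
#'
#' @param m An [expression_matrix()] with >= 3 samples and >= 2 genes.
#' @param method `"spearman"` (default, recommended for RNA-Seq) or
#'   `"pearson"`.
#' @param min_abs_rho Minimum absolute correlation for an edge
#'   (default 0.8).
#' @param max_fdr Maximum BH-FDR for an edge (default 0.05; set to 1 to
#'   threshold on correlation alone).
#' @param positive_only Keep only positively correlated pairs (negative
#'   co-expression is often not biologically meaningful).
#' @return A [coex_network()]; empty (with a warning) if no pair survives.
#' @export
build_network <- function(m, method = c("spearman", "pearson"),
                          min_abs_rho = 0.8, max_fdr = 0.05,
                          positive_only = FALSE) {
  method <- match.arg(method)
  if (ncol(m) < 3L) gcoex_error("network construction needs >= 3 samples")
  if (nrow(m) < 2L) gcoex_error("network construction needs >= 2 genes")
  vals <- unclass(m)
  if (method == "spearman") {
    vals <- t(apply(vals, 1L, rank, ties.method = "average"))
  }
  sds <- apply(vals, 1L, stats::sd)
  const <- sds == 0
  if (any(const)) {
    message(sprintf("skipping %d constant-expression gene(s)", sum(const)))
    vals <- vals[!const, , drop = FALSE]
  }
  genes <- rownames(vals)
  ng <- nrow(vals)
  if (ng < 2L) {
    gcoex_warning("fewer than 2 non-constant genes: empty network")
    return(coex_network(character(), character(), numeric()))
  }
  C <- stats::cor(t(vals), method = "pearson")
  ut <- upper.tri(C)
  idx <- which(ut, arr.ind = TRUE)
  rho <- pmin(1, pmax(-1, C[ut]))
  pval <- correlation_pvalue(rho, ncol(m))
  fdr <- bh_fdr(pval)
  keep <- abs(rho) >= min_abs_rho & fdr <= max_fdr
  if (positive_only) keep <- keep & rho > 0
  if (!any(keep)) {
    gcoex_warning("no gene pair passed the correlation/FDR thresholds")
    return(coex_network(character(), character(), numeric()))
  }
  coex_network(genes[idx[keep, 1L]], genes[idx[keep, 2L]],
               rho[keep], pval[keep], fdr[keep])
}

#' Merge co-expression networks by edge support
#'
#' Network aggregation across datasets improves co-expression inference;
#' the merge keeps an edge iff it occurs in at least `min_support` of the
#' input networks, with the merged weight equal to the mean of the weights
#' in the networks containing it.  Per-network p-values are no longer
#' meaningful after aggregation, so the statistical columns are dropped
#' (absent).
#'
#' @param nets List of two or more [coex_network()] objects.
#' @param min_support Minimum number of networks an edge must appear in
#'   (between 1 and `length(nets)`).
#' @return The merged [coex_network()].
#' @export
merge_networks <- function(nets, min_support = 2L) {
  if (!is.list(nets) || length(nets) < 2L) {
    gcoex_error("need at least 2 networks to merge")
  }
  if (min_support < 1L || min_support > length(nets)) {
    gcoex_error(sprintf("min_support must lie in [1, %d]", length(nets)))
  }
  key <- unlist(lapply(nets, function(n) paste(n$gene_a, n$gene_b, sep = "\t")),
                use.names = FALSE)
  w <- unlist(lapply(nets, `[[`, "rho"), use.names = FALSE)
  support <- tapply(w, key, length)
  weight <- tapply(w, key, mean)
  keep <- names(support)[support >= min_support]
  if (length(keep) == 0L) {
    gcoex_warning("no edge reaches the requested support")
    return(coex_network(character(), character(), numeric()))
  }
  parts <- strsplit(keep, "\t", fixed = TRUE)
  coex_network(vapply(parts, `[[`, character(1L), 1L),
               vapply(parts, `[[`, character(1L), 2L),
               as.numeric(weight[keep]))
}

#' Summarize network topology
#'
#' Node/edge counts, the degree histogram, and a log10 degree-frequency
#' table (gene co-expression networks are approximately scale-free, so the
#' latter is close to a straight line).
#'
#' @param net A non-empty [coex_network()].
#' @return List with `n_nodes`, `n_edges`, `degree_hist` (data frame
#'   `degree`/`count`), and `loglog` (data frame `log10_degree`/
#'   `log10_count`).
#' @export
network_stats <- function(net) {
  if (nrow(net) == 0L) gcoex_error("network is empty")
  deg <- table(c(net$gene_a, net$gene_b))
  hist <- table(as.integer(deg))
  dh <- data.frame(degree = as.integer(names(hist)),
                   count = as.integer(hist))
  list(n_nodes = length(deg),
       n_edges = nrow(net),
       degree_hist = dh,
       loglog = data.frame(log10_degree = log10(dh$degree),
                           log10_count = log10(dh$count)))
}
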