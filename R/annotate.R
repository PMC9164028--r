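#' Hypergeometric enrichment p-value
#'
#' Probability of observing at least `k` annotated genes among `n` drawn
#' neighbours when `M` of the `N` background genes carry the annotation:
#' \deqn{p = 1 - \sum_{i=0}^{k-1} \binom{M}{i}\binom{N-M}{n-i} /
#'   \binom{N}{n}}
#' (upper tail; evaluated in log space via `stats::phyper` for stability).
#'
#' @param N Background size.
#' @param M Background genes carrying the term (`M <= N`).
#' @param n Number of neighbours drawn (`n <= N`).
#' @param k Annotated neighbours observed (`0 <= k <= min(n, M)`).
#' @return The enrichment p-value in \[0, 1\]; `k = 0` gives 1.
#' @export
hypergeom_pvalue <- function(N, M, n, k) {
  bad <- N < 0 | M < 0 | n < 0 | k < 0 | M > N | n > N | k > pmin(n, M)
  if (any(bad)) {
    gcoex_error("require 0 <= k <= min(n, M), n <= N, M <= N")
  }
  stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Annotate target genes from their direct network neighbours
#'
#' Guilt-by-association enrichment: for each target, its annotated
#' neighbours vote for their terms, and each term carried by at least one
#' neighbour is tested with [hypergeom_pvalue()] against the background.
#' BH-FDR is applied jointly across all (target, term) tests of the call;
#' records with `fdr <= max_fdr` are returned sorted by (gene, p-value).
#'
#' @param net A [coex_network()].
#' @param ann An [annotation_map()].
#' @param targets Gene IDs to annotate; targets absent from the network
#'   are skipped with a warning.
#' @param max_fdr Maximum BH-FDR for a reported association (default 0.05).
#' @param background `"network"` (default: annotated genes that are
#'   network nodes — genes that can never be neighbours should not inflate
#'   the background) or `"annotation"` (all annotated genes).
#' @return Data frame with columns `gene`, `term`, `k`, `n`, `M`, `N`,
#'   `pvalue`, `fdr`.
#' @export
annotate_by_neighbors <- function(net, ann, targets, max_fdr = 0.05,
                                  background = c("network", "annotation")) {
  background <- match.arg(background)
  adj <- adjacency_list(net)
  missing <- setdiff(targets, names(adj))
  if (length(missing)) {
    gcoex_warning(sprintf("targets absent from network, skipped: %s",
                          paste(missing, collapse = ", ")))
    targets <- setdiff(targets, missing)
  }
  bg <- if (background == "network") {
    intersect(annotated_genes(ann), names(adj))
  } else {
    annotated_genes(ann)
  }
  neighbour_sets <- lapply(targets, function(g) adj[[g]])
  names(neighbour_sets) <- targets
  enrich_records(neighbour_sets, ann, bg, max_fdr)
}

#' Annotate target genes from co-members of their module
#'
#' Identical to [annotate_by_neighbors()] except that the voting set of a
#' target is the other members of its module; unassigned targets receive
#' no records.  The background is the annotated genes of the partition's
#' gene universe.
#'
#' @param partition A [identify_modules()] result.
#' @inheritParams annotate_by_neighbors
#' @return Data frame as in [annotate_by_neighbors()].
#' @export
annotate_by_module <- function(partition, ann, targets, max_fdr = 0.05) {
  membership <- module_membership(partition)
  missing <- setdiff(targets, names(membership))
  if (length(missing)) {
    gcoex_warning(sprintf("targets absent from partition, skipped: %s",
                          paste(missing, collapse = ", ")))
    targets <- setdiff(targets, missing)
  }
  bg <- intersect(annotated_genes(ann), names(membership))
  neighbour_sets <- lapply(targets, function(g) {
    mod <- membership[[g]]
    if (is.na(mod)) character() else
      setdiff(names(membership)[!is.na(membership) & membership == mod], g)
  })
  names(neighbour_sets) <- targets
  enrich_records(neighbour_sets, ann, bg, max_fdr)
}

# Shared enrichment core: one hypergeometric test per (target, term seen
# among the target's annotated voters), joint BH across all tests.
enrich_records <- function(neighbour_sets, ann, bg, max_fdr) {
  N <- length(bg)
  rec <- list()
  for (g in names(neighbour_sets)) {
    voters <- intersect(neighbour_sets[[g]], bg)
    n <- length(voters)
    if (n == 0L) next
    terms <- lex_sort(unique(unlist(ann$gene_to_terms[voters],
                                    use.names = FALSE)))
    for (t in terms) {
      carriers <- ann$term_to_genes[[t]]
      k <- length(intersect(voters, carriers))
      M <- length(intersect(carriers, bg))
      rec[[length(rec) + 1L]] <- data.frame(
        gene = g, term = t, k = k, n = n, M = M, N = N,
        pvalue = hypergeom_pvalue(N, M, n, k), stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(gene = character(), term = character(),
                      k = integer(), n = integer(), M = integer(),
                      N = integer(), pvalue = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
  if (length(rec) == 0L) return(empty)
  out <- do.call(rbind, rec)
  out$fdr <- bh_fdr(out$pvalue)
  out <- out[out$fdr <= max_fdr, , drop = FALSE]
  if (nrow(out) == 0L) { rownames(empty) <- NULL; return(empty) }
  out <- out[lex_order(out$gene, xtfrm(out$pvalue), out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random walk with restart over a co-expression network
#'
#' Network propagation \deqn{p^{(k)} = \alpha p^{(0)} + (1-\alpha) W
#' p^{(k-1)}} where `W` is the column-normalized (column sums 1)
#' adjacency matrix of the network and `p0` is uniform over the seed
#' genes (or proportional to supplied seed weights).  Iteration stops when
#' the L1 change drops below `tol`; the result sums to 1 at every step.
#' `alpha = 1` returns `p0`.
#'
#' @param net A [coex_network()].
#' @param seeds Character vector of seed genes, or a named non-negative
#'   numeric vector of seed weights; all seeds must be network nodes.
#' @param alpha Restart probability in (0, 1\] (default 0.5).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @param weighted Use `|rho|`-weighted adjacency columns instead of edge
#'   presence (default `FALSE`).
#' @return Named numeric vector of per-gene scores summing to 1, sorted by
#'   decreasing score (ties by gene ID); attribute `iterations` records
#'   the number of iterations used.
#' @export
rwr <- function(net, seeds, alpha = 0.5, tol = 1e-10, max_iter = 1000L,
                weighted = FALSE) {
  if (alpha <= 0 || alpha > 1) gcoex_error("alpha must lie in (0, 1]")
  nodes <- network_nodes(net)
  if (length(nodes) == 0L) gcoex_error("network is empty")
  if (is.numeric(seeds)) {
    if (is.null(names(seeds)) || any(seeds < 0) || sum(seeds) <= 0) {
      gcoex_error("weighted seeds must be a named non-negative vector with positive sum")
    }
    seed_genes <- names(seeds)
    seed_w <- as.numeric(seeds)
  } else {
    seed_genes <- as.character(seeds)
    seed_w <- rep(1, length(seed_genes))
  }
  if (length(seed_genes) == 0L) gcoex_error("at least one seed gene is required")
  bad <- setdiff(seed_genes, nodes)
  if (length(bad)) {
    gcoex_error(sprintf("seed genes not in network: %s",
                        paste(bad, collapse = ", ")))
  }
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  w <- if (weighted) abs(net$rho) else rep(1, nrow(net))
  W[cbind(net$gene_b, net$gene_a)] <- w
  W[cbind(net$gene_a, net$gene_b)] <- w
  p0 <- stats::setNames(rep(0, n), nodes)
  p0[seed_genes] <- seed_w
  p0 <- p0 / sum(p0)
  cs <- colSums(W)
  dangling <- cs == 0
  if (any(dangling)) {
    message(sprintf("%d degree-0 column(s) redistributed to the restart vector",
                    sum(dangling)))
    W[, dangling] <- p0
    cs[dangling] <- 1
  }
  W <- sweep(W, 2L, cs, `/`)
  p <- p0
  iter <- 0L
  if (alpha < 1) {
    for (iter in seq_len(max_iter)) {
      p_new <- alpha * p0 + (1 - alpha) * drop(W %*% p)
      delta <- sum(abs(p_new - p))
      p <- p_new
      if (delta < tol) break
    }
  }
  p <- p / sum(p)
  o <- order(-p, method = "radix")
  p <- p[o]
  attr(p, "iterations") <- iter
  p
}

#' Degree-preserving network shuffle
#'
#' Null-model rewiring by random double-edge swaps: two edges (u,v), (x,y)
#' are replaced by (u,x), (v,y) or (u,y), (v,x), rejecting swaps that
#' would create self-edges or duplicate edges, so the degree of every node
#' is preserved exactly.  Used as the control network when judging
#' annotation-transfer accuracy.  If no swap succeeds (e.g. a triangle,
#' where every swap is illegal) the input is returned unchanged with a
#' warning.
#'
#' @param net A [coex_network()] with >= 2 edges.
#' @param seed Integer RNG seed; the same seed always yields the same
#'   shuffled network (the caller's RNG state is untouched).
#' @param n_swaps_per_edge Attempted swaps per edge (default 10).
#' @return A [coex_network()] with the same degree sequence; edge weights
#'   travel with the first slot of each swapped pair and the statistical
#'   columns are dropped.
#' @export
shuffle_network <- function(net, seed, n_swaps_per_edge = 10L) {
  if (nrow(net) < 2L) gcoex_error("shuffling needs >= 2 edges")
  a <- net$gene_a
  b <- net$gene_b
  m <- length(a)
  edge_key <- function(x, y) {
    swap <- lex_lt(y, x)
    paste(ifelse(swap, y, x), ifelse(swap, x, y), sep = "\t")
  }
  withr::with_seed(as.integer(seed), {
    keys <- new.env(parent = emptyenv())
    for (k in edge_key(a, b)) assign(k, TRUE, envir = keys)
    successes <- 0L
    n_attempts <- as.integer(n_swaps_per_edge) * m
    for (att in seq_len(n_attempts)) {
      ij <- sample.int(m, 2L)
      i <- ij[1L]; j <- ij[2L]
      u <- a[i]; v <- b[i]; x <- a[j]; y <- b[j]
      if (stats::runif(1) < 0.5) { tmp <- x; x <- y; y <- tmp }
      # proposed replacement: (u, x) and (v, y)
      if (u == x || v == y) next
      k1 <- edge_key(u, x); k2 <- edge_key(v, y)
      if (exists(k1, envir = keys) || exists(k2, envir = keys) || k1 == k2) next
      rm(list = edge_key(u, v), envir = keys)
      rm(list = edge_key(x, y), envir = keys)
      assign(k1, TRUE, envir = keys)
      assign(k2, TRUE, envir = keys)
      a[i] <- u; b[i] <- x
      a[j] <- v; b[j] <- y
      successes <- successes + 1L
    }
  })
  if (successes == 0L) {
    gcoex_warning("no legal degree-preserving swap found; network returned unchanged")
    return(net)
  }
  coex_network(a, b, net$rho)
}

#' Leave-one-out annotation accuracy versus a shuffled control
#'
#' For every annotated network gene, its annotations are hidden and
#' re-predicted from the chosen voting set ([annotate_by_neighbors()] or
#' [annotate_by_module()]); the gene counts as a hit when any of its true
#' terms appears among its FDR-passing predictions.  Accuracy is
#' hits / evaluated genes; genes with no annotated voters are excluded
#' from the denominator and reported separately.  The identical procedure
#' is applied to a degree-preserving [shuffle_network()] control, and the
#' real-minus-control difference is reported: a positive difference is the
#' evidence that annotation transfer exploits genuine co-expression
#' structure rather than degree alone.
#'
#' @param net A [coex_network()].
#' @param ann A non-empty [annotation_map()].
#' @param max_fdr Maximum BH-FDR for a prediction (default 0.05).
#' @param mode `"neighbors"` (default) or `"module"`.
#' @param control_seed RNG seed for the shuffled control network.
#' @param similarity_cutoff,min_module_size Passed to [identify_modules()]
#'   when `mode = "module"`.
#' @return List of class `accuracy_report`: `accuracy_real`,
#'   `accuracy_shuffled`, `difference`, plus per-network counts
#'   (`evaluated`, `hits`, `excluded`).
#' @export
evaluate_accuracy <- function(net, ann, max_fdr = 0.05,
                              mode = c("neighbors", "module"),
                              control_seed = 1L,
                              similarity_cutoff = 0.5,
                              min_module_size = 3L) {
  mode <- match.arg(mode)
  if (length(annotated_genes(ann)) == 0L) {
    gcoex_error("annotation map is empty")
  }
  run_loo <- function(network) {
    voters_of <- if (mode == "neighbors") {
      adj <- adjacency_list(network)
      function(g) adj[[g]]
    } else {
      part <- identify_modules(network, similarity_cutoff, min_module_size)
      membership <- module_membership(part)
      function(g) {
        mod <- membership[[g]]
        if (is.na(mod)) character() else
          setdiff(names(membership)[!is.na(membership) & membership == mod], g)
      }
    }
    genes <- intersect(network_nodes(network), annotated_genes(ann))
    hits <- 0L; evaluated <- 0L; excluded <- 0L
    for (g in genes) {
      ann_loo <- drop_gene_annotation(ann, g)
      voters <- intersect(voters_of(g), annotated_genes(ann_loo))
      if (length(voters) == 0L) { excluded <- excluded + 1L; next }
      evaluated <- evaluated + 1L
      sets <- stats::setNames(list(voters_of(g)), g)
      bg <- intersect(annotated_genes(ann_loo), network_nodes(network))
      pred <- enrich_records(sets, ann_loo, bg, max_fdr)
      if (any(pred$term %in% ann$gene_to_terms[[g]])) hits <- hits + 1L
    }
    list(evaluated = evaluated, hits = hits, excluded = excluded,
         accuracy = if (evaluated > 0L) hits / evaluated else NA_real_)
  }
  real <- run_loo(net)
  if (real$evaluated == 0L) {
    gcoex_error("no annotated gene with annotated voters: accuracy undefined")
  }
  shuffled_net <- shuffle_network(net, control_seed)
  control <- run_loo(shuffled_net)
  structure(list(
    accuracy_real = real$accuracy,
    accuracy_shuffled = control$accuracy,
    difference = real$accuracy -
      (if (is.na(control$accuracy)) 0 else control$accuracy),
    real = real, shuffled = control, mode = mode,
    control_seed = as.integer(control_seed)),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "<accuracy_report> mode=%s\n  real:     %.3f (%d/%d evaluated, %d excluded)\n  shuffled: %.3f (%d/%d evaluated, %d excluded)\n  difference: %+.3f\n",
    x$mode, x$accuracy_real, x$real$hits, x$real$evaluated, x$real$excluded,
    x$accuracy_shuffled, x$shuffled$hits, x$shuffled$evaluated,
    x$shuffled$excluded, x$difference))
  invisible(x)
}
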