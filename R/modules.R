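#' Node similarity from shared network neighbourhood
#'
#' Topological similarity of two genes in a co-expression network,
#' \deqn{s_{ij} = \frac{h_{ij} + a_{ij}}{c_i + c_j - h_{ij} - a_{ij}}}
#' where \eqn{h_{ij}} is the number of neighbours shared by i and j,
#' \eqn{a_{ij}} is 1 if i and j are adjacent (else 0), and \eqn{c_i},
#' \eqn{c_j} are their degrees.  The value lies in \[0, 1\]; it is 1 for an
#' isolated edge or an adjacent pair in a triangle, and defined as 0 when
#' the numerator is 0.
#'
#' @param net A [coex_network()].
#' @param i,j Distinct gene IDs present in the network.
#' @return The similarity in \[0, 1\].
#' @export
node_similarity <- function(net, i, j) {
  if (identical(i, j)) gcoex_error("node similarity of a gene with itself is undefined")
  adj <- adjacency_list(net)
  if (!i %in% names(adj) || !j %in% names(adj)) {
    gcoex_error("both genes must be network nodes")
  }
  node_similarity_adj(adj, i, j)
}

node_similarity_adj <- function(adj, i, j) {
  ni <- adj[[i]]; nj <- adj[[j]]
  h <- length(intersect(ni, nj))
  a <- as.integer(j %in% ni)
  num <- h + a
  if (num == 0L) return(0)
  num / (length(ni) + length(nj) - h - a)
}

# Dense node-similarity matrix over all node pairs (NA on the diagonal).
node_similarity_matrix <- function(net) {
  adj <- adjacency_list(net)
  nodes <- names(adj)
  n <- length(nodes)
  s <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s[i, j] <- s[j, i] <- node_similarity_adj(adj, nodes[i], nodes[j])
    }
  }
  s
}

#' Identify network modules by similarity-based hierarchical clustering
#'
#' Agglomerative clustering on the shared-neighbour node similarity
#' ([node_similarity()]): every gene starts as a singleton; the pair of
#' clusters with the highest average pairwise node similarity (average
#' linkage) is merged repeatedly while that similarity is at least
#' `similarity_cutoff`.  Candidate pairs are restricted to clusters joined
#' by at least one network edge, so modules are always connected
#' subgraphs.  Ties are broken deterministically by the lexicographically
#' smallest (cluster-label) pair, a cluster's label being its smallest
#' member gene.  Final clusters of size >= `min_module_size` become
#' modules; the remaining genes are reported as unassigned.
#'
#' @param net A non-empty [coex_network()].
#' @param similarity_cutoff Minimum average similarity for a merge
#'   (default 0.5; values > 1 make the condition vacuous, so nothing
#'   merges).
#' @param min_module_size Minimum genes per reported module (default 3).
#' @return A list of class `module_partition` with elements `modules`
#'   (list of sorted gene-ID vectors, ordered by their smallest member)
#'   and `unassigned` (sorted gene-ID vector).
#' @export
identify_modules <- function(net, similarity_cutoff = 0.5,
                             min_module_size = 3L) {
  if (nrow(net) == 0L) gcoex_error("cannot identify modules in an empty network")
  if (!is.numeric(similarity_cutoff) || similarity_cutoff <= 0) {
    gcoex_error("similarity_cutoff must be > 0")
  }
  if (min_module_size < 1L) gcoex_error("min_module_size must be >= 1")

  s <- node_similarity_matrix(net)
  nodes <- rownames(s)
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[cbind(net$gene_a, net$gene_b)] <- TRUE
  A[cbind(net$gene_b, net$gene_a)] <- TRUE

  clusters <- as.list(nodes)
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    labels <- vapply(clusters, function(cl) lex_sort(cl)[1L], character(1L))
    best <- NULL
    best_sim <- -Inf
    for (p in seq_len(k - 1L)) {
      for (q in seq.int(p + 1L, k)) {
        ip <- clusters[[p]]; iq <- clusters[[q]]
        if (!any(A[ip, iq])) next
        sim <- mean(s[ip, iq])
        lab <- lex_sort(c(labels[p], labels[q]))
        if (sim > best_sim ||
            (sim == best_sim && !is.null(best) &&
             lex_pair_lt(lab, best$lab))) {
          best <- list(p = p, q = q, lab = lab)
          best_sim <- sim
        }
      }
    }
    if (is.null(best) || best_sim < similarity_cutoff) break
    merged <- c(clusters[[best$p]], clusters[[best$q]])
    clusters <- c(clusters[-c(best$p, best$q)], list(merged))
  }

  sizes <- lengths(clusters)
  modules <- lapply(clusters[sizes >= min_module_size], lex_sort)
  if (length(modules)) {
    modules <- modules[lex_order(vapply(modules, `[[`, character(1L), 1L))]
  }
  unassigned <- unlist(clusters[sizes < min_module_size], use.names = FALSE)
  unassigned <- if (is.null(unassigned)) character() else lex_sort(unassigned)
  structure(list(modules = modules, unassigned = unassigned),
            class = "module_partition")
}

# TRUE if label pair a = c(lo, hi) precedes pair b lexicographically.
lex_pair_lt <- function(a, b) {
  if (a[1L] != b[1L]) return(lex_lt(a[1L], b[1L]))
  a[2L] != b[2L] && lex_lt(a[2L], b[2L])
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules, %d unassigned genes\n",
              length(x$modules), length(x$unassigned)))
  for (i in seq_along(x$modules)) {
    cat(sprintf("  M%d (%d): %s\n", i, length(x$modules[[i]]),
                paste(utils::head(x$modules[[i]], 8L), collapse = ", ")))
  }
  invisible(x)
}

# module membership lookup: named character vector gene -> "M<i>"/NA
module_membership <- function(partition) {
  genes <- c(unlist(partition$modules, use.names = FALSE),
             partition$unassigned)
  lab <- c(rep(sprintf("M%d", seq_along(partition$modules)),
               lengths(partition$modules)),
           rep(NA_character_, length(partition$unassigned)))
  names(lab) <- genes
  lab
}
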