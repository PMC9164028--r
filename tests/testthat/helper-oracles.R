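# Independent oracles used by the property and acceptance tests.  They are
# deliberately naive (counting, enumeration, closed forms) and share no code
# with the package internals they check.

# Two-pass product-moment correlation: mean first, then the sum formula.
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Average ranks by counting smaller/equal elements, no call to rank().
naive_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    smaller <- sum(x < x[i])
    ties <- sum(x == x[i])
    smaller + (ties + 1) / 2
  }, numeric(1))
}

naive_spearman <- function(x, y) {
  naive_pearson(naive_ranks(x), naive_ranks(y))
}

# Shared-neighbour similarity by explicit enumeration over the node set.
brute_node_similarity <- function(edges, i, j) {
  nbrs <- function(g) {
    unique(c(edges$gene_b[edges$gene_a == g], edges$gene_a[edges$gene_b == g]))
  }
  ni <- nbrs(i); nj <- nbrs(j)
  h <- sum(ni %in% nj)
  a <- as.integer(j %in% ni)
  if (h + a == 0L) return(0)
  (h + a) / (length(ni) + length(nj) - h - a)
}

# Exact hypergeometric upper tail from the binomial-coefficient sum.
brute_hypergeom <- function(N, M, n, k) {
  ch <- function(a, b) if (b > a || b < 0) 0 else choose(a, b)
  if (k == 0) return(1)
  s <- sum(vapply(0:(k - 1), function(i) ch(M, i) * ch(N - M, n - i),
                  numeric(1)))
  1 - s / ch(N, n)
}

# Random simple graph on `n` labelled nodes with edge probability `p`,
# returned as a gcoex network (resampled until at least one edge exists).
random_graph <- function(n, p = 0.4, connected = FALSE) {
  nodes <- sprintf("n%02d", seq_len(n))
  repeat {
    pairs <- t(combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < p
    if (connected && n > 1) {
      # chain backbone guarantees connectivity
      chain <- cbind(nodes[-n], nodes[-1])
      pairs <- rbind(pairs[keep, , drop = FALSE], chain)
      pairs <- pairs[!duplicated(paste(pairs[, 1], pairs[, 2])), , drop = FALSE]
      keep <- rep(TRUE, nrow(pairs))
    }
    if (any(keep)) {
      return(coex_network(pairs[keep, 1], pairs[keep, 2],
                          rep(0.9, sum(keep))))
    }
  }
}

# Agglomerative module detection re-derived from scratch: recomputes every
# cluster-pair average similarity at every step straight from the edge list.
brute_modules <- function(net, cutoff = 0.5, min_size = 3L) {
  nodes <- sort(unique(c(net$gene_a, net$gene_b)), method = "radix")
  clusters <- as.list(nodes)
  adjacent <- function(ca, cb) {
    any((net$gene_a %in% ca & net$gene_b %in% cb) |
          (net$gene_a %in% cb & net$gene_b %in% ca))
  }
  avg_sim <- function(ca, cb) {
    mean(vapply(ca, function(i) {
      vapply(cb, function(j) brute_node_similarity(net, i, j), numeric(1))
    }, numeric(length(cb))))
  }
  repeat {
    k <- length(clusters)
    if (k < 2) break
    best <- NULL; best_sim <- -Inf
    for (p in seq_len(k - 1)) {
      for (q in (p + 1):k) {
        if (!adjacent(clusters[[p]], clusters[[q]])) next
        sim <- avg_sim(clusters[[p]], clusters[[q]])
        lab <- sort(c(min(sort(clusters[[p]], method = "radix")),
                      min(sort(clusters[[q]], method = "radix"))),
                    method = "radix")
        better <- sim > best_sim ||
          (sim == best_sim && !is.null(best) &&
             (lab[1] < best$lab[1] ||
                (lab[1] == best$lab[1] && lab[2] < best$lab[2])))
        if (better) { best <- list(p = p, q = q, lab = lab); best_sim <- sim }
      }
    }
    if (is.null(best) || best_sim < cutoff) break
    clusters <- c(clusters[-c(best$p, best$q)],
                  list(c(clusters[[best$p]], clusters[[best$q]])))
  }
  sizes <- lengths(clusters)
  mods <- lapply(clusters[sizes >= min_size], sort, method = "radix")
  mods <- mods[order(vapply(mods, `[`, character(1), 1), method = "radix")]
  un <- unlist(clusters[sizes < min_size], use.names = FALSE)
  list(modules = mods,
       unassigned = if (is.null(un)) character() else sort(un, method = "radix"))
}

# Partition of all genes as a label vector (unassigned genes get unique
# labels), for adjusted-Rand comparisons.
partition_labels <- function(partition, genes) {
  lab <- character(length(genes)); names(lab) <- genes
  for (i in seq_along(partition$modules)) {
    lab[partition$modules[[i]]] <- sprintf("M%d", i)
  }
  un <- intersect(partition$unassigned, genes)
  lab[un] <- sprintf("U%d", seq_along(un))
  lab
}

expr_fixture <- function(values, genes = sprintf("g%d", seq_len(nrow(values))),
                         samples = sprintf("s%d", seq_len(ncol(values)))) {
  expression_matrix(values, genes, samples)
}
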