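#' Simulate an expression matrix with planted co-expression blocks
#'
#' Latent-factor Gaussian construction: each block shares one latent
#' profile across samples, and every gene in the block is
#' `baseline + sqrt(within_rho) * latent + noise_sd * sqrt(1 - within_rho) * eps`
#' with independent standard-normal noise, so at the default
#' `noise_sd = 1` the expected within-block Pearson correlation is exactly
#' `within_rho` and cross-block correlations are 0.  `noise_sd` scales the
#' calibrated noise: smaller values push within-block correlations towards
#' 1.  If any simulated value is negative, the whole matrix is shifted up
#' by a constant (correlations are unaffected) so that expression values
#' stay non-negative.  With `count_mode = TRUE` values are exponentiated
#' (`2^z`), giving positively skewed count-like data for exercising the
#' normalization methods; ranks, and hence Spearman correlations, are
#' unchanged by this transform.
#'
#' @param n_blocks Number of planted modules (default 3).
#' @param genes_per_block Genes per module (default 10).
#' @param n_samples Number of samples, >= 4 (default 20).
#' @param within_rho Target within-block Pearson correlation in (0, 1)
#'   (default 0.9).
#' @param noise_sd Non-negative multiplier of the calibrated noise scale
#'   (default 1; 0 gives perfectly correlated blocks).
#' @param seed Integer RNG seed; the same seed reproduces the matrix
#'   exactly.
#' @param baseline Mean expression level added to every value (default 10).
#' @param count_mode Exponentiate values to a count-like scale
#'   (default `FALSE`).
#' @return List with `matrix` (an [expression_matrix()]) and `labels`
#'   (named character vector mapping each gene to its block, `"B1"`,
#'   `"B2"`, ...).
#' @export
make_block_matrix <- function(n_blocks = 3L, genes_per_block = 10L,
                              n_samples = 20L, within_rho = 0.9,
                              noise_sd = 1, seed = 1L, baseline = 10,
                              count_mode = FALSE) {
  if (n_samples < 4L) gcoex_error("need at least 4 samples")
  if (n_blocks < 1L || genes_per_block < 1L) {
    gcoex_error("need at least one block with at least one gene")
  }
  if (!is.numeric(within_rho) || within_rho <= 0 || within_rho >= 1) {
    gcoex_error("within_rho must lie strictly in (0, 1)")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    gcoex_error(sprintf(
      "infeasible target correlation %.3g for noise_sd %.3g",
      within_rho, noise_sd))
  }
  n_genes <- n_blocks * genes_per_block
  block <- rep(seq_len(n_blocks), each = genes_per_block)
  gene_ids <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
  sample_ids <- sprintf("s%02d", seq_len(n_samples))
  vals <- withr::with_seed(as.integer(seed), {
    latent <- matrix(stats::rnorm(n_blocks * n_samples), n_blocks, n_samples)
    noise <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
    sqrt(within_rho) * latent[block, , drop = FALSE] +
      noise_sd * sqrt(1 - within_rho) * noise
  })
  vals <- if (count_mode) 2^(vals + baseline / 2) else vals + baseline
  if (min(vals) < 0) vals <- vals - min(vals)
  labels <- stats::setNames(sprintf("B%d", block), gene_ids)
  list(matrix = expression_matrix(vals, gene_ids, sample_ids),
       labels = labels)
}

#' Simulate a block-truth annotation map
#'
#' Assigns term `"T<block>"` to a random `coverage_fraction` of each
#' block's genes (`floor(coverage_fraction * block size)` genes, sampled
#' without replacement), emulating the partial functional annotation of a
#' real genome in which the remaining genes play the role of unannotated
#' lncRNAs.
#'
#' @param labels Named character vector gene -> block, as returned by
#'   [make_block_matrix()].
#' @param coverage_fraction Fraction of each block to annotate, in
#'   (0, 1\] (default 0.8).
#' @param seed Integer RNG seed.
#' @return An [annotation_map()] with terms `"T1"`, `"T2"`, ...
#' @export
make_annotation <- function(labels, coverage_fraction = 0.8, seed = 1L) {
  if (coverage_fraction <= 0 || coverage_fraction > 1) {
    gcoex_error("coverage_fraction must lie in (0, 1]")
  }
  blocks <- lex_sort(unique(labels))
  withr::with_seed(as.integer(seed), {
    genes <- character(); terms <- character()
    for (b in blocks) {
      members <- names(labels)[labels == b]
      n_pick <- floor(coverage_fraction * length(members))
      if (n_pick == 0L) next
      picked <- lex_sort(sample(members, n_pick))
      genes <- c(genes, picked)
      terms <- c(terms, rep(sub("^B", "T", b), n_pick))
    }
    annotation_map(genes, terms)
  })
}
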