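#' Median normalization
#'
#' Each sample is rescaled so that all per-sample medians coincide: sample
#' j is multiplied by (mean of all sample medians) / (median of sample j).
#' Zeros count towards the medians.  Applying the operation twice equals
#' applying it once (the factors become 1 on the second pass).
#'
#' @param m An [expression_matrix()].
#' @return The normalized [expression_matrix()].
#' @export
normalize_median <- function(m) {
  meds <- apply(m, 2L, stats::median)
  if (any(meds <= 0)) {
    bad <- colnames(m)[which(meds <= 0)[1L]]
    gcoex_error(sprintf("sample '%s' has median %s; cannot median-normalize",
                        bad, meds[which(meds <= 0)[1L]]))
  }
  as_expr_matrix(sweep(unclass(m), 2L, mean(meds) / meds, `*`))
}

#' Quantile normalization
#'
#' Each sample's sorted values are replaced by the across-sample mean of
#' the values at that sort rank, so that afterwards every sample has an
#' identical empirical distribution.  Tied values within a sample receive
#' the mean of the rank-mean values their positions span.
#'
#' @param m An [expression_matrix()] with at least 2 samples.
#' @return The normalized [expression_matrix()].
#' @export
normalize_quantile <- function(m) {
  if (ncol(m) < 2L) gcoex_error("quantile normalization needs >= 2 samples")
  rank_means <- rowMeans(apply(unclass(m), 2L, sort))
  out <- apply(unclass(m), 2L, function(x) {
    v <- rank_means[rank(x, ties.method = "first")]
    stats::ave(v, match(x, x), FUN = mean)
  })
  dimnames(out) <- dimnames(m)
  as_expr_matrix(out)
}

#' Median-of-ratios (size factor) normalization
#'
#' Per-sample size factors are the medians of the ratios of each sample's
#' values to the per-gene geometric means across samples, computed over
#' genes expressed in every sample (any zero excludes a gene from the
#' reference set); each sample is then divided by its factor.  The factors
#' are delegated to the reference implementation of the method
#' (`DESeq2::estimateSizeFactorsForMatrix`) and then rescaled to geometric
#' mean 1, which makes the operation idempotent (re-normalizing a
#' normalized matrix changes nothing).
#'
#' @param m An [expression_matrix()].
#' @return List with elements `matrix` (normalized [expression_matrix()])
#'   and `size_factors` (named numeric, one per sample).
#' @export
normalize_median_of_ratios <- function(m) {
  all_pos <- apply(unclass(m) > 0, 1L, all)
  if (!any(all_pos)) {
    gcoex_error("no gene is positive in every sample; size factors undefined")
  }
  sf <- DESeq2::estimateSizeFactorsForMatrix(unclass(m))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(m)
  list(matrix = as_expr_matrix(sweep(unclass(m), 2L, sf, `/`)),
       size_factors = sf)
}

#' Trimmed mean of M-values (TMM) normalization
#'
#' Composition-aware scaling factors following the published TMM method
#' (via its reference implementation, `edgeR::calcNormFactors`): reference
#' sample chosen by upper-quartile proximity to the mean upper quartile;
#' per-sample log2 ratios (M) and average log intensities (A) computed over
#' genes positive in both sample and reference, doubly trimmed (30% on M,
#' 5% on A); the factor is 2 to the inverse-variance-weighted mean of the
#' retained M values, and factors are rescaled to have log-mean zero.
#' Normalized values are the input divided by (library size x factor),
#' i.e. library-fraction scale.
#'
#' @param m An [expression_matrix()] with >= 2 samples and positive
#'   library sizes (column sums).
#' @return List with elements `matrix` (normalized [expression_matrix()])
#'   and `scaling_factors` (named numeric, log-mean zero).
#' @export
normalize_tmm <- function(m) {
  if (ncol(m) < 2L) gcoex_error("TMM normalization needs >= 2 samples")
  lib <- colSums(unclass(m))
  if (any(lib <= 0)) {
    gcoex_error(sprintf("sample '%s' has library size 0",
                        colnames(m)[which(lib <= 0)[1L]]))
  }
  f <- edgeR::calcNormFactors(unclass(m), method = "TMM")
  if (any(!is.finite(f))) {
    gcoex_error(sprintf(
      "TMM factor undefined for sample '%s' (no gene positive in both it and the reference)",
      colnames(m)[which(!is.finite(f))[1L]]))
  }
  names(f) <- colnames(m)
  list(matrix = as_expr_matrix(sweep(unclass(m), 2L, lib * f, `/`)),
       scaling_factors = f)
}

#' Housekeeping-gene normalization
#'
#' Samples are rescaled so the median expression of a supplied
#' housekeeping-gene set is identical in every sample: sample j is scaled
#' by (mean across samples of the housekeeping medians) / (housekeeping
#' median of sample j).
#'
#' @param m An [expression_matrix()].
#' @param hk Character vector of housekeeping gene IDs; at least one must
#'   be present in the matrix (absent IDs trigger a warning, or an error if
#'   none remain).
#' @return The normalized [expression_matrix()].
#' @export
normalize_housekeeping <- function(m, hk) {
  hk <- unique(as.character(hk))
  missing <- setdiff(hk, rownames(m))
  present <- intersect(hk, rownames(m))
  if (length(present) == 0L) {
    gcoex_error(sprintf("no housekeeping gene found in matrix; missing: %s",
                        paste(missing, collapse = ", ")))
  }
  if (length(missing)) {
    gcoex_warning(sprintf("housekeeping genes absent from matrix: %s",
                          paste(missing, collapse = ", ")))
  }
  meds <- apply(unclass(m)[present, , drop = FALSE], 2L, stats::median)
  if (any(meds <= 0)) {
    gcoex_error(sprintf("sample '%s' has housekeeping median %s",
                        colnames(m)[which(meds <= 0)[1L]],
                        meds[which(meds <= 0)[1L]]))
  }
  as_expr_matrix(sweep(unclass(m), 2L, mean(meds) / meds, `*`))
}

#' Filter low-expression genes
#'
#' Low-expression genes add noise to a co-expression network; an empirical
#' default is to discard the lowest quarter of genes by mean expression.
#' `mode = "fraction"` drops the lowest `floor(value * n_genes)` genes by
#' the chosen statistic (ties broken stably by input row order);
#' `mode = "threshold"` keeps genes whose statistic is `>= value`.
#'
#' @param m An [expression_matrix()].
#' @param statistic `"mean"` or `"variance"` of each gene's values.
#' @param mode `"fraction"` (default) or `"threshold"`.
#' @param value Fraction in \[0, 1) or threshold; default drops the lowest
#'   quarter by mean.
#' @return The filtered [expression_matrix()] (row order preserved).
#' @export
filter_genes <- function(m, statistic = c("mean", "variance"),
                         mode = c("fraction", "threshold"), value = 0.25) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  stat <- switch(statistic,
                 mean = rowMeans(unclass(m)),
                 variance = apply(unclass(m), 1L, stats::var))
  keep <- if (mode == "fraction") {
    if (value < 0 || value >= 1) {
      gcoex_error("fraction must lie in [0, 1)")
    }
    n_drop <- floor(value * nrow(m))
    # order() is stable: ties at the boundary resolve by input row order
    drop_idx <- order(stat)[seq_len(n_drop)]
    setdiff(seq_len(nrow(m)), drop_idx)
  } else {
    which(stat >= value)
  }
  if (length(keep) == 0L) {
    gcoex_error("filter removed every gene")
  }
  as_expr_matrix(unclass(m)[sort(keep), , drop = FALSE])
}

#' Log2 transform with pseudocount
#'
#' Optional pretreatment (`log2(x + pseudocount)`) before Pearson
#' correlation on count-scale data; off by default since Spearman on raw
#' values is the recommended path for RNA-Seq.
#'
#' @param m An [expression_matrix()].
#' @param pseudocount Positive offset added before the log (default 1).
#' @return The transformed [expression_matrix()].
#' @export
log_transform <- function(m, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    gcoex_error("pseudocount must be > 0")
  }
  as_expr_matrix(log2(unclass(m) + pseudocount))
}
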