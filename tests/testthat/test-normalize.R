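test_that("median normalization equalizes sample medians", {
  m <- expr_fixture(matrix(c(1, 2, 3, 2, 4, 6), 3, 2))
  out <- normalize_median(m)
  expect_equal(unname(unclass(out)),
               matrix(c(1.5, 3, 4.5, 1.5, 3, 4.5), 3, 2))
  # all per-sample medians equal after normalization; idempotent
  expect_equal(unname(diff(apply(out, 2, median))), 0)
  expect_equal(unclass(normalize_median(out)), unclass(out),
               tolerance = 1e-12)
  # single sample and identical samples are fixed points
  one <- expr_fixture(matrix(c(1, 5, 9), 3, 1))
  expect_equal(unclass(normalize_median(one)), unclass(one))
  same <- expr_fixture(matrix(rep(c(1, 5, 9), 3), 3, 3))
  expect_equal(unclass(normalize_median(same)), unclass(same))
  # zero median is a named error
  zm <- expr_fixture(matrix(c(0, 0, 1, 1, 2, 3), 3, 2))
  expect_error(normalize_median(zm), "s1")
})

test_that("quantile normalization matches the rank-mean substitution", {
  m <- expr_fixture(matrix(c(5, 2, 3, 4, 1, 6), 3, 2), samples = c("A", "B"))
  out <- normalize_quantile(m)
  expect_equal(unname(unclass(out)),
               matrix(c(5.5, 1.5, 3.5, 3.5, 1.5, 5.5), 3, 2))
  # definitional: all sorted sample vectors identical
  expect_identical(as.numeric(sort(out[, 1])), as.numeric(sort(out[, 2])))
  same <- expr_fixture(matrix(rep(c(2, 7, 4), 2), 3, 2))
  expect_equal(unclass(normalize_quantile(same)), unclass(same))
  expect_error(normalize_quantile(expr_fixture(matrix(1:3, 3, 1))),
               ">= 2 samples")
})

test_that("quantile ties receive the mean of the spanned rank means", {
  # sample A has a 2-way tie at its two lowest positions
  m <- expr_fixture(matrix(c(1, 1, 5, 2, 4, 6), 3, 2))
  out <- normalize_quantile(m)
  rank_means <- rowMeans(cbind(sort(m[, 1]), sort(m[, 2])))
  expect_equal(unname(out[1:2, 1]), rep(mean(rank_means[1:2]), 2))
  expect_equal(unname(out[3, 1]), unname(rank_means[3]))
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(42)
  m <- expr_fixture(matrix(runif(60, 1, 100), 12, 5))
  expect_equal(unname(unclass(normalize_quantile(m))),
               unname(limma::normalizeQuantiles(unclass(m))),
               tolerance = 1e-12)
})

test_that("median-of-ratios reproduces hand-computed size factors", {
  m <- expr_fixture(matrix(c(2, 8, 4, 16), 2, 2))
  r <- normalize_median_of_ratios(m)
  expect_equal(unname(r$size_factors), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  expect_equal(unname(unclass(r$matrix)),
               matrix(rep(c(2 * sqrt(2), 8 * sqrt(2)), 2), 2, 2),
               tolerance = 1e-12)
  # identical samples: factors 1; idempotence; scale equivariance
  same <- expr_fixture(matrix(rep(c(3, 9, 27), 3), 3, 3))
  expect_equal(unname(normalize_median_of_ratios(same)$size_factors),
               rep(1, 3))
  twice <- normalize_median_of_ratios(r$matrix)
  expect_equal(unclass(twice$matrix), unclass(r$matrix), tolerance = 1e-12)
  # scaling one sample by c: factor ratios pick up c, and the normalized
  # matrix changes only by a global constant (the geometric means absorb
  # a factor c^(1/n_samples))
  scaled <- unclass(m); scaled[, 2] <- scaled[, 2] * 7
  r2 <- normalize_median_of_ratios(expr_fixture(scaled))
  expect_equal(r2$size_factors[[2]] / r2$size_factors[[1]],
               7 * r$size_factors[[2]] / r$size_factors[[1]],
               tolerance = 1e-12)
  ratio <- unclass(r2$matrix) / unclass(r$matrix)
  expect_equal(unname(ratio), matrix(sqrt(7), 2, 2), tolerance = 1e-12)
  # all-zero-containing genes: no reference gene -> error
  z <- expr_fixture(matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(normalize_median_of_ratios(z), "positive in every sample")
})

test_that("TMM factors are 1 for identical samples and absorb library-size shifts", {
  same <- expr_fixture(matrix(rep(c(10, 60, 30, 90, 5), 3), 5, 3))
  r <- normalize_tmm(same)
  expect_equal(unname(r$scaling_factors), rep(1, 3), tolerance = 1e-12)

  set.seed(3)
  a <- round(runif(50, 5, 500))
  m <- expr_fixture(cbind(a, 2 * a))
  r2 <- normalize_tmm(m)
  cs <- colSums(unclass(r2$matrix))
  expect_equal(cs[1], cs[2], ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(unclass(r2$matrix)[, 1], unclass(r2$matrix)[, 2],
               ignore_attr = TRUE, tolerance = 1e-9)

  expect_error(normalize_tmm(expr_fixture(matrix(1:4, 4, 1))), ">= 2")
})

test_that("TMM trimming removes a single extreme composition gene", {
  set.seed(8)
  base <- round(runif(20, 20, 200))
  # sample 2 is a clean 2x library-size shift (tiny distinct jitters keep
  # the M-value ranks well defined) plus one massive composition outlier
  b <- base * 2 * (1 + seq_len(20) * 1e-8)
  b[20] <- base[20] * 1000
  r <- normalize_tmm(expr_fixture(cbind(base, b)))
  norm <- unclass(r$matrix)
  # once the outlier is trimmed out of the factor, the 19 unperturbed genes
  # align across samples
  expect_equal(norm[1:19, 1], norm[1:19, 2], ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("housekeeping normalization equalizes housekeeping medians", {
  vals <- matrix(c(2, 4, 10, 4, 8, 3), 3, 2)
  m <- expr_fixture(vals, genes = c("hk1", "hk2", "g1"))
  out <- normalize_housekeeping(m, c("hk1", "hk2"))
  # hand-derived factors: medians 3 and 6, mean 4.5 -> 1.5 and 0.75
  expect_equal(unname(unclass(out)), vals %*% diag(c(1.5, 0.75)))
  meds <- apply(unclass(out)[c("hk1", "hk2"), ], 2, median)
  expect_equal(diff(meds), 0, ignore_attr = TRUE)

  expect_warning(out2 <- normalize_housekeeping(m, c("hk1", "hk2", "nope")),
                 "nope")
  expect_equal(unclass(out2), unclass(out))
  expect_error(normalize_housekeeping(m, c("absent1", "absent2")),
               "absent1.*absent2")
})

test_that("gene filtering drops by fraction or threshold with stable ties", {
  set.seed(9)
  vals <- matrix(runif(32, 1, 10), 8, 4)
  m <- expr_fixture(vals)
  kept <- filter_genes(m, "mean", "fraction", 0.25)
  expect_equal(nrow(kept), 6L)  # floor(0.25 * 8) = 2 dropped
  dropped <- setdiff(rownames(m), rownames(kept))
  gene_means <- rowMeans(unclass(m))
  expect_equal(sort(unname(gene_means[dropped])),
               unname(sort(gene_means)[1:2]))
  # kept genes preserve input order
  expect_identical(rownames(kept),
                   rownames(m)[rownames(m) %in% rownames(kept)])

  expect_equal(nrow(filter_genes(m, "mean", "threshold", 0)), 8L)
  withzero <- expr_fixture(rbind(vals, 0))
  expect_false("g9" %in% rownames(filter_genes(withzero, "mean",
                                               "threshold", 0.5)))
  expect_error(filter_genes(m, "mean", "fraction", 1), "fraction")
  expect_error(filter_genes(m, "mean", "threshold", 1e9), "every gene")
  # variance statistic: constant gene goes first
  flat <- expr_fixture(rbind(vals, rep(5, 4)))
  expect_false("g9" %in% rownames(filter_genes(flat, "variance",
                                               "fraction", 0.2)))
})

test_that("scaling normalizations preserve within-sample value ratios", {
  set.seed(21)
  m <- expr_fixture(matrix(runif(40, 1, 100), 10, 4))
  ratio <- function(x) x[2:10, ] / x[rep(1, 9), ]
  for (out in list(normalize_median(m),
                   normalize_median_of_ratios(m)$matrix,
                   normalize_tmm(m)$matrix,
                   normalize_housekeeping(m, c("g1", "g2")))) {
    expect_equal(ratio(unclass(out)), ratio(unclass(m)), tolerance = 1e-12)
  }
})

test_that("log transform applies log2(x + pseudocount)", {
  m <- expr_fixture(matrix(c(0, 1, 3, 7), 2, 2))
  out <- log_transform(m)
  expect_equal(unname(unclass(out)), matrix(c(0, 1, 2, 3), 2, 2))
  expect_error(log_transform(m, pseudocount = 0), "pseudocount")
  # per-gene monotonicity
  expect_equal(order(out[1, ]), order(m[1, ]))
})
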