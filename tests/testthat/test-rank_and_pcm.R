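test_that("rank_transform assigns midranks and rejects constant columns", {
  sm <- signal_matrix(cbind(a = c(3.2, 1.1, 2.5), b = c(5, 5, 1)))
  r <- rank_transform(sm)
  expect_equal(unname(r$values[, "a"]), c(3, 1, 2))
  expect_equal(unname(r$values[, "b"]), c(2.5, 2.5, 1))
  expect_identical(r$scale_tag, "rank")
  const <- signal_matrix(cbind(a = c(1, 2, 3), b = c(7, 7, 7)))
  expect_error(rank_transform(const), class = "spcnet_constant_column")
})

test_that("rank_transform is invariant under strictly monotone maps", {
  sm <- random_signal(50, 4, seed = 10)
  sm$values <- abs(sm$values) + 0.1
  pos <- signal_matrix(sm$values, sm$sample_ids, sm$variable_names,
                       "normalized")
  logged <- signal_matrix(log(pos$values), pos$sample_ids,
                          pos$variable_names, "normalized")
  expect_equal(rank_transform(pos)$values, rank_transform(logged)$values)
})

test_that("correlation_matrix matches the definitional Pearson sum formula", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  # definitional oracle
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  C <- correlation_matrix(signal_matrix(cbind(X = x, Y = y, Z = -x)))
  expect_equal(C$values["X", "Y"], r_def)
  expect_equal(C$values["X", "X"], 1)
  expect_equal(C$values["X", "Z"], -1)
  expect_identical(C$kind, "correlation")
})

test_that("partial correlations: identity, p = 2, and equicorrelated p = 3", {
  I3 <- assoc_matrix(diag(3), "correlation", n_samples = 100)
  expect_equal(partial_correlation_matrix(I3)$values, diag(3))

  C2 <- assoc_matrix(matrix(c(1, 0.4, 0.4, 1), 2), "correlation",
                     n_samples = 50)
  expect_equal(partial_correlation_matrix(C2)$values[1, 2], 0.4)

  C3 <- matrix(0.5, 3, 3); diag(C3) <- 1
  P3 <- partial_correlation_matrix(assoc_matrix(C3, "correlation", 100))
  expect_equal(P3$values[upper.tri(P3$values)], rep(1 / 3, 3),
               tolerance = 1e-12)
  expect_equal(P3$values[1, 2], oracle_first_order(0.5, 0.5, 0.5),
               tolerance = 1e-10)
  expect_identical(P3$n_controls, 1L)
})

test_that("singular correlation matrices are fatal with guidance", {
  C <- matrix(c(1, 1, 1, 1), 2)
  expect_error(
    partial_correlation_matrix(assoc_matrix(C, "correlation", 10)),
    class = "spcnet_singular")
})

test_that("inversion equals residual-regression partials on random instances", {
  for (s in 1:20) {
    p <- withr::with_seed(s, sample(3:8, 1))
    X <- random_signal(withr::with_seed(s + 50, sample(50:300, 1)), p,
                       seed = s + 100)$values
    P <- partial_correlation_matrix(
      assoc_matrix(cor(X), "correlation", nrow(X)))$values
    expect_equal(P, oracle_partial_residuals(X), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("inversion matches the first-order recursion for p = 3", {
  for (s in 1:25) {
    X <- random_signal(60, 3, seed = 300 + s)$values
    C <- cor(X)
    P <- partial_correlation_matrix(assoc_matrix(C, "correlation", 60))$values
    expect_equal(P[1, 2], oracle_first_order(C[1, 2], C[1, 3], C[2, 3]),
                 tolerance = 1e-10)
    expect_equal(P[1, 3], oracle_first_order(C[1, 3], C[1, 2], C[3, 2]),
                 tolerance = 1e-10)
  }
})

test_that("empirical partial correlations converge to the precision truth", {
  truth <- random_sparse_precision(6, 7, seed = 9)
  X <- sample_ggm(truth, 1e5, seed = 10)
  P <- partial_correlation_matrix(
    assoc_matrix(cor(X$values), "correlation", 1e5))$values
  expect_lt(max(abs(P - truth$partial_corr_true)), 0.02)
})

test_that("fisher_z_significance follows the closed-form normal oracle", {
  # r = 0 -> p = 1
  C <- assoc_matrix(diag(2), "correlation", 100)
  sig0 <- fisher_z_significance(C)
  expect_equal(sig0$pvalues[1, 2], 1)

  # r = 0.1, n = 1000, 21 controls -> p = 2 * (1 - Phi(atanh(0.1) * sqrt(976)))
  A <- assoc_matrix(matrix(c(1, 0.1, 0.1, 1), 2), "partial_correlation",
                    n_samples = 1000, n_controls = 21)
  sig <- fisher_z_significance(A)
  expect_equal(sig$pvalues[1, 2], 2 * (1 - pnorm(atanh(0.1) * sqrt(976))),
               tolerance = 1e-12)
  expect_true(all(sig$qvalues[upper.tri(sig$qvalues)] >=
                    sig$pvalues[upper.tri(sig$pvalues)]))

  # |r| = 1 degenerates to p = 0 with a warning
  B <- assoc_matrix(matrix(c(1, 1, 1, 1), 2), "partial_correlation",
                    n_samples = 100, n_controls = 0)
  expect_warning(sigd <- fisher_z_significance(B), "p-value set to 0")
  expect_equal(sigd$pvalues[1, 2], 0)

  # insufficient samples for the degrees of freedom
  expect_error(fisher_z_significance(
    assoc_matrix(diag(2), "partial_correlation", n_samples = 5,
                 n_controls = 3)), class = "spcnet_df")
})

test_that("null p-values are approximately uniform (KS)", {
  pvals <- unlist(lapply(1:200, function(s) {
    res <- pcm_pipeline(random_signal(200, 5, seed = 7000 + s))
    res$sig$pvalues[upper.tri(res$sig$pvalues)]
  }))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("bh_adjust matches the step-up oracle and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  for (s in 1:50) {
    pv <- withr::with_seed(s, runif(sample(1:50, 1)))
    expect_identical(bh_adjust(pv), oracle_bh_stepup(pv))
    expect_equal(bh_adjust(pv), stats::p.adjust(pv, "BH"))
  }
  # m larger than the number of observed p-values
  expect_equal(bh_adjust(c(0.01, 0.1), m = 4), oracle_bh_stepup(c(0.01, 0.1), m = 4))
})

test_that("pipeline is exactly invariant under monotone marginal transforms", {
  sm <- random_signal(80, 4, seed = 77)
  warped <- signal_matrix(exp(sm$values / 2), sm$sample_ids,
                          sm$variable_names, "normalized")
  a <- pcm_pipeline(sm)
  b <- pcm_pipeline(warped)
  expect_identical(a$pcm$values, b$pcm$values)
  expect_identical(a$sig$qvalues, b$sig$qvalues)
})
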