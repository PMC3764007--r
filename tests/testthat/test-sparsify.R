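test_that("fold_split partitions samples into near-equal folds, reproducibly", {
  f1 <- fold_split(10, 10, seed = 1)
  expect_equal(sort(unique(f1)), 1:10)
  expect_true(all(table(f1) == 1))

  f2 <- fold_split(103, 10, seed = 2)
  expect_equal(length(f2), 103)
  expect_true(all(table(f2) %in% c(10, 11)))

  expect_identical(fold_split(103, 10, seed = 3), fold_split(103, 10, seed = 3))
  expect_false(identical(fold_split(103, 10, seed = 3),
                         fold_split(103, 10, seed = 4)))
})

test_that("cv_prediction_error matches hand-computed OLS cases", {
  # 1-predictor toy: train (x, y) = (1,2),(2,4),(3,6); test (4, 9); yhat = 8
  train <- signal_matrix(cbind(x = c(1, 2, 3), y = c(2, 4, 6)))
  test <- signal_matrix(cbind(x = 4, y = 9))
  P_only_y <- matrix(c(0, 0, 1, 0), 2, 2)  # column 2 (y) has co-variable x
  # error_x is intercept-only: (4 - mean(1,2,3))^2 = 4; error_y = (9 - 8)^2 = 1
  expect_equal(2 * cv_prediction_error(train, test, P_only_y) - 4, 1)
  # symmetric pattern: error_y = 1, error_x = (4 - 4.5)^2 = 0.25
  P_sym <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(cv_prediction_error(train, test, P_sym), (1 + 0.25) / 2)

  # empty predictor sets: intercept-only, mean squared deviation from train mean
  P0 <- matrix(0, 2, 2)
  expect_equal(cv_prediction_error(train, test, P0),
               ((4 - 2)^2 + (9 - 4)^2) / 2)

  # exact linear relation: near-zero error
  tr <- signal_matrix(cbind(x = 1:10, y = 2 * (1:10)))
  te <- signal_matrix(cbind(x = 11:12, y = 2 * (11:12)))
  expect_lt(cv_prediction_error(tr, te, P_sym), 1e-20)
})

test_that("internal Gram-matrix error path agrees with cv_prediction_error", {
  for (s in 1:5) {
    X <- random_signal(60, 5, seed = 400 + s)$values
    tr <- X[1:40, ]; te <- X[41:60, ]
    qmat <- withr::with_seed(500 + s, {
      q <- matrix(runif(25), 5, 5); q <- (q + t(q)) / 2; diag(q) <- Inf; q
    })
    thresholds <- c(0.9, 0.5, 0.2, 0.05, 0)
    fast <- spcnet:::cv_error_path(tr, te, qmat, thresholds)
    slow <- vapply(thresholds, function(t) {
      sp <- (qmat <= t) * 1; diag(sp) <- 0
      cv_prediction_error(signal_matrix(tr), signal_matrix(te), sp)
    }, numeric(1))
    expect_equal(fast, slow, tolerance = 1e-8)
    # monotone sparsification: lowering the threshold never adds edges
    masks <- lapply(thresholds, function(t) qmat <= t)
    for (k in seq_along(masks)[-1]) {
      expect_true(all(masks[[k]] <= masks[[k - 1]]))
    }
  }
})

test_that("select_threshold applies the 10%-of-range rule", {
  curve <- list(thresholds = c(1e-1, 1e-2, 1e-3, 1e-4),
                errors = c(0.40, 0.42, 0.45, 0.90))
  expect_equal(select_threshold(curve, tolerance = 0.10), 1e-3)
  # flat curve: lowest threshold in the grid
  flat <- list(thresholds = c(0.5, 0.05, 0.005), errors = rep(1, 3))
  expect_equal(select_threshold(flat), 0.005)
  # tolerance 0: lowest threshold attaining the minimum
  expect_equal(select_threshold(curve, tolerance = 0), 1e-1)
  tie <- list(thresholds = c(0.1, 0.01), errors = c(0.4, 0.4))
  expect_equal(select_threshold(tie, tolerance = 0), 0.01)
})

test_that("build_mask votes edges by fold support", {
  p <- 4
  mk <- function(n_present, i = 1, j = 2) {
    lapply(1:10, function(f) {
      m <- matrix(FALSE, p, p)
      if (f <= n_present) m[i, j] <- m[j, i] <- TRUE
      m
    })
  }
  expect_true(build_mask(mk(7))$keep[1, 2])    # 7/10 kept
  expect_true(build_mask(mk(10))$keep[1, 2])   # 10/10 kept
  expect_false(build_mask(mk(6))$keep[1, 2])   # 6/10 dropped
  expect_false(build_mask(mk(0))$keep[1, 2])
  m <- build_mask(mk(8))
  expect_equal(m$support[1, 2], 8L)
  expect_identical(m$provenance[1, 2], "masked")
  expect_false(any(diag(m$keep)))
})

test_that("complete_special_node adds lowest-q edges up to the target degree", {
  vars <- c("mRNA", "A", "B", "C", "D", "E")
  p <- length(vars)
  keep <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  keep["mRNA", "D"] <- keep["D", "mRNA"] <- TRUE
  keep["mRNA", "E"] <- keep["E", "mRNA"] <- TRUE
  mask <- structure(list(keep = keep, support = keep * 10L,
                         provenance = ifelse(keep, "masked", ""),
                         n_folds = 10L, min_support = 7L),
                    class = "edge_mask")
  qm <- matrix(1, p, p, dimnames = list(vars, vars))
  qm["mRNA", c("A", "B", "C")] <- c(0.3, 0.1, 0.2)
  qm[, "mRNA"] <- qm["mRNA", ]
  out <- complete_special_node(mask, fake_sig(qm), node = "mRNA",
                               target_degree = 4)
  expect_true(out$keep["mRNA", "B"])
  expect_true(out$keep["mRNA", "C"])
  expect_false(out$keep["mRNA", "A"])
  expect_identical(out$provenance["mRNA", "B"], "mrna_completed")
  expect_identical(out$provenance["mRNA", "D"], "masked")

  # already at or above target: unchanged
  out2 <- complete_special_node(out, fake_sig(qm), "mRNA", 4)
  expect_identical(out2$keep, out$keep)

  # saturation: fewer candidates than needed
  vars3 <- c("mRNA", "A", "B", "C")
  keep3 <- matrix(FALSE, 4, 4, dimnames = list(vars3, vars3))
  mask3 <- structure(list(keep = keep3, support = keep3 * 0L,
                          provenance = ifelse(keep3, "masked", ""),
                          n_folds = 10L, min_support = 7L),
                     class = "edge_mask")
  qm3 <- matrix(0.5, 4, 4, dimnames = list(vars3, vars3))
  expect_warning(out3 <- complete_special_node(mask3, fake_sig(qm3), "mRNA", 4),
                 "candidate")
  expect_equal(sum(out3$keep["mRNA", ]), 3)

  expect_error(complete_special_node(mask, fake_sig(qm), "nope", 4),
               class = "spcnet_missing_node")
})

test_that("spcn recovers chain structure and returns empty nets under independence", {
  # 3-variable chain: edges 1-2 and 2-3, no 1-3
  X <- sample_ggm(chain_truth(), 5000, seed = 21)
  net <- spcn(X, seed = 22)
  expect_true(net$mask$keep["V1", "V2"])
  expect_true(net$mask$keep["V2", "V3"])
  expect_false(net$mask$keep["V1", "V3"])

  # independence model: diagonal precision
  ind <- random_sparse_precision(6, 0, seed = 23)
  Xi <- sample_ggm(ind, 5000, seed = 24)
  neti <- spcn(Xi, seed = 25)
  expect_equal(sum(neti$weights[upper.tri(neti$weights)] != 0), 0)
})

test_that("spcn runs are deterministic given data and seed", {
  truth <- random_sparse_precision(6, 6, seed = 31)
  X <- sample_ggm(truth, 800, seed = 32)
  n1 <- spcn(X, n_folds = 5, min_support = 4, seed = 33)
  n2 <- spcn(X, n_folds = 5, min_support = 4, seed = 33)
  expect_identical(n1$weights, n2$weights)
  expect_identical(n1$mask$support, n2$mask$support)
})

test_that("kept edges (pre-completion) are q-significant in >= min_support folds", {
  truth <- random_sparse_precision(7, 8, seed = 41)
  X <- sample_ggm(truth, 1000, seed = 42)
  net <- spcn(X, n_folds = 5, min_support = 4, seed = 43)
  kept <- which(net$mask$keep & upper.tri(net$mask$keep))
  expect_true(all(net$mask$support[kept] >= 4))
})
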