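#' Assign samples to cross-validation folds
#'
#' Random partition of `1..n_samples` into `n_folds` disjoint test sets of
#' near-equal size (sizes differ by at most one), deterministic given `seed`.
#'
#' @param n_samples Number of samples.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..n_folds`, one per sample.
#' @export
fold_split <- function(n_samples, n_folds = 10, seed = 1) {
  stopifnot(n_folds >= 2, n_samples >= n_folds)
  withr::with_seed(as.integer(seed),
                   sample(rep_len(seq_len(n_folds), n_samples)))
}

#' Cross-validated prediction error of a sparse partial correlation matrix
#'
#' For each variable, an ordinary least squares regression (with intercept)
#' is fitted on the training set using as predictors only the co-variables
#' with a nonzero entry in that variable's column of `sparse_P`. The mean
#' squared prediction error on the test set is averaged over all variables;
#' variables with no co-variables get an intercept-only model.
#'
#' @param train,test [signal_matrix()] objects over the same variables.
#' @param sparse_P A p x p matrix (or [assoc_matrix()]) whose zero pattern
#'   defines the co-variable sets; computed on the training data only.
#' @return Mean over variables of the test-set mean squared error.
#' @export
cv_prediction_error <- function(train, test, sparse_P) {
  if (inherits(sparse_P, "assoc_matrix")) sparse_P <- sparse_P$values
  Xtr <- if (inherits(train, "signal_matrix")) train$values else as.matrix(train)
  Xte <- if (inherits(test, "signal_matrix")) test$values else as.matrix(test)
  stopifnot(ncol(Xtr) == ncol(Xte), ncol(Xtr) == ncol(sparse_P))
  p <- ncol(Xtr)
  errs <- vapply(seq_len(p), function(i) {
    covars <- setdiff(which(sparse_P[, i] != 0), i)
    A_tr <- cbind(1, Xtr[, covars, drop = FALSE])
    fit <- stats::lm.fit(A_tr, Xtr[, i])
    beta <- fit$coefficients
    if (anyNA(beta)) {
      warning("singular co-variable design; dropping redundant columns")
      beta[is.na(beta)] <- 0
    }
    pred <- cbind(1, Xte[, covars, drop = FALSE]) %*% beta
    mean((Xte[, i] - pred)^2)
  }, numeric(1))
  mean(errs)
}

#' Pick the sparsest q-threshold within tolerance of the minimum error
#'
#' With abundant data the prediction error increases continuously as the
#' network is sparsified, so the error minimum alone would select the full
#' matrix. Instead the lowest (sparsest) threshold t is chosen such that
#' E(t) does not exceed the minimum error by more than `tolerance` of the
#' min-max error range.
#'
#' @param curve A `cv_error_curve` (list with `thresholds` in decreasing
#'   order and matching `errors`), as produced inside [spcn()], or any list
#'   with those two fields.
#' @param tolerance Fraction of the error range allowed above the minimum
#'   (default 0.10).
#' @return The selected q-value threshold.
#' @export
select_threshold <- function(curve, tolerance = 0.10) {
  stopifnot(length(curve$thresholds) == length(curve$errors),
            length(curve$errors) >= 1, all(is.finite(curve$errors)),
            tolerance >= 0, tolerance <= 1)
  e_min <- min(curve$errors)
  e_max <- max(curve$errors)
  cutoff <- e_min + tolerance * (e_max - e_min)
  min(curve$thresholds[curve$errors <= cutoff])
}

#' Combine per-fold sparse matrices into an edge mask by support voting
#'
#' @param fold_sparse_matrices List of p x p logical matrices, one per fold,
#'   `TRUE` where the edge survived that fold's selected threshold.
#' @param min_support Minimum number of folds an edge must appear in to be
#'   kept (default 7 of 10).
#' @return An object of class `edge_mask` with logical `keep`, integer
#'   `support`, and character `provenance` matrices.
#' @export
build_mask <- function(fold_sparse_matrices, min_support = 7) {
  stopifnot(length(fold_sparse_matrices) >= 1)
  dims <- vapply(fold_sparse_matrices, function(m) ncol(m), integer(1))
  stopifnot(length(unique(dims)) == 1, min_support >= 1,
            min_support <= length(fold_sparse_matrices))
  support <- Reduce(`+`, lapply(fold_sparse_matrices, function(m) m * 1L))
  diag(support) <- 0L
  storage.mode(support) <- "integer"
  keep <- support >= min_support
  provenance <- matrix("", ncol(keep), ncol(keep), dimnames = dimnames(keep))
  provenance[keep] <- "masked"
  structure(list(keep = keep, support = support, provenance = provenance,
                 n_folds = length(fold_sparse_matrices),
                 min_support = as.integer(min_support)),
            class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("edge_mask: %d/%d edges kept (support >= %d of %d folds)\n",
              sum(x$keep[upper.tri(x$keep)]), sum(upper.tri(x$keep)),
              x$min_support, x$n_folds))
  invisible(x)
}

#' Complete a node of special interest up to a target degree
#'
#' Signals concentrated in a small part of the analysed window (expression
#' being the motivating case) can end up with few network connections even
#' when real associations exist. If the named node has fewer than
#' `target_degree` kept edges, edges to the unconnected variables with the
#' smallest full-data q-values are added until the target is reached; added
#' edges are tagged `mrna_completed`.
#'
#' @param mask An [build_mask()] result; `keep` must carry variable dimnames.
#' @param Q A `significance_matrices` object from the full data.
#' @param node Variable name to complete (default `"mRNA"`).
#' @param target_degree Degree to complete up to (default 4).
#' @return The updated `edge_mask`.
#' @export
complete_special_node <- function(mask, Q, node = "mRNA", target_degree = 4) {
  stopifnot(inherits(mask, "edge_mask"))
  vars <- colnames(mask$keep)
  if (is.null(vars)) vars <- Q$variable_names
  if (!node %in% vars) {
    abort_spcn(sprintf("special node '%s' not among variables", node),
               "spcnet_missing_node")
  }
  i <- match(node, vars)
  degree <- sum(mask$keep[i, ])
  if (degree >= target_degree) return(mask)
  candidates <- setdiff(which(!mask$keep[i, ]), i)
  need <- target_degree - degree
  if (length(candidates) < need) {
    warning(sprintf("only %d candidate edges available to complete '%s' (need %d)",
                    length(candidates), node, need))
    need <- length(candidates)
  }
  qv <- Q$qvalues[i, candidates]
  add <- candidates[order(qv)][seq_len(need)]
  for (j in add) {
    mask$keep[i, j] <- mask$keep[j, i] <- TRUE
    mask$provenance[i, j] <- mask$provenance[j, i] <- "mrna_completed"
  }
  mask
}

# Threshold grid for one training fold: the sorted unique q-values, thinned
# to at most max_grid log-spaced points when larger, always retaining both
# extremes; 0 is appended so that the empty network is attainable.
threshold_grid <- function(qvals, max_grid = 200) {
  qs <- sort(unique(qvals))
  if (length(qs) > max_grid) {
    lo <- max(min(qs), .Machine$double.xmin)
    marks <- exp(seq(log(lo), log(max(qs)), length.out = max_grid))
    idx <- unique(pmax(findInterval(marks, qs), 1L))
    qs <- sort(unique(c(qs[idx], min(qs), max(qs))))
  }
  c(rev(qs), 0)
}

# Per-fold error sweep on the q-threshold grid, computed from Gram matrices
# so its cost does not grow with n per threshold. Identical (up to numerics)
# to calling cv_prediction_error() at each threshold. Co-variable sets are
# nested along the sweep, so errors are cached per (variable, set).
cv_error_path <- function(Xtr, Xte, qmat, thresholds) {
  p <- ncol(Xtr)
  Atr <- cbind(1, Xtr)
  Ate <- cbind(1, Xte)
  Gtr <- crossprod(Atr)
  Gte <- crossprod(Ate)
  n_te <- nrow(Xte)
  cache <- new.env(parent = emptyenv())
  var_error <- function(i, covars) {
    key <- paste0(i, ":", paste(covars, collapse = ","))
    if (exists(key, envir = cache, inherits = FALSE)) return(cache[[key]])
    sel <- c(1L, covars + 1L)
    yi <- i + 1L
    beta <- tryCatch(solve(Gtr[sel, sel, drop = FALSE], Gtr[sel, yi]),
                     error = function(e) {
                       b <- qr.coef(qr(Gtr[sel, sel, drop = FALSE]),
                                    Gtr[sel, yi])
                       b[is.na(b)] <- 0
                       b
                     })
    err <- (Gte[yi, yi] - 2 * sum(beta * Gte[sel, yi]) +
              drop(crossprod(beta, Gte[sel, sel, drop = FALSE] %*% beta))) / n_te
    cache[[key]] <- max(err, 0)
    cache[[key]]
  }
  errors <- vapply(thresholds, function(t) {
    mean(vapply(seq_len(p), function(i) {
      covars <- setdiff(which(qmat[, i] <= t), i)
      var_error(i, covars)
    }, numeric(1)))
  }, numeric(1))
  errors
}

#' Build a sparse partial correlation network
#'
#' Full pipeline: the matrix is rank-transformed once, then split into
#' `n_folds` cross-validation folds. On each training fold a partial
#' correlation matrix and its q-values are computed; a decreasing sweep of
#' q-value thresholds produces increasingly sparse matrices, each scored by
#' the mean test-fold prediction error of per-variable linear regressions on
#' the surviving co-variables. The sparsest threshold whose error stays
#' within `tolerance` of the min-max error range is selected per fold, and
#' an edge is kept if it survives in at least `min_support` folds. The mask
#' is applied to the full-data partial correlation matrix; optionally a
#' special node (e.g. `"mRNA"`) is completed up to `special_degree` edges
#' using full-data q-values.
#'
#' @param X A [signal_matrix()].
#' @param n_folds Number of cross-validation folds (default 10).
#' @param min_support Minimum per-edge fold support (default 7).
#' @param tolerance Error-range tolerance for threshold selection
#'   (default 0.10).
#' @param special_node Optional variable name to complete (default `NULL`,
#'   i.e. no completion).
#' @param special_degree Completion target degree (default 4).
#' @param df_offset Fisher-z degrees-of-freedom constant (default 3).
#' @param seed Integer seed governing the fold assignment.
#' @param max_grid Cap on the number of threshold grid points per fold.
#' @param rank Rank-transform the input first (default TRUE).
#' @return An object of class `spcn`: list with `weights` (masked signed
#'   partial correlations), `pcm`, `sig`, `mask`, per-fold `cv` curves and
#'   selected thresholds, `variable_names`, and the `config` used.
#' @export
spcn <- function(X, n_folds = 10, min_support = 7, tolerance = 0.10,
                 special_node = NULL, special_degree = 4, df_offset = 3,
                 seed = 1, max_grid = 200, rank = TRUE) {
  stopifnot(inherits(X, "signal_matrix"),
            min_support >= 1, min_support <= n_folds,
            tolerance >= 0, tolerance <= 1)
  Xr <- if (rank) rank_transform(X) else X
  vals <- Xr$values
  n <- nrow(vals)
  p <- ncol(vals)
  folds <- fold_split(n, n_folds, seed)
  fold_sparse <- vector("list", n_folds)
  cv_curves <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    Xtr <- vals[tr, , drop = FALSE]
    Xte <- vals[!tr, , drop = FALSE]
    C_tr <- assoc_matrix((cor(Xtr) + t(cor(Xtr))) / 2, "correlation",
                         n_samples = nrow(Xtr))
    P_tr <- partial_correlation_matrix(C_tr)
    sig_tr <- fisher_z_significance(P_tr, df_offset = df_offset)
    qmat <- sig_tr$qvalues
    diag(qmat) <- Inf
    thresholds <- threshold_grid(qmat[upper.tri(qmat)], max_grid = max_grid)
    errors <- cv_error_path(Xtr, Xte, qmat, thresholds)
    curve <- structure(list(thresholds = thresholds, errors = errors,
                            e_min = min(errors), e_max = max(errors)),
                       class = "cv_error_curve")
    t_sel <- select_threshold(curve, tolerance = tolerance)
    curve$selected <- t_sel
    cv_curves[[f]] <- curve
    sparse <- qmat <= t_sel
    diag(sparse) <- FALSE
    fold_sparse[[f]] <- sparse
  }
  mask <- build_mask(fold_sparse, min_support = min_support)
  full <- pcm_pipeline(Xr, rank = FALSE, df_offset = df_offset)
  if (!is.null(special_node)) {
    mask <- complete_special_node(mask, full$sig, node = special_node,
                                  target_degree = special_degree)
  }
  weights <- full$pcm$values * mask$keep
  diag(weights) <- 0
  structure(list(weights = weights, pcm = full$pcm, sig = full$sig,
                 mask = mask, cv = cv_curves,
                 variable_names = Xr$variable_names,
                 config = list(n_folds = n_folds, min_support = min_support,
                               tolerance = tolerance,
                               special_node = special_node,
                               special_degree = special_degree,
                               df_offset = df_offset, seed = seed,
                               max_grid = max_grid, rank = rank)),
            class = "spcn")
}

#' @export
print.spcn <- function(x, ...) {
  ut <- upper.tri(x$weights)
  kept <- sum(x$weights[ut] != 0)
  cat(sprintf("sparse partial correlation network: %d variables, %d edges (of %d possible)\n",
              length(x$variable_names), kept, sum(ut)))
  cat(sprintf("folds = %d, min support = %d, tolerance = %.2f, seed = %d\n",
              x$config$n_folds, x$config$min_support, x$config$tolerance,
              x$config$seed))
  invisible(x)
}

#' Edge table of a sparse partial correlation network
#'
#' @param x An `spcn` object.
#' @return data.frame with one row per kept edge: `var_a`, `var_b`,
#'   `partial_correlation`, `q_value`, `support_count`, `provenance`.
#' @export
spcn_edges <- function(x) {
  stopifnot(inherits(x, "spcn"))
  keep <- x$mask$keep
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  vars <- x$variable_names
  data.frame(
    var_a = vars[idx[, 1]],
    var_b = vars[idx[, 2]],
    partial_correlation = x$pcm$values[idx],
    q_value = x$sig$qvalues[idx],
    support_count = x$mask$support[idx],
    provenance = x$mask$provenance[idx],
    stringsAsFactors = FALSE
  )
}
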