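#' Random sparse precision matrix with known edge set
#'
#' Constructs a Gaussian graphical model: a random edge set of the requested
#' size, off-diagonal precision entries of uniform magnitude with random
#' signs, and a diagonal of (row-wise absolute sum + margin), which makes
#' the matrix strictly diagonally dominant and hence positive definite. The
#' implied true partial correlations are `-omega_ij / sqrt(omega_ii
#' omega_jj)`; edge sets whose induced partial correlations fall below
#' `min_abs_partial` in magnitude are resampled (bounded retries).
#'
#' @param p Number of variables.
#' @param n_edges Number of edges (nonzero off-diagonal pairs).
#' @param min_abs_partial Minimum absolute true partial correlation on the
#'   edges (default 0.1).
#' @param seed Integer seed.
#' @param margin Diagonal dominance margin, in units of the off-diagonal
#'   magnitude (default 1).
#' @param max_tries Retry budget before giving up (default 100).
#' @return An object of class `ggm_truth`: `precision`, `edge_set`
#'   (2-column index matrix, i < j), `partial_corr_true`,
#'   `variable_names`.
#' @export
random_sparse_precision <- function(p, n_edges, min_abs_partial = 0.1,
                                    seed = 1, margin = 1, max_tries = 100) {
  n_pairs <- p * (p - 1) / 2
  stopifnot(p >= 2, n_edges >= 0, n_edges <= n_pairs, margin > 0)
  pairs <- upper_pairs(p)
  vars <- paste0("V", seq_len(p))
  for (try in seq_len(max_tries)) {
    res <- withr::with_seed(derive_seed(seed, try), {
      chosen <- if (n_edges > 0) sort(sample.int(n_pairs, n_edges)) else integer(0)
      omega <- matrix(0, p, p)
      if (n_edges > 0) {
        signs <- sample(c(-1, 1), n_edges, replace = TRUE)
        ij <- pairs[chosen, , drop = FALSE]
        omega[ij] <- signs
        omega[ij[, c(2, 1), drop = FALSE]] <- signs
      }
      diag(omega) <- rowSums(abs(omega)) + margin
      list(omega = omega, chosen = chosen)
    })
    omega <- res$omega
    d <- sqrt(diag(omega))
    pc <- -omega / tcrossprod(d)
    diag(pc) <- 1
    ok_pd <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) > 0
    edge_set <- pairs[res$chosen, , drop = FALSE]
    ok_mag <- n_edges == 0 ||
      min(abs(pc[edge_set])) >= min_abs_partial
    if (ok_pd && ok_mag) {
      dimnames(omega) <- dimnames(pc) <- list(vars, vars)
      return(structure(list(precision = omega, edge_set = edge_set,
                            partial_corr_true = pc, variable_names = vars),
                       class = "ggm_truth"))
    }
  }
  abort_spcn(sprintf(
    "could not build a precision matrix with %d edges and |partial| >= %g in %d tries (density too high for the requested magnitude)",
    n_edges, min_abs_partial, max_tries), "spcnet_infeasible")
}

#' @export
print.ggm_truth <- function(x, ...) {
  cat(sprintf("ggm_truth: %d variables, %d edges, min |true partial| = %.3f\n",
              ncol(x$precision), nrow(x$edge_set),
              if (nrow(x$edge_set)) min(abs(x$partial_corr_true[x$edge_set])) else NA))
  invisible(x)
}

#' Sample from a Gaussian graphical model
#'
#' Draws n observations from the zero-mean multivariate normal whose
#' covariance is the inverse of the truth's precision matrix.
#'
#' @param truth A [random_sparse_precision()] result.
#' @param n Number of samples (>= p + 4).
#' @param seed Integer seed.
#' @return A [signal_matrix()] (`scale_tag = "normalized"`, i.e. continuous
#'   signal ready for ranking).
#' @export
sample_ggm <- function(truth, n, seed = 1) {
  stopifnot(inherits(truth, "ggm_truth"))
  p <- ncol(truth$precision)
  stopifnot(n >= p + 4)
  sigma <- solve(truth$precision)
  sigma <- (sigma + t(sigma)) / 2
  R <- chol(sigma)
  X <- withr::with_seed(as.integer(seed),
                        matrix(rnorm(n * p), n, p) %*% R)
  colnames(X) <- truth$variable_names
  signal_matrix(X, scale_tag = "normalized")
}

#' Distort marginals through strictly monotone transforms
#'
#' Passes each column through a strictly increasing transform, producing
#' non-Gaussian (optionally multimodal) marginals while leaving every
#' column's ranks — and therefore the entire rank-based pipeline — exactly
#' unchanged. `"lognormal"` exponentiates the standardized column;
#' `"bimodal"` maps the column through empirical quantile matching onto a
#' two-component normal mixture, emulating the dip-separated signal
#' distributions seen for many histone marks.
#'
#' @param X A [signal_matrix()].
#' @param mode `"lognormal"` or `"bimodal"`.
#' @param seed Integer seed (used by the mixture draw in `"bimodal"` mode).
#' @param mixture Parameters for the bimodal mixture: list with `means`,
#'   `sds`, `weight` (probability of the first component).
#' @return A [signal_matrix()] with the same dimensions and ranks.
#' @export
monotone_distort <- function(X, mode = c("lognormal", "bimodal"), seed = 1,
                             mixture = list(means = c(-2, 2),
                                            sds = c(0.5, 0.7),
                                            weight = 0.5)) {
  stopifnot(inherits(X, "signal_matrix"))
  mode <- match.arg(mode)
  vals <- X$values
  n <- nrow(vals)
  out <- switch(
    mode,
    lognormal = apply(vals, 2, function(col) {
      s <- stats::sd(col)
      exp((col - mean(col)) / if (s > 0) s else 1)
    }),
    bimodal = withr::with_seed(as.integer(seed), {
      apply(vals, 2, function(col) {
        comp <- runif(n) < mixture$weight
        draws <- ifelse(comp,
                        rnorm(n, mixture$means[1], mixture$sds[1]),
                        rnorm(n, mixture$means[2], mixture$sds[2]))
        # empirical quantile matching: i-th smallest value of the column is
        # mapped to the i-th smallest mixture draw, a strictly increasing map
        sort(draws)[rank(col, ties.method = "first")]
      })
    })
  )
  signal_matrix(out, X$sample_ids, X$variable_names, scale_tag = "normalized")
}
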