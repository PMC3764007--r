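#' Rank-transform a signal matrix
#'
#' Each column is independently replaced by its ranks 1..n, with average
#' (mid-)ranks for ties. Ranking makes every downstream statistic invariant
#' under strictly monotone transformations of the marginals, which protects
#' the network against the multimodal, heavy-tailed distributions typical of
#' ChIP-seq count data.
#'
#' @param X A [signal_matrix()] with `scale_tag` `"raw"` or `"normalized"`.
#' @return A [signal_matrix()] with `scale_tag = "rank"`.
#' @export
rank_transform <- function(X) {
  stopifnot(inherits(X, "signal_matrix"))
  if (X$scale_tag == "rank") return(X)
  constant <- apply(X$values, 2, function(col) length(unique(col)) == 1L)
  if (any(constant)) {
    abort_spcn(sprintf("constant column(s): %s (rank correlation undefined)",
                       paste(X$variable_names[constant], collapse = ", ")),
               "spcnet_constant_column")
  }
  ranked <- apply(X$values, 2, rank, ties.method = "average")
  signal_matrix(ranked, X$sample_ids, X$variable_names, scale_tag = "rank")
}

#' Construct a symmetric association matrix object
#'
#' @param values p x p symmetric numeric matrix with unit diagonal.
#' @param kind `"correlation"` or `"partial_correlation"`.
#' @param n_samples Number of samples the matrix was estimated from.
#' @param n_controls Number of control variables per entry (0 for marginal
#'   correlations, p - 2 for full-order partial correlations).
#' @return An object of class `assoc_matrix`.
#' @export
assoc_matrix <- function(values, kind = c("correlation", "partial_correlation"),
                         n_samples, n_controls = 0L) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot_symmetric(values, what = "association matrix")
  if (max(abs(diag(values) - 1)) > 1e-8) {
    abort_spcn("association matrix must have unit diagonal", "spcnet_diag")
  }
  off <- values[upper.tri(values)]
  if (length(off) && max(abs(off)) > 1 + 1e-8) {
    abort_spcn("off-diagonal association entries must lie in [-1, 1]",
               "spcnet_range")
  }
  structure(list(values = values, kind = kind,
                 n_samples = as.integer(n_samples),
                 n_controls = as.integer(n_controls),
                 variable_names = colnames(values)),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("%s matrix, %d variables (n = %d, controls = %d)\n",
              x$kind, ncol(x$values), x$n_samples, x$n_controls))
  invisible(x)
}

#' Pearson correlation matrix of a signal matrix
#'
#' On rank-transformed input this is the Spearman correlation of the original
#' data. The pipeline always ranks first; applying this to raw data gives the
#' ordinary Pearson matrix.
#'
#' @param X A [signal_matrix()].
#' @return An [assoc_matrix()] of kind `"correlation"`.
#' @export
correlation_matrix <- function(X) {
  stopifnot(inherits(X, "signal_matrix"))
  n <- nrow(X$values)
  if (n < 3L) abort_spcn("need at least 3 samples", "spcnet_too_few")
  sds <- apply(X$values, 2, stats::sd)
  if (any(sds == 0)) {
    abort_spcn("constant column: correlation undefined", "spcnet_constant_column")
  }
  C <- cor(X$values)
  if (any(!is.finite(C))) {
    abort_spcn("non-finite correlation entries", "spcnet_nonfinite")
  }
  C <- (C + t(C)) / 2
  diag(C) <- 1
  assoc_matrix(C, "correlation", n_samples = n, n_controls = 0L)
}

#' Partial correlation matrix from a correlation matrix
#'
#' Inverts the correlation matrix C to obtain the precision matrix Omega,
#' then normalizes and negates: P_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)
#' for i != j, with unit diagonal. Each entry is the correlation between two
#' variables after linearly regressing out all p - 2 remaining variables
#' from both.
#'
#' @param C An [assoc_matrix()] of kind `"correlation"`.
#' @param max_condition Fatal bound on the 2-norm condition number of C;
#'   near-singular matrices indicate collinear variables.
#' @return An [assoc_matrix()] of kind `"partial_correlation"` with
#'   `n_controls = p - 2`.
#' @export
partial_correlation_matrix <- function(C, max_condition = 1e12) {
  stopifnot(inherits(C, "assoc_matrix"))
  if (C$kind != "correlation") {
    abort_spcn("input must be a correlation matrix", "spcnet_kind")
  }
  cv <- C$values
  p <- ncol(cv)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > max_condition) {
    abort_spcn(sprintf(
      "correlation matrix is singular or ill-conditioned (condition number %.3g); check for collinear variables",
      if (min(ev) <= 0) Inf else max(ev) / min(ev)), "spcnet_singular")
  }
  omega <- solve(cv)
  d <- sqrt(diag(omega))
  P <- -omega / tcrossprod(d)
  diag(P) <- 1
  P <- (P + t(P)) / 2
  dimnames(P) <- dimnames(cv)
  assoc_matrix(P, "partial_correlation", n_samples = C$n_samples,
               n_controls = max(p - 2L, 0L))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of m * p_(j) / j on the
#' sorted p-values, clipped at 1. Thresholding the q-values at t controls the
#' false discovery rate at t.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param m Number of tests; defaults to `length(pvals)`.
#' @return Vector of q-values, same order as `pvals`.
#' @export
bh_adjust <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1), m >= length(pvals))
  n <- length(pvals)
  if (n == 0L) return(numeric(0))
  ord <- order(pvals)
  ranked <- pvals[ord] * m / seq_len(n)
  q_sorted <- rev(cummin(rev(ranked)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(n)
  out[ord] <- q_sorted
  out
}

#' Significance of partial correlations via the Fisher z-transform
#'
#' Each off-diagonal entry r is mapped to z = atanh(r) * sqrt(n - k - df_offset),
#' where k is the number of control variables; under the null z is
#' approximately standard normal, giving two-sided p-values. The p(p-1)/2
#' upper-triangle tests are then Benjamini-Hochberg adjusted.
#'
#' @param P An [assoc_matrix()] (partial correlations from the pipeline, but
#'   marginal correlations are accepted with `n_controls = 0`).
#' @param df_offset Constant subtracted along with the number of controls in
#'   the effective degrees of freedom (3 is the standard Fisher value).
#' @return An object of class `significance_matrices` with symmetric
#'   `pvalues` and `qvalues` matrices and `n_tests`.
#' @export
fisher_z_significance <- function(P, df_offset = 3) {
  stopifnot(inherits(P, "assoc_matrix"))
  p <- ncol(P$values)
  df <- P$n_samples - P$n_controls - df_offset
  if (df < 1) {
    abort_spcn(sprintf(
      "non-positive degrees of freedom (n = %d, controls = %d): need more samples",
      P$n_samples, P$n_controls), "spcnet_df")
  }
  r <- P$values
  degenerate <- abs(r) >= 1 & row(r) != col(r)
  if (any(degenerate)) {
    warning("|partial correlation| = 1 encountered; p-value set to 0")
  }
  z <- atanh(pmin(pmax(r, -1), 1)) * sqrt(df)
  pv <- 2 * pnorm(-abs(z))
  pv[degenerate] <- 0
  diag(pv) <- NA_real_
  ut <- upper.tri(pv)
  qv <- matrix(NA_real_, p, p, dimnames = dimnames(pv))
  qv[ut] <- bh_adjust(pv[ut])
  qv[lower.tri(qv)] <- t(qv)[lower.tri(qv)]
  pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  structure(list(pvalues = pv, qvalues = qv, n_tests = sum(ut),
                 df = df, variable_names = colnames(pv)),
            class = "significance_matrices")
}

#' @export
print.significance_matrices <- function(x, ...) {
  cat(sprintf("significance matrices over %d tests (df = %d); min q = %.3g\n",
              x$n_tests, x$df, min(x$qvalues, na.rm = TRUE)))
  invisible(x)
}

#' Full-data partial correlation matrix and significance in one call
#'
#' Convenience wrapper: rank transform (unless already ranked), correlation,
#' partial correlation, Fisher-z significance.
#'
#' @param X A [signal_matrix()].
#' @param rank Apply the rank transform first.
#' @param df_offset See [fisher_z_significance()].
#' @return List with elements `pcm` ([assoc_matrix()]) and `sig`
#'   (`significance_matrices`).
#' @export
pcm_pipeline <- function(X, rank = TRUE, df_offset = 3) {
  Xr <- if (rank) rank_transform(X) else X
  P <- partial_correlation_matrix(correlation_matrix(Xr))
  list(pcm = P, sig = fisher_z_significance(P, df_offset = df_offset))
}
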