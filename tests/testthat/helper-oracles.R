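# Independent oracles used across tests. These deliberately avoid the code
# paths they check: partial correlations via residual regression instead of
# matrix inversion, BH via the literal step-up definition instead of the
# vectorized cummin form.

# Partial correlation of every pair after regressing both members on all
# remaining variables ("keep the residuals").
oracle_partial_residuals <- function(X) {
  p <- ncol(X)
  P <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      Z <- cbind(1, X[, -c(i, j), drop = FALSE])
      ri <- X[, i] - Z %*% qr.solve(Z, X[, i])
      rj <- X[, j] - Z %*% qr.solve(Z, X[, j])
      P[i, j] <- P[j, i] <- cor(ri, rj)
    }
  }
  P
}

# Literal BH definition: q_i = min over { j : p_(j) >= p_i } of m * p_(j) / j.
oracle_bh_stepup <- function(pv, m = length(pv)) {
  sp <- sort(pv)
  vapply(pv, function(pi) {
    js <- which(sp >= pi)
    min(1, min(m * sp[js] / js))
  }, numeric(1))
}

# First-order recursion for a single control variable.
oracle_first_order <- function(r_xy, r_xz, r_yz) {
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

# Exact P(overlap >= x) of two random n-subsets of 1..N by enumeration:
# fix the first list as 1..n (exchangeability) and enumerate the second.
oracle_two_list_tail <- function(x, n, N) {
  sets <- utils::combn(N, n)
  overlaps <- colSums(sets <= n)
  mean(overlaps >= x)
}

# Exact P(common to all three lists >= x) for three random n-subsets of
# 1..N by full enumeration of list triples.
oracle_three_list_tail <- function(x, n, N) {
  sets <- utils::combn(N, n, simplify = FALSE)
  hits <- 0L
  total <- 0L
  for (a in sets) for (b in sets) for (cc in sets) {
    total <- total + 1L
    if (length(intersect(intersect(a, b), cc)) >= x) hits <- hits + 1L
  }
  hits / total
}

# Chain-structured precision matrix 1-2-3 with known truth.
chain_truth <- function(w = 0.5) {
  om <- diag(3)
  om[1, 2] <- om[2, 1] <- -w
  om[2, 3] <- om[3, 2] <- -w
  om[2, 2] <- 1 + 2 * w^2  # keeps om positive definite
  pc <- -om / sqrt(tcrossprod(diag(om)))
  diag(pc) <- 1
  dimnames(om) <- dimnames(pc) <- list(paste0("V", 1:3), paste0("V", 1:3))
  structure(list(precision = om, edge_set = rbind(c(1L, 2L), c(2L, 3L)),
                 partial_corr_true = pc, variable_names = paste0("V", 1:3)),
            class = "ggm_truth")
}

random_signal <- function(n, p, seed, names = paste0("V", seq_len(p))) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p)
    colnames(m) <- names
    signal_matrix(m, scale_tag = "normalized")
  })
}

# significance_matrices stand-in with prescribed q-values (symmetric).
fake_sig <- function(qm) {
  qm <- as.matrix(qm)
  diag(qm) <- NA_real_
  structure(list(pvalues = qm, qvalues = qm,
                 n_tests = sum(upper.tri(qm)),
                 variable_names = colnames(qm)),
            class = "significance_matrices")
}
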