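#' First-order partial correlation with a single control variable
#'
#' Correlation between x and y after controlling for a single variable z:
#' `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`.
#'
#' @param r_xy,r_xz,r_yz Marginal correlation coefficients in \[-1, 1\].
#' @return The partial correlation of x and y given z. Vectorized.
#' @export
single_control_partial <- function(r_xy, r_xz, r_yz) {
  if (any(abs(c(r_xy, r_xz, r_yz)) > 1 + 1e-12)) {
    abort_spcn("correlations must lie in [-1, 1]", "spcnet_range")
  }
  if (any(abs(r_xz) >= 1) || any(abs(r_yz) >= 1)) {
    abort_spcn("|r_xz| = 1 or |r_yz| = 1: partial correlation undefined",
               "spcnet_degenerate")
  }
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Explaining-away effect matrix
#'
#' For every unordered pair of variables the effect matrix records the
#' marginal correlation `r`, the full-control partial correlation `p_full`,
#' their difference `diff = p_full - r`, and — by an exhaustive scan over
#' single control variables — the control whose removal changes the marginal
#' correlation the most: `top_explainer` with `top_effect = max_k
#' |r_ij.k - r_ij|`. A large drop means the control explains the pair's
#' association away; an increase indicates collider-type conditioning.
#'
#' @param X A [signal_matrix()] with at least 3 variables.
#' @param rank Rank-transform first (default TRUE, matching the pipeline).
#' @return An object of class `effect_matrix` with fields `r`, `p_full`,
#'   `diff`, `top_explainer`, `top_effect`, `variable_names`.
#' @export
effect_matrix <- function(X, rank = TRUE) {
  stopifnot(inherits(X, "signal_matrix"))
  p <- ncol(X$values)
  if (p < 3) abort_spcn("need at least 3 variables", "spcnet_too_few")
  Xr <- if (rank) rank_transform(X) else X
  C <- correlation_matrix(Xr)
  P <- partial_correlation_matrix(C)
  r <- C$values
  vars <- Xr$variable_names
  top_explainer <- matrix(NA_character_, p, p, dimnames = dimnames(r))
  top_effect <- matrix(NA_real_, p, p, dimnames = dimnames(r))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ks <- setdiff(seq_len(p), c(i, j))
      r_k <- single_control_partial(r[i, j], r[i, ks], r[j, ks])
      eff <- abs(r_k - r[i, j])
      best <- ks[which.max(eff)]  # which.max takes the first: ties break by variable order
      top_explainer[i, j] <- top_explainer[j, i] <- vars[best]
      top_effect[i, j] <- top_effect[j, i] <- max(eff)
    }
  }
  diff <- P$values - r
  diag(diff) <- 0
  structure(list(r = r, p_full = P$values, diff = diff,
                 top_explainer = top_explainer, top_effect = top_effect,
                 variable_names = vars),
            class = "effect_matrix")
}

#' @export
print.effect_matrix <- function(x, ...) {
  ut <- upper.tri(x$diff)
  cat(sprintf("effect matrix over %d variables; max |partial - marginal| = %.3f\n",
              length(x$variable_names), max(abs(x$diff[ut]))))
  invisible(x)
}

#' Consensus effect matrix across conditions
#'
#' Merges per-condition effect matrices over their shared variables,
#' reporting for each pair the modal top explainer and the number of
#' conditions agreeing on it, together with the mean signed difference.
#'
#' @param effects List of [effect_matrix()] objects.
#' @return An object of class `consensus_effect_matrix` with
#'   `top_explainer` (modal), `explainer_support` (integer matrix) and
#'   `mean_diff` over the shared variable universe.
#' @export
consensus_effect_matrix <- function(effects) {
  stopifnot(length(effects) >= 2,
            all(vapply(effects, inherits, logical(1), "effect_matrix")))
  shared <- Reduce(intersect, lapply(effects, `[[`, "variable_names"))
  if (length(shared) < 3) {
    abort_spcn("fewer than 3 shared variables across conditions",
               "spcnet_too_few")
  }
  sub <- lapply(effects, function(e) {
    idx <- match(shared, e$variable_names)
    list(top = e$top_explainer[idx, idx, drop = FALSE],
         diff = e$diff[idx, idx, drop = FALSE])
  })
  p <- length(shared)
  modal <- matrix(NA_character_, p, p, dimnames = list(shared, shared))
  support <- matrix(0L, p, p, dimnames = list(shared, shared))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      tops <- vapply(sub, function(s) s$top[i, j], character(1))
      tab <- sort(table(tops), decreasing = TRUE)
      modal[i, j] <- modal[j, i] <- names(tab)[1]
      support[i, j] <- support[j, i] <- as.integer(tab[1])
    }
  }
  mean_diff <- Reduce(`+`, lapply(sub, `[[`, "diff")) / length(sub)
  structure(list(top_explainer = modal, explainer_support = support,
                 mean_diff = mean_diff, n_conditions = length(effects),
                 variable_names = shared),
            class = "consensus_effect_matrix")
}
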