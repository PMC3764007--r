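#' Consensus network across conditions
#'
#' Keeps edges present in at least `min_conditions` of the supplied
#' networks, over the intersection of their variable universes. Each kept
#' edge is annotated with its support count, per-condition weights, and a
#' sign label: `"+"` or `"-"` when all supporting conditions agree on the
#' sign of the partial correlation, `"conflict"` otherwise.
#'
#' @param spcns Named list of `spcn` objects (>= 2), one per condition.
#' @param min_conditions Minimum number of networks an edge must appear in
#'   (default 2).
#' @param include_completed Include special-node completed edges
#'   (provenance `mrna_completed`) in the comparison (default TRUE; set to
#'   FALSE to restrict to mask-voted edges).
#' @return An object of class `consensus_network`: a data.frame with
#'   `var_a`, `var_b`, `support`, `sign` and one weight column per
#'   condition (NA when the edge is absent there).
#' @export
consensus_network <- function(spcns, min_conditions = 2,
                              include_completed = TRUE) {
  if (length(spcns) < 2) {
    abort_spcn("need at least 2 networks for a consensus", "spcnet_too_few")
  }
  stopifnot(all(vapply(spcns, inherits, logical(1), "spcn")),
            min_conditions >= 1, min_conditions <= length(spcns))
  cond <- names(spcns)
  if (is.null(cond)) cond <- paste0("condition_", seq_along(spcns))
  shared <- Reduce(intersect, lapply(spcns, `[[`, "variable_names"))
  dropped <- setdiff(unique(unlist(lapply(spcns, `[[`, "variable_names"))), shared)
  if (length(dropped)) {
    log_msg("variables dropped from consensus (not shared): ",
            paste(dropped, collapse = ", "))
  }
  if (length(shared) < 2) {
    abort_spcn("fewer than 2 shared variables", "spcnet_too_few")
  }
  shared <- sort(shared)
  p <- length(shared)
  idx <- upper_pairs(p)
  keys <- pair_key(shared[idx[, 1]], shared[idx[, 2]])
  weight_of <- function(net) {
    m <- match(shared, net$variable_names)
    keep <- net$mask$keep[m, m, drop = FALSE]
    if (!include_completed) {
      keep <- keep & net$mask$provenance[m, m, drop = FALSE] == "masked"
    }
    w <- net$pcm$values[m, m, drop = FALSE]
    ifelse(keep[cbind(idx[, 1], idx[, 2])],
           w[cbind(idx[, 1], idx[, 2])], NA_real_)
  }
  W <- vapply(spcns, weight_of, numeric(nrow(idx)))
  W <- matrix(W, nrow = nrow(idx), dimnames = list(NULL, cond))
  support <- rowSums(!is.na(W))
  sgn <- apply(W, 1, function(w) {
    s <- sign(w[!is.na(w)])
    if (!length(s)) return(NA_character_)
    if (all(s > 0)) "+" else if (all(s < 0)) "-" else "conflict"
  })
  keep_rows <- support >= min_conditions
  out <- data.frame(var_a = shared[idx[, 1]], var_b = shared[idx[, 2]],
                    pair = keys, support = as.integer(support), sign = sgn,
                    stringsAsFactors = FALSE)[keep_rows, , drop = FALSE]
  Wk <- W[keep_rows, , drop = FALSE]
  colnames(Wk) <- paste0("weight_", cond)
  out <- cbind(out, as.data.frame(Wk))
  rownames(out) <- NULL
  structure(out, class = c("consensus_network", "data.frame"),
            conditions = cond, min_conditions = min_conditions,
            variables = shared)
}
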