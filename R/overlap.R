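#' Rank variable pairs by significance
#'
#' Orders the p(p-1)/2 upper-triangle pairs by ascending q-value, breaking
#' ties by descending absolute partial correlation and then by lexicographic
#' pair name (so the ordering is deterministic).
#'
#' @param Q A `significance_matrices` object.
#' @param P The matching [assoc_matrix()] of partial correlations.
#' @return An object of class `ranked_pair_list`: `pairs` (character keys
#'   `"a|b"` in rank order), `pair_table` (data.frame with q and \|partial\|),
#'   `N_total`, `variables`.
#' @export
rank_pairs <- function(Q, P) {
  stopifnot(inherits(P, "assoc_matrix"))
  vars <- P$variable_names
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(P$values)))
  stopifnot(ncol(Q$qvalues) == ncol(P$values))
  p <- length(vars)
  idx <- upper_pairs(p)
  keys <- pair_key(vars[idx[, 1]], vars[idx[, 2]])
  tab <- data.frame(
    pair = keys,
    var_a = vars[idx[, 1]],
    var_b = vars[idx[, 2]],
    q = Q$qvalues[idx],
    abs_partial = abs(P$values[idx]),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$q, -tab$abs_partial, tab$pair)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(pairs = tab$pair, pair_table = tab,
                 N_total = nrow(tab), variables = sort(vars)),
            class = "ranked_pair_list")
}

#' Expected two-list top-n overlap proportion under the null
#'
#' With two independent random lists of n pairs drawn from N, the shared
#' count is hypergeometric with mean n^2/N, so the expected proportion of
#' the top n shared by both lists is n/N — a straight line in n.
#'
#' @param n Number of top pairs considered.
#' @param N Total number of pairs.
#' @return `n / N`.
#' @export
expected_two_list <- function(n, N) {
  stopifnot(all(n >= 1), all(n <= N))
  n / N
}

#' Hypergeometric tail p-value for a two-list overlap
#'
#' P(X >= x) where X ~ Hypergeometric with n white balls, N - n black balls
#' and n draws: both lists have the same length n, drawn from a universe of
#' N pairs.
#'
#' @param x Observed overlap count.
#' @param n List length.
#' @param N Universe size.
#' @return Upper tail probability (inclusive).
#' @export
hypergeom_pvalue <- function(x, n, N) {
  stopifnot(all(x >= 0), all(x <= n), all(n <= N))
  phyper(x - 1, m = n, n = N - n, k = n, lower.tail = FALSE)
}

#' Monte-Carlo null for the overlap of three or more lists
#'
#' Expected proportion of the top n shared by all L independent random
#' lists is (n/N)^(L-1) (for L = 3 a quadratic curve: each pair lands in
#' one list with probability n/N, and must land in the remaining L - 1).
#' The p-value is the fraction of simulated L-list intersections at least as
#' large as the observation; when that fraction is zero, 1/n_sims is
#' reported and flagged as an upper bound.
#'
#' @param x Observed intersection count.
#' @param n List length.
#' @param N Universe size.
#' @param L Number of lists (>= 3).
#' @param n_sims Number of null simulations (default 1e5).
#' @param seed Integer seed.
#' @param replace Sample the null lists with replacement. The default
#'   (`FALSE`) reflects that a ranked top-n list contains distinct pairs;
#'   `TRUE` reproduces sampling each list uniformly with replacement.
#' @return List with `expected`, `p_value`, `is_bound`.
#' @export
multi_list_null <- function(x, n, N, L = 3, n_sims = 1e5, seed = 1,
                            replace = FALSE) {
  stopifnot(L >= 3, n_sims >= 1, x >= 0, x <= n, n <= N)
  expected <- (n / N)^(L - 1)
  sizes <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_sims), function(s) {
      hits <- integer(N)
      for (l in seq_len(L)) {
        drawn <- unique(sample.int(N, n, replace = replace))
        hits[drawn] <- hits[drawn] + 1L
      }
      sum(hits == L)
    }, integer(1))
  })
  p <- mean(sizes >= x)
  is_bound <- FALSE
  if (p == 0) {
    p <- 1 / n_sims
    is_bound <- TRUE
  }
  list(expected = expected, p_value = p, is_bound = is_bound)
}

#' Top-n overlap curve across ranked pair lists
#'
#' For each n, the observed proportion of the n top-ranked pairs common to
#' all lists, the null expectation (n/N for two lists, (n/N)^(L-1)
#' otherwise) and a p-value: hypergeometric for two lists, Monte-Carlo for
#' three or more.
#'
#' @param lists List of [rank_pairs()] results over the same variable
#'   universe.
#' @param n_values Integer vector of list depths to evaluate (default: all
#'   1..N).
#' @param n_sims Simulations for the multi-list null (default 2000; the
#'   curve evaluates many n at once, see [multi_list_null()] for a precise
#'   single-n p-value).
#' @param seed Integer seed for the multi-list null.
#' @return An object of class `overlap_result`: data.frame with columns
#'   `n`, `observed_count`, `observed_proportion`, `expected_proportion`,
#'   `p_value`, `is_bound`, plus attributes `method` and `L`.
#' @export
overlap_curve <- function(lists, n_values = NULL, n_sims = 2000, seed = 1) {
  stopifnot(length(lists) >= 2,
            all(vapply(lists, inherits, logical(1), "ranked_pair_list")))
  L <- length(lists)
  N <- lists[[1]]$N_total
  uni <- lists[[1]]$variables
  for (l in lists[-1]) {
    if (l$N_total != N || !identical(l$variables, uni)) {
      abort_spcn("ranked pair lists span different universes", "spcnet_universe")
    }
  }
  if (is.null(n_values)) n_values <- seq_len(N)
  stopifnot(all(n_values >= 1), all(n_values <= N))
  # rank of every pair in every list; a pair is in all top-n lists iff its
  # maximum rank across lists is <= n
  all_pairs <- sort(lists[[1]]$pairs)
  ranks <- vapply(lists, function(l) match(all_pairs, l$pairs), numeric(length(all_pairs)))
  if (anyNA(ranks)) {
    abort_spcn("lists do not contain the same pairs", "spcnet_universe")
  }
  maxrank <- apply(ranks, 1, max)
  counts_at <- cumsum(tabulate(maxrank, nbins = N))
  observed_count <- counts_at[n_values]
  observed <- observed_count / n_values
  if (L == 2) {
    expected <- expected_two_list(n_values, N)
    pv <- hypergeom_pvalue(observed_count, n_values, N)
    bound <- rep(FALSE, length(n_values))
    method <- "hypergeometric"
  } else {
    expected <- (n_values / N)^(L - 1)
    # one set of simulated rankings serves every n: per simulation, draw L
    # random permutations and read off the max-rank distribution
    sim_counts <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_sims), function(s) {
        mr <- do.call(pmax, lapply(seq_len(L), function(l) sample.int(N)))
        cumsum(tabulate(mr, nbins = N))[n_values]
      }, numeric(length(n_values)))
    })
    sim_counts <- matrix(sim_counts, nrow = length(n_values))
    pv <- rowMeans(sim_counts >= observed_count)
    bound <- pv == 0
    pv[bound] <- 1 / n_sims
    method <- "simulation"
  }
  out <- data.frame(n = n_values, observed_count = observed_count,
                    observed_proportion = observed,
                    expected_proportion = expected,
                    p_value = pv, is_bound = bound)
  structure(out, class = c("overlap_result", "data.frame"),
            method = method, L = L, N_total = N)
}
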