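#' @importFrom stats cor pnorm qnorm phyper rnorm runif approxfun setNames
#' @importFrom utils read.table write.table packageVersion
NULL

# Upper-triangle index pairs (i < j) of a p x p matrix, as a 2-column matrix.
upper_pairs <- function(p) {
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# Canonical key for an unordered variable pair: names sorted, joined by "|".
pair_key <- function(a, b) {
  swap <- a > b
  key_a <- ifelse(swap, b, a)
  key_b <- ifelse(swap, a, b)
  paste(key_a, key_b, sep = "|")
}

# Deterministic sub-seed derivation so that independent stochastic stages of
# one run (fold split, data generation, null simulations) do not share a
# stream. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

abort_spcn <- function(msg, class) {
  stop(structure(
    class = c(class, "spcnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stopifnot_symmetric <- function(m, tol = 1e-12, what = "matrix") {
  if (max(abs(m - t(m))) > tol) {
    abort_spcn(sprintf("%s is not symmetric (max asymmetry %g)",
                       what, max(abs(m - t(m)))), "spcnet_asymmetric")
  }
}

log_msg <- function(..., verbose = getOption("spcnet.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
}
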