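#' Construct a signal matrix
#'
#' A signal matrix holds per-region signal levels: rows are genomic regions
#' (samples), columns are variables such as histone modifications, DNaseIHS
#' or mRNA. The `scale_tag` records where the matrix sits in the pipeline:
#' `"raw"` read counts, `"normalized"` counts-per-bp, or `"rank"` after the
#' columnwise rank transform.
#'
#' @param values Numeric matrix, samples x variables.
#' @param sample_ids Character vector of row identifiers. Defaults to the
#'   rownames of `values` or `region_1..n`.
#' @param variable_names Character vector of unique column names. Defaults to
#'   the colnames of `values`.
#' @param scale_tag One of `"raw"`, `"normalized"`, `"rank"`.
#' @return An object of class `signal_matrix` with fields `values`,
#'   `sample_ids`, `variable_names`, `scale_tag`.
#' @export
signal_matrix <- function(values, sample_ids = NULL, variable_names = NULL,
                          scale_tag = c("raw", "normalized", "rank")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(variable_names)) variable_names <- colnames(values)
  if (is.null(variable_names)) {
    variable_names <- paste0("V", seq_len(ncol(values)))
  }
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("region_", seq_len(nrow(values)))
  if (anyDuplicated(variable_names)) {
    abort_spcn("duplicate variable names in signal matrix", "spcnet_dup_names")
  }
  if (length(variable_names) != ncol(values)) {
    abort_spcn("variable_names length does not match column count",
               "spcnet_bad_dim")
  }
  if (length(sample_ids) != nrow(values)) {
    abort_spcn("sample_ids length does not match row count", "spcnet_bad_dim")
  }
  if (any(!is.finite(values))) {
    abort_spcn("signal matrix contains non-finite values", "spcnet_nonfinite")
  }
  dimnames(values) <- list(sample_ids, variable_names)
  structure(
    list(values = values, sample_ids = sample_ids,
         variable_names = variable_names, scale_tag = scale_tag),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d samples x %d variables [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  cat("variables:", paste(x$variable_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

#' Load a signal matrix from a TSV file
#'
#' Reads a tab-separated file whose first row holds variable names and whose
#' first column holds sample (region) identifiers. Gzip-compressed files are
#' read transparently. Rows containing missing or non-numeric entries are
#' dropped (and counted) when `drop_missing = TRUE`, otherwise they are fatal.
#'
#' @param path Path to a TSV file (optionally gzipped).
#' @param drop_missing Drop rows with missing values instead of failing.
#' @param scale_tag Scale tag to attach to the loaded matrix.
#' @return A [signal_matrix()].
#' @export
load_signal_matrix <- function(path, drop_missing = FALSE,
                               scale_tag = "raw") {
  if (!file.exists(path)) {
    abort_spcn(sprintf("file not found: %s", path), "spcnet_io")
  }
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "", quote = "")
  if (anyDuplicated(colnames(df))) {
    abort_spcn("duplicate variable names in header", "spcnet_dup_names")
  }
  values <- as.matrix(df)
  if (!is.numeric(values)) {
    suppressWarnings(storage.mode(values) <- "double")
  }
  bad <- !stats::complete.cases(values) | apply(values, 1, function(r) any(!is.finite(r)))
  if (any(bad)) {
    if (!drop_missing) {
      abort_spcn(sprintf("%d rows contain missing/non-numeric values (set drop_missing = TRUE to drop them)",
                         sum(bad)), "spcnet_missing")
    }
    log_msg(sprintf("dropping %d rows with missing values", sum(bad)))
    values <- values[!bad, , drop = FALSE]
  }
  log_msg(sprintf("loaded %d samples x %d variables from %s",
                  nrow(values), ncol(values), path))
  signal_matrix(values, scale_tag = scale_tag)
}

#' Save a signal matrix to a TSV file
#'
#' Writes the matrix in the dialect read by [load_signal_matrix()]: header
#' row of variable names, first column of sample ids, full precision.
#'
#' @param x A [signal_matrix()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
save_signal_matrix <- function(x, path) {
  stopifnot(inherits(x, "signal_matrix"))
  df <- data.frame(id = x$sample_ids, x$values, check.names = FALSE)
  names(df)[1] <- "id"
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  # format() would round; write values through as.character for full precision
  mat <- vapply(seq_len(ncol(x$values)),
                function(j) formatC(x$values[, j], digits = 17, format = "g"),
                character(nrow(x$values)))
  if (nrow(x$values) == 1L) mat <- matrix(mat, nrow = 1L)
  out <- cbind(x$sample_ids, mat)
  writeLines(paste(c("id", x$variable_names), collapse = "\t"), con)
  writeLines(apply(out, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Normalize read counts by region or transcript length
#'
#' Converts raw read counts to reads per base pair. ChIP-type columns share a
#' single fixed region length (the promoter window, 4000 bp by default);
#' mRNA-type columns are divided by a per-region transcript length, since
#' spliced transcript lengths differ between genes.
#'
#' @param raw A [signal_matrix()] with `scale_tag = "raw"`.
#' @param lengths Optional data.frame with columns `region_id` and
#'   `length_bp` giving per-region transcript lengths. Required when
#'   `mrna_columns` is non-empty.
#' @param mrna_columns Character vector of column names to normalize by the
#'   per-region transcript length.
#' @param region_length Fixed window length in bp for all other columns.
#' @return A [signal_matrix()] with `scale_tag = "normalized"`.
#' @export
normalize_counts <- function(raw, lengths = NULL, mrna_columns = character(),
                             region_length = 4000) {
  stopifnot(inherits(raw, "signal_matrix"))
  if (raw$scale_tag != "raw") {
    abort_spcn("normalize_counts expects a raw-count matrix", "spcnet_scale")
  }
  if (region_length <= 0) abort_spcn("region_length must be > 0", "spcnet_arg")
  values <- raw$values
  is_mrna <- raw$variable_names %in% mrna_columns
  if (length(mrna_columns) && !all(mrna_columns %in% raw$variable_names)) {
    abort_spcn("mrna_columns not all present in the matrix", "spcnet_arg")
  }
  values[, !is_mrna] <- values[, !is_mrna, drop = FALSE] / region_length
  if (any(is_mrna)) {
    if (is.null(lengths)) {
      abort_spcn("per-region transcript lengths required for mRNA columns",
                 "spcnet_missing_length")
    }
    stopifnot(all(c("region_id", "length_bp") %in% names(lengths)))
    if (any(lengths$length_bp <= 0)) {
      abort_spcn("transcript lengths must be positive", "spcnet_arg")
    }
    idx <- match(raw$sample_ids, lengths$region_id)
    if (anyNA(idx)) {
      abort_spcn("missing transcript length for some regions",
                 "spcnet_missing_length")
    }
    len <- lengths$length_bp[idx]
    values[, is_mrna] <- raw$values[, is_mrna, drop = FALSE] / len
  }
  signal_matrix(values, raw$sample_ids, raw$variable_names,
                scale_tag = "normalized")
}
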