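#' Write a network edge list to TSV
#'
#' @param x An `spcn` or `consensus_network` object, or a data.frame of
#'   edges.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  df <- if (inherits(x, "spcn")) spcn_edges(x) else as.data.frame(x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge list from TSV
#'
#' @param path Path written by [write_edge_list()].
#' @return data.frame of edges.
#' @export
read_edge_list <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Convert a sparse partial correlation network to an igraph object
#'
#' Nodes are variables; edges carry the signed partial correlation
#' (`weight`), q-value, fold support and provenance.
#'
#' @param x An `spcn` object.
#' @return An [igraph::graph_from_data_frame()] undirected graph.
#' @export
spcn_to_igraph <- function(x) {
  stopifnot(inherits(x, "spcn"))
  edges <- spcn_edges(x)
  names(edges)[names(edges) == "partial_correlation"] <- "weight"
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = x$variable_names))
}

#' Write a network to GraphML
#'
#' @param x An `spcn` object or an igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(x, path) {
  g <- if (inherits(x, "spcn")) spcn_to_igraph(x) else x
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write an effect matrix as a pairwise TSV table
#'
#' One row per unordered pair: marginal correlation `r`, full-control
#' partial `p_full`, signed difference `diff`, the single control with the
#' largest effect and that effect's magnitude.
#'
#' @param em An [effect_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effect_matrix <- function(em, path) {
  stopifnot(inherits(em, "effect_matrix"))
  p <- length(em$variable_names)
  idx <- upper_pairs(p)
  df <- data.frame(
    var_a = em$variable_names[idx[, 1]],
    var_b = em$variable_names[idx[, 2]],
    r = em$r[idx],
    p_full = em$p_full[idx],
    diff = em$diff[idx],
    top_explainer = em$top_explainer[idx],
    top_effect = em$top_effect[idx],
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a symmetric matrix (correlations, q-values, ...) as TSV
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
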