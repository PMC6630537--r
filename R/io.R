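#' Read and write pipeline tables
#'
#' Tab-separated plain-text readers/writers for the tables exchanged between
#' the simulator and the inference pipeline: tracks
#' (`cell_id`, `kind`, `t`, `row`, `col`), angle series
#' (`cell_id`, `kind`, `t`, `angle`), and TE edge lists
#' (`macrophage`, `fibroblast`, `te`, plus window columns when present).
#'
#' @param x The table to write.
#' @param path File path.
#' @return `read_*` return tibbles; `write_*` return `path` invisibly.
#' @name pipeline_io
NULL

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' @rdname pipeline_io
#' @export
write_tracks <- function(x, path) write_tsv_plain(x, path)

#' @rdname pipeline_io
#' @export
read_tracks <- function(path) {
  x <- read_tsv_plain(path)
  need <- c("cell_id", "kind", "t", "row", "col")
  if (!all(need %in% names(x))) {
    rlang::abort(paste0("tracks file must have columns: ", paste(need, collapse = ", ")))
  }
  x
}

#' @rdname pipeline_io
#' @export
write_angle_series <- function(x, path) write_tsv_plain(x, path)

#' @rdname pipeline_io
#' @export
write_te_edges <- function(x, path) write_tsv_plain(x, path)

#' Convert a TE network to an igraph object
#'
#' Vertices carry `kind` (`"macrophage"`/`"fibroblast"`) and the bipartite
#' `type` attribute; edges carry the pairwise transfer entropy in `te`.
#' Optionally attaches per-node centralities as a `centrality` attribute.
#'
#' @param network A `te_network`.
#' @param centrality Optional `centrality_result` for the same network.
#' @return An undirected igraph graph.
#' @export
as_igraph <- function(network, centrality = NULL) {
  stopifnot(inherits(network, "te_network"))
  verts <- data.frame(
    name = c(paste0("M", network$m_nodes), paste0("F", network$f_nodes)),
    kind = rep(c("macrophage", "fibroblast"),
               c(length(network$m_nodes), length(network$f_nodes))),
    type = rep(c(FALSE, TRUE),
               c(length(network$m_nodes), length(network$f_nodes)))
  )
  if (!is.null(centrality)) verts$centrality <- centrality$centrality
  edges <- data.frame(
    from = paste0("M", network$edges$macrophage),
    to = paste0("F", network$edges$fibroblast),
    te = network$edges$te
  )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Write a TE network as GraphML
#'
#' @inheritParams as_igraph
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, centrality = NULL) {
  igraph::write_graph(as_igraph(network, centrality), path, format = "graphml")
  invisible(path)
}

#' Write a cytokine field snapshot as a delimited-text matrix
#'
#' @param field Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_snapshot <- function(field, path) {
  utils::write.table(field, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
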