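#' Remove non-physical interaction types from an edge list
#'
#' Interaction networks exported from curated databases mix physical
#' binding edges with functional ones; for a physical-interaction
#' subnetwork, types such as "transcription regulation" and "transport"
#' are discarded. Matching is case-insensitive on the verbatim label;
#' unknown labels are treated as physical and kept.
#'
#' @param edges An [edge_list()].
#' @param excluded_types Character vector of type labels to drop.
#' @return The filtered [edge_list()].
#' @export
filter_physical_edges <- function(edges,
                                  excluded_types = c(
                                    "transcription regulation",
                                    "transport")) {
  stopifnot(inherits(edges, "edge_list"))
  keep <- !(tolower(trimws(edges$interaction)) %in%
              tolower(trimws(excluded_types)))
  edge_list(tibble::as_tibble(edges)[keep, , drop = FALSE])
}

#' First-neighbor subnetwork around a seed set
#'
#' Extracts the subgraph induced by the seed proteins present in the graph
#' together with every node adjacent to a seed: all edges with both
#' endpoints in that node set are retained, including edges between two
#' neighbors. Seeds absent from the edge list are reported, not silently
#' dropped.
#'
#' @param edges An [edge_list()], already filtered to physical types.
#' @param seeds Character vector of seed proteins.
#' @return An `interaction_graph`: list with `edges` (the induced
#'   [edge_list()]), `nodes` (tibble `node`, `role` in seed/neighbor) and
#'   `seeds_missing` (seeds absent from the graph).
#' @export
first_neighbor_subnetwork <- function(edges, seeds) {
  stopifnot(inherits(edges, "edge_list"))
  seeds <- unique(seeds)
  graph_nodes <- union(edges$source, edges$target)
  seeds_present <- intersect(seeds, graph_nodes)
  seeds_missing <- setdiff(seeds, graph_nodes)
  touches_seed <- edges$source %in% seeds_present |
    edges$target %in% seeds_present
  neighbors <- setdiff(
    union(edges$source[touches_seed], edges$target[touches_seed]),
    seeds_present
  )
  node_set <- union(seeds_present, neighbors)
  induced <- edges$source %in% node_set & edges$target %in% node_set
  sub <- edge_list(tibble::as_tibble(edges)[induced, , drop = FALSE])
  nodes <- tibble::tibble(
    node = c(sort(seeds_present), sort(neighbors)),
    role = rep(c("seed", "neighbor"),
               c(length(seeds_present), length(neighbors)))
  )
  structure(list(edges = sub, nodes = nodes,
                 seeds_missing = sort(seeds_missing)),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf(
    "<interaction_graph> %d seeds + %d neighbors, %d edges (%d seeds not in graph)\n",
    sum(x$nodes$role == "seed"), sum(x$nodes$role == "neighbor"),
    nrow(x$edges), length(x$seeds_missing)))
  invisible(x)
}

#' Write a subnetwork as SIF plus node attributes
#'
#' @param graph An `interaction_graph` from [first_neighbor_subnetwork()].
#' @param sif_path Output SIF path (tab-separated source, type, target).
#' @param nodes_path Output node-attribute TSV path (`node`, `role`).
#' @return Invisibly, the two paths.
#' @export
write_subnetwork <- function(graph, sif_path, nodes_path) {
  stopifnot(inherits(graph, "interaction_graph"))
  writeLines(paste(graph$edges$source, graph$edges$interaction,
                   graph$edges$target, sep = "\t"), sif_path)
  readr::write_tsv(graph$nodes, nodes_path, progress = FALSE)
  invisible(c(sif_path, nodes_path))
}
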