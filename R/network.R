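# Function-similarity network: Kamada-Kawai force-directed layout with the
# mismatch proportions as target edge lengths, so pairs that rarely
# mismatch sit close together.

#' Function-similarity network from a mismatch matrix
#'
#' Builds a graph whose edges are the unmasked property pairs, weighted by
#' their mismatch proportion, and lays it out with the Kamada-Kawai
#' path-length cost function (larger mismatch = longer target distance).
#' Masked entries are absent edges and are reached through shortest paths
#' inside the layout algorithm. The layout is deterministic: it starts
#' from a circular arrangement, so identical matrices give identical
#' coordinates. A disconnected graph is laid out per component with a
#' warning.
#'
#' @param matrix a [build_mismatch_matrix()] object.
#' @param eps lower bound on edge lengths (zero-mismatch pairs would
#'   otherwise request zero distance), default 1e-3.
#' @return Object of class `"similarity_network"`: list with `nodes`
#'   (property, x, y), `edges` (from, to, proportion, n) and the `igraph`
#'   graph.
#' @export
similarity_network <- function(matrix, eps = 1e-3) {
  stopifnot(inherits(matrix, "mismatch_matrix"))
  P <- matrix$proportion
  props <- matrix$properties
  idx <- which(upper.tri(P) & !is.na(P), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("no unmasked pairs: cannot build a network", call. = FALSE)
  }
  edges <- data.frame(from = props[idx[, 1]], to = props[idx[, 2]],
                      proportion = P[idx],
                      n = matrix$counts[idx],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = props))
  if (!igraph::is_connected(g)) {
    warning("mismatch graph is disconnected; components are laid out independently",
            call. = FALSE)
  }
  w <- pmax(edges$proportion, eps)
  coords <- igraph::layout_with_kk(g, weights = w,
                                   coords = igraph::layout_in_circle(g))
  nodes <- data.frame(property = igraph::V(g)$name,
                      x = coords[, 1], y = coords[, 2],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, igraph = g),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network: %d properties, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a similarity network
#'
#' Writes the graph as GraphML (with mismatch proportions as edge
#' attributes and layout coordinates as node attributes) and, optionally,
#' the node coordinates as CSV.
#'
#' @param network a [similarity_network()] object.
#' @param graphml_path path for the GraphML file.
#' @param coords_path optional path for a node-coordinates CSV.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, graphml_path, coords_path = NULL) {
  stopifnot(inherits(network, "similarity_network"))
  g <- network$igraph
  igraph::V(g)$x <- network$nodes$x
  igraph::V(g)$y <- network$nodes$y
  igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(coords_path)) {
    utils::write.csv(network$nodes, coords_path, row.names = FALSE)
  }
  invisible(c(graphml_path, coords_path))
}
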