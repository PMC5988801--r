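#' Edge betweenness centrality
#'
#' For each edge, the number of shortest paths between unordered vertex
#' pairs that pass through the edge, with fractional splitting when a pair
#' is joined by several geodesics. Unnormalized (rank correlations are
#' invariant to positive scaling). Disconnected pairs contribute 0.
#'
#' @param g An igraph object.
#' @return An `edge_measure` table.
#' @export
edge_betweenness_centrality <- function(g) {
  vals <- igraph::edge_betweenness(g, directed = FALSE, weights = NA)
  edge_measure(g, vals, "edge_betweenness")
}

#' Embeddedness of edges
#'
#' The number of neighbours shared by the two endpoints of each edge --
#' identical to the number of triangles containing the edge.
#'
#' @param g An igraph object.
#' @param e Optional single edge (length-2 vector of internal ids); if
#'   omitted an `edge_measure` over all edges is returned.
#' @return An `edge_measure` table, or a scalar when `e` is given.
#' @export
embeddedness <- function(g, e = NULL) {
  if (is.null(e)) {
    edge_measure(g, edge_triangles(g), "embeddedness")
  } else {
    edge_triangles(g, e)
  }
}

#' Dispersion of edges
#'
#' Absolute dispersion of an edge (u, v): over all unordered pairs {s, t}
#' of common neighbours of u and v, count the pairs that are *not* well
#' connected in the sense that s and t are non-adjacent and share no
#' common neighbour other than u and v. High dispersion marks edges whose
#' mutual acquaintances come from otherwise unconnected contexts.
#'
#' @param g An igraph object.
#' @param e Optional single edge (length-2 vector of internal ids); if
#'   omitted an `edge_measure` over all edges is returned.
#' @return An `edge_measure` table, or a scalar when `e` is given.
#' @export
dispersion <- function(g, e = NULL) {
  adj <- adj_list(g)
  disp_one <- function(u, v) {
    cn <- intersect(adj[[u]], adj[[v]])
    if (length(cn) < 2L) return(0)
    total <- 0
    for (i in seq_len(length(cn) - 1L)) {
      for (j in seq.int(i + 1L, length(cn))) {
        s <- cn[i]; t <- cn[j]
        if (t %in% adj[[s]]) next
        others <- setdiff(intersect(adj[[s]], adj[[t]]), c(u, v))
        if (length(others) == 0L) total <- total + 1
      }
    }
    total
  }
  if (is.null(e)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    vals <- if (nrow(el) == 0L) numeric(0) else
      vapply(seq_len(nrow(el)), function(i) disp_one(el[i, 1L], el[i, 2L]), 1.0)
    edge_measure(g, vals, "dispersion")
  } else {
    stopifnot(length(e) == 2L)
    if (!igraph::are_adjacent(g, e[1L], e[2L])) {
      stop("(", e[1L], ",", e[2L], ") is not an edge of the graph")
    }
    disp_one(as.integer(e[1L]), as.integer(e[2L]))
  }
}

#' Vertex degree
#'
#' @param g An igraph object.
#' @return A `vertex_measure` table.
#' @export
vertex_degree <- function(g) {
  vertex_measure(g, igraph::degree(g), "degree")
}

#' Vertex betweenness centrality
#'
#' Number of shortest paths between unordered pairs of other vertices that
#' pass through each vertex, with fractional splitting over multiple
#' geodesics; unnormalized.
#'
#' @param g An igraph object.
#' @return A `vertex_measure` table.
#' @export
vertex_betweenness <- function(g) {
  vertex_measure(g, igraph::betweenness(g, directed = FALSE, weights = NA),
                 "betweenness")
}

#' Local clustering coefficient
#'
#' Realized edges between the neighbours of a vertex divided by the number
#' possible; vertices of degree < 2 get 0.
#'
#' @param g An igraph object.
#' @return A `vertex_measure` table.
#' @export
clustering_coefficient <- function(g) {
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  vertex_measure(g, cc, "clustering")
}
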