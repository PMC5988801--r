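#' Forman-Ricci curvature of all edges
#'
#' Combinatorial (unweighted) Forman-Ricci curvature of every edge:
#' `F(e) = 4 - deg(v1) - deg(v2)` for an edge e = (v1, v2). This is the
#' 1-dimensional Bochner-Weitzenboeck discretization specialised to unit
#' weights; for weighted graphs see [forman_edge_weighted()].
#'
#' @param g An igraph object (undirected, simple).
#' @return An `edge_measure` table with one value per edge.
#' @export
forman_curvature <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  vals <- if (nrow(el) == 0L) numeric(0) else 4 - deg[el[, 1L]] - deg[el[, 2L]]
  edge_measure(g, vals, "forman")
}

#' Augmented Forman-Ricci curvature of all edges
#'
#' Forman-Ricci curvature with 3-cliques counted as 2-dimensional cells.
#' In unweighted graphs this reduces to `F#(e) = F(e) + 3 m`, where `m` is
#' the number of triangles containing the edge; cycles of length 4 and
#' greater are deliberately not filled in. The weighted general form is
#' available through [augmented_forman_edge_weighted()].
#'
#' @param g An igraph object (undirected, simple).
#' @return An `edge_measure` table with one value per edge.
#' @export
augmented_forman_curvature <- function(g) {
  f <- forman_curvature(g)
  edge_measure(g, f$value + 3 * edge_triangles(g), "augmented_forman")
}

# internal: validate weight lookups
.get_pos_weight <- function(w, key, what) {
  val <- if (is.null(w) || is.null(w[[key]])) 1 else w[[key]]
  if (!is.finite(val) || val <= 0) stop("nonpositive ", what, " weight for ", key)
  val
}

# internal: canonical string key for an edge / triangle over internal ids
.ekey <- function(a, b) paste0(min(a, b), "|", max(a, b))
.tkey <- function(tri) paste0(sort(tri), collapse = "|")

#' Weighted Forman-Ricci curvature of one edge
#'
#' Full weighted 1-dimensional Forman curvature of the edge e = (v1, v2):
#' \deqn{F(e) = w_e\Big(\frac{w_{v_1}}{w_e} + \frac{w_{v_2}}{w_e}
#'  - \sum_{e_{v_1} \sim e}\frac{w_{v_1}}{\sqrt{w_e w_{e_{v_1}}}}
#'  - \sum_{e_{v_2} \sim e}\frac{w_{v_2}}{\sqrt{w_e w_{e_{v_2}}}}\Big)}
#' where the sums run over edges incident on v1 (resp. v2) other than e
#' itself. With all weights 1 this reduces to `4 - deg(v1) - deg(v2)`.
#'
#' @param g An igraph object.
#' @param e Length-2 vector of internal vertex ids forming an edge.
#' @param vertex_weights Named list/vector: vertex id -> positive weight
#'   (missing entries default to 1).
#' @param edge_weights Named list: `"u|v"` (u < v, internal ids) -> positive
#'   weight (missing entries default to 1).
#' @return The curvature value (scalar).
#' @export
forman_edge_weighted <- function(g, e, vertex_weights = NULL,
                                 edge_weights = NULL) {
  stopifnot(length(e) == 2L)
  if (!igraph::are_adjacent(g, e[1L], e[2L])) {
    stop("(", e[1L], ",", e[2L], ") is not an edge of the graph")
  }
  v1 <- as.integer(e[1L]); v2 <- as.integer(e[2L])
  wv1 <- .get_pos_weight(vertex_weights, as.character(v1), "vertex")
  wv2 <- .get_pos_weight(vertex_weights, as.character(v2), "vertex")
  we <- .get_pos_weight(edge_weights, .ekey(v1, v2), "edge")
  adj <- adj_list(g)
  s1 <- sum(vapply(setdiff(adj[[v1]], v2), function(w) {
    wv1 / sqrt(we * .get_pos_weight(edge_weights, .ekey(v1, w), "edge"))
  }, 1.0))
  s2 <- sum(vapply(setdiff(adj[[v2]], v1), function(w) {
    wv2 / sqrt(we * .get_pos_weight(edge_weights, .ekey(v2, w), "edge"))
  }, 1.0))
  we * (wv1 / we + wv2 / we - s1 - s2)
}

#' Weighted augmented Forman-Ricci curvature of one edge
#'
#' General weighted Forman curvature of an edge in the 2-complex whose
#' 2-cells are the 3-cliques of the graph:
#' \deqn{F^{\#}(e) = w_e\Big[\Big(\sum_{e < f}\frac{w_e}{w_f}
#'   + \sum_{v < e}\frac{w_v}{w_e}\Big)
#'   - \sum_{\hat e \parallel e}\Big|\sum_{f > e, \hat e}
#'     \frac{\sqrt{w_e w_{\hat e}}}{w_f}
#'   - \sum_{v < e, \hat e}\frac{w_v}{\sqrt{w_e w_{\hat e}}}\Big|\Big]}
#' An edge \eqn{\hat e} is *parallel* to e when the two share a vertex
#' (common child) or a triangular face (common parent) but not both. With
#' triangles as the only 2-cells, an edge sharing a face with e always
#' also shares a vertex, so the parallel set is exactly the edges adjacent
#' to e that do not co-bound a triangle with e; for those the face sum in
#' the absolute value is empty. Face weights default to 1 on every 3-clique
#' containing e (faces are materialised lazily, only here).
#'
#' With all weights 1 this equals `forman + 3 m` on every edge
#' (m = triangles on the edge).
#'
#' @inheritParams forman_edge_weighted
#' @param face_weights Named list: `"a|b|c"` (sorted internal ids) ->
#'   positive weight for that 3-clique (missing entries default to 1).
#' @return The curvature value (scalar).
#' @export
augmented_forman_edge_weighted <- function(g, e, vertex_weights = NULL,
                                           edge_weights = NULL,
                                           face_weights = NULL) {
  stopifnot(length(e) == 2L)
  if (!igraph::are_adjacent(g, e[1L], e[2L])) {
    stop("(", e[1L], ",", e[2L], ") is not an edge of the graph")
  }
  v1 <- as.integer(e[1L]); v2 <- as.integer(e[2L])
  adj <- adj_list(g)
  wv1 <- .get_pos_weight(vertex_weights, as.character(v1), "vertex")
  wv2 <- .get_pos_weight(vertex_weights, as.character(v2), "vertex")
  we <- .get_pos_weight(edge_weights, .ekey(v1, v2), "edge")
  common <- intersect(adj[[v1]], adj[[v2]])  # apex of each triangle on e
  # faces containing e
  face_term <- sum(vapply(common, function(w) {
    we / .get_pos_weight(face_weights, .tkey(c(v1, v2, w)), "face")
  }, 1.0))
  # classify each adjacent edge: co-bounds a face with e iff its far
  # endpoint is a common neighbour of v1 and v2
  par_term <- 0
  for (side in list(c(v1, v2), c(v2, v1))) {
    a <- side[1L]; b <- side[2L]
    wa <- if (a == v1) wv1 else wv2
    for (w in setdiff(adj[[a]], b)) {
      we2 <- .get_pos_weight(edge_weights, .ekey(a, w), "edge")
      if (w %in% common) next  # shares vertex AND face: not parallel
      par_term <- par_term + abs(0 - wa / sqrt(we * we2))
    }
  }
  we * ((face_term + (wv1 + wv2) / we) - par_term)
}
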