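#' riccinet: discrete Ricci curvature and robustness analysis for networks
#'
#' Two discretizations of Ricci curvature for undirected graphs --
#' Ollivier-Ricci curvature from exact Wasserstein-1 optimal transport
#' between random-walk neighbourhood measures, and Forman-Ricci curvature
#' on (weighted) CW complexes with a triangle-augmented variant -- together
#' with random-graph generators, classical edge/vertex measures, ensemble
#' rank-correlation experiments and ranked-removal robustness experiments.
#'
#' @useDynLib riccinet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor runif uniroot
#' @importFrom utils write.table
#' @keywords internal
"_PACKAGE"

#' Read a whitespace-separated edge list
#'
#' Parses the edge-list dialect used by the KONECT network collection:
#' lines starting with `%` are comments, every other line carries at least
#' two whitespace-separated integer vertex ids; any further columns
#' (weights, timestamps) are ignored. The result is always a simple
#' undirected graph: duplicate lines and reversed duplicates collapse to a
#' single edge, and self-loop lines are dropped with a warning giving the
#' count. Original vertex labels are kept as the `name` vertex attribute;
#' internal ids are contiguous integers in order of first appearance.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph][igraph::graph] object.
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*%", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges in ", path)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge-list line ", idx[bad[1L]], " in ", path,
         ": fewer than 2 tokens")
  }
  u <- vapply(toks, function(t) t[[1L]], "")
  v <- vapply(toks, function(t) t[[2L]], "")
  if (anyNA(suppressWarnings(as.numeric(c(u, v))))) {
    nonnum <- which(is.na(suppressWarnings(as.numeric(u))) |
                      is.na(suppressWarnings(as.numeric(v))))[1L]
    stop("malformed edge-list line ", idx[nonnum], " in ", path,
         ": non-numeric vertex id")
  }
  loops <- u == v
  if (any(loops)) {
    warning(sum(loops), " self-loop line(s) dropped from ", path)
    u <- u[!loops]; v <- v[!loops]
  }
  if (length(u) == 0L) stop("no edges survive self-loop removal in ", path)
  labels <- unique(c(rbind(u, v)))
  g <- igraph::graph_from_edgelist(
    cbind(match(u, labels), match(v, labels)), directed = FALSE)
  igraph::V(g)$name <- labels
  ndup <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(g) < ndup) {
    message(ndup - igraph::ecount(g), " duplicate edge(s) collapsed")
  }
  g
}

#' Write a graph as a KONECT-style edge list
#'
#' @param g An igraph object.
#' @param path Output path.
#' @param comment Optional character vector written as `%`-prefixed header
#'   lines (used by the generators to record the model specification).
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path, comment = NULL) {
  el <- igraph::as_edgelist(g, names = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("%", comment), con)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  invisible(path)
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected component; ties between
#' equally large components are broken in favour of the component
#' containing the smallest vertex id. Vertex and edge attributes
#' (weights, names) are carried over.
#'
#' @param g An igraph object with at least one vertex.
#' @return The induced subgraph, an igraph object.
#' @export
largest_connected_component <- function(g) {
  stopifnot(igraph::vcount(g) >= 1L)
  comp <- igraph::components(g)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    # smallest minimum vertex id wins; membership indexes vertices in id order
    first_vertex <- vapply(cand, function(k) min(which(comp$membership == k)), 1L)
    cand <- cand[which.min(first_vertex)]
  }
  igraph::induced_subgraph(g, which(comp$membership == cand[1L]))
}

#' Number of triangles containing each edge
#'
#' For an edge (u, v) this is the number of common neighbours
#' |N(u) ∩ N(v)|, i.e. the number of 3-cliques the edge lies in.
#' Identical to the embeddedness of the edge.
#'
#' @param g An igraph object.
#' @param e Optional single edge as a length-2 vector of vertex ids
#'   (internal integer ids); if omitted, a vector over all edges in
#'   `igraph::E(g)` order is returned.
#' @return Integer vector of triangle counts.
#' @export
edge_triangles <- function(g, e = NULL) {
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  if (is.null(e)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    if (nrow(el) == 0L) return(integer(0))
    vapply(seq_len(nrow(el)), function(i) {
      length(intersect(adj[[el[i, 1L]]], adj[[el[i, 2L]]]))
    }, 1L)
  } else {
    stopifnot(length(e) == 2L)
    if (!igraph::are_adjacent(g, e[1L], e[2L])) {
      stop("(", e[1L], ",", e[2L], ") is not an edge of the graph")
    }
    length(intersect(adj[[e[1L]]], adj[[e[2L]]]))
  }
}

#' Shortest-path hop distances from one source
#'
#' Breadth-first hop counts on the unweighted graph. Unreachable vertices
#' are reported as `Inf` (an explicit sentinel, never a large finite
#' stand-in: downstream efficiency computations rely on 1/d being exactly
#' zero for unreachable pairs).
#'
#' @param g An igraph object.
#' @param source A single vertex id.
#' @return Numeric vector of distances indexed by vertex.
#' @export
hop_distances <- function(g, source) {
  d <- igraph::distances(g, v = source, weights = NA)
  as.numeric(d[1L, ])
}

# internal: adjacency list as plain integer vectors
adj_list <- function(g) lapply(igraph::as_adj_list(g, mode = "all"), as.integer)

#' Edge measure table
#'
#' A data frame with columns `u`, `v` (vertex names if present, else
#' internal ids, in `igraph::E(g)` order) and `value`, tagged with the
#' measure name and any parameters. All edge-level measures in the package
#' return this shape.
#'
#' @param g The graph the measure was computed on.
#' @param values Numeric vector aligned with `igraph::E(g)`.
#' @param measure Label for the measure.
#' @param ... Further attributes to record (e.g. `alpha`).
#' @return A data frame of class `edge_measure`.
#' @export
edge_measure <- function(g, values, measure, ...) {
  el <- igraph::as_edgelist(g, names = TRUE)
  stopifnot(length(values) == nrow(el))
  out <- data.frame(u = el[, 1L], v = el[, 2L], value = as.numeric(values),
                    stringsAsFactors = FALSE)
  attr(out, "measure") <- measure
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("edge_measure", "data.frame")
  out
}

#' Vertex measure table
#'
#' @param g The graph the measure was computed on.
#' @param values Numeric vector aligned with `igraph::V(g)`.
#' @param measure Label for the measure.
#' @param ... Further attributes to record.
#' @return A data frame of class `vertex_measure` with columns `v`, `value`.
#' @export
vertex_measure <- function(g, values, measure, ...) {
  stopifnot(length(values) == igraph::vcount(g))
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- seq_len(igraph::vcount(g))
  out <- data.frame(v = nm, value = as.numeric(values), stringsAsFactors = FALSE)
  attr(out, "measure") <- measure
  extra <- list(...)
  for (a in names(extra)) attr(out, a) <- extra[[a]]
  class(out) <- c("vertex_measure", "data.frame")
  out
}

#' Write a measure table as TSV
#'
#' Edge tables are written with a `u v value` header, vertex tables with
#' `v value`.
#'
#' @param tab An `edge_measure` or `vertex_measure` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measure_table <- function(tab, path) {
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.edge_measure <- function(x, ...) {
  cat("Edge measure:", attr(x, "measure"))
  if (!is.null(attr(x, "alpha"))) cat(" (alpha =", attr(x, "alpha"), ")")
  cat(", ", nrow(x), " edges\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
print.vertex_measure <- function(x, ...) {
  cat("Vertex measure:", attr(x, "measure"), ", ", nrow(x), " vertices\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Sum an edge measure into a vertex measure
#'
#' The curvature of a vertex is defined as the sum of the curvatures of the
#' edges incident on it (the discrete analogue of scalar curvature).
#' Isolated vertices get 0. Works for any edge-level measure.
#'
#' @param g The graph the edge table was computed on.
#' @param etab An `edge_measure` computed on `g`.
#' @return A `vertex_measure` of incident-edge sums.
#' @export
vertex_curvature <- function(g, etab) {
  stopifnot(inherits(etab, "edge_measure"), nrow(etab) == igraph::ecount(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  out <- numeric(igraph::vcount(g))
  for (i in seq_len(nrow(el))) {
    out[el[i, 1L]] <- out[el[i, 1L]] + etab$value[i]
    out[el[i, 2L]] <- out[el[i, 2L]] + etab$value[i]
  }
  vertex_measure(g, out, paste0("vertex_", attr(etab, "measure")),
                 alpha = attr(etab, "alpha"))
}
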