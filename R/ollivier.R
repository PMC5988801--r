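#' Random-walk neighbourhood measure of a vertex
#'
#' The one-step measure of the (possibly lazy) random walk at `x`: mass
#' `alpha` stays at `x` itself and the remaining `1 - alpha` is spread
#' uniformly over the neighbours of `x`. `alpha = 0` is the non-lazy walk
#' (no mass at `x`); `alpha = 0.5` is the conventional lazy walk.
#'
#' @param g An igraph object.
#' @param x A single vertex id (internal integer id).
#' @param alpha Idleness in \[0, 1).
#' @return A list of class `prob_measure` with fields `support` (vertex
#'   ids) and `mass` (nonnegative, summing to 1).
#' @export
neighbor_measure <- function(g, x, alpha = 0) {
  stopifnot(alpha >= 0, alpha < 1)
  x <- as.integer(x)
  nb <- as.integer(igraph::neighbors(g, x))
  if (length(nb) == 0L) stop("vertex ", x, " is isolated: no walk measure defined")
  if (alpha > 0) {
    support <- c(x, nb)
    mass <- c(alpha, rep((1 - alpha) / length(nb), length(nb)))
  } else {
    support <- nb
    mass <- rep(1 / length(nb), length(nb))
  }
  structure(list(support = support, mass = mass), class = "prob_measure")
}

#' @export
print.prob_measure <- function(x, ...) {
  cat("Probability measure on", length(x$support), "vertices\n")
  print(data.frame(vertex = x$support, mass = x$mass))
  invisible(x)
}

#' Wasserstein-1 distance between two measures on a graph
#'
#' Exact optimum of the transport linear program between `mu` and `nu`
#' with cost given by shortest-path hop distances on `g` (computed on the
#' whole graph, not the subgraph of the supports). Solved by successive
#' shortest augmenting paths with node potentials, which is exact for this
#' uncapacitated transportation problem.
#'
#' @param g An igraph object.
#' @param mu,nu `prob_measure` objects (see [neighbor_measure()]).
#' @return A list of class `transport_plan` with fields `cost` (the W1
#'   value), `plan` (matrix of shipped mass, rows = support of `mu`,
#'   columns = support of `nu`), and the two supports.
#' @export
wasserstein1 <- function(g, mu, nu) {
  stopifnot(inherits(mu, "prob_measure"), inherits(nu, "prob_measure"))
  stopifnot(abs(sum(mu$mass) - 1) < 1e-9, abs(sum(nu$mass) - 1) < 1e-9)
  d <- igraph::distances(g, v = mu$support, to = nu$support, weights = NA)
  if (any(!is.finite(d))) {
    stop("supports lie in different components: transport cost is infinite")
  }
  res <- cpp_transport(matrix(as.numeric(d), nrow = length(mu$support)),
                       mu$mass, nu$mass)
  structure(list(cost = res$cost, plan = res$plan,
                 from = mu$support, to = nu$support,
                 potential_from = res$u, potential_to = res$v),
            class = "transport_plan")
}

#' @export
print.transport_plan <- function(x, ...) {
  cat("Optimal transport plan, cost =", format(x$cost), "\n")
  dimnames(x$plan) <- list(x$from, x$to)
  print(round(x$plan, 6))
  invisible(x)
}

#' Ollivier-Ricci curvature of one edge
#'
#' For an edge (x, y), `kappa(x, y) = 1 - W1(m_x, m_y) / d(x, y)` where
#' `m_x`, `m_y` are the random-walk neighbourhood measures with idleness
#' `alpha` and `d(x, y) = 1` on an edge, so `kappa = 1 - W1`.
#'
#' @param g An igraph object.
#' @param e Length-2 vector of internal vertex ids forming an edge.
#' @param alpha Idleness in \[0, 1).
#' @return The curvature value (scalar).
#' @export
ollivier_edge <- function(g, e, alpha = 0) {
  stopifnot(length(e) == 2L)
  if (!igraph::are_adjacent(g, e[1L], e[2L])) {
    stop("(", e[1L], ",", e[2L], ") is not an edge of the graph")
  }
  mu <- neighbor_measure(g, e[1L], alpha)
  nu <- neighbor_measure(g, e[2L], alpha)
  1 - wasserstein1(g, mu, nu)$cost
}

#' Ollivier-Ricci curvature of all edges
#'
#' Batch computation of `kappa(e) = 1 - W1(m_x, m_y)` over every edge of a
#' connected graph. All support points of the two measures of an edge lie
#' within hop distance 3 of each other, so distances are obtained by
#' depth-limited breadth-first search and each transport problem is solved
#' exactly in compiled code.
#'
#' @param g A connected igraph object (apply [largest_connected_component()] first).
#' @param alpha Idleness in \[0, 1); default 0.5, the conventional lazy walk.
#' @return An `edge_measure` table with one value per edge, tagged with
#'   `alpha`.
#' @export
ollivier_curvature <- function(g, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha < 1)
  if (igraph::vcount(g) == 0L) stop("empty graph")
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; restrict to the largest connected ",
         "component (largest_connected_component) first")
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L) return(edge_measure(g, numeric(0), "ollivier", alpha = alpha))
  vals <- cpp_ollivier_all(igraph::vcount(g),
                           matrix(as.integer(el - 1L), ncol = 2L), alpha)
  edge_measure(g, vals, "ollivier", alpha = alpha)
}
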