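# Fixture builders and independent oracles used across the test files.
# Oracles are deliberately written with different algorithms from the
# package code paths they check.

star_graph <- function(m) {
  igraph::make_star(m + 1L, mode = "undirected", center = 1L)
}

# two stars with m and mp leaves, hubs joined by a bridge edge (hubs 1, 2)
double_star_graph <- function(m, mp) {
  edges <- c(1, 2,
             rbind(1, 2 + seq_len(m)),
             rbind(2, 2 + m + seq_len(mp)))
  igraph::make_graph(edges, directed = FALSE)
}

path_graph <- function(n) {
  igraph::make_graph(c(rbind(seq_len(n - 1), seq_len(n - 1) + 1)),
                     directed = FALSE)
}

# connected sparse random graph by rejection sampling
random_connected_graph <- function(n, p, seed) {
  for (s in seed + 0:200) {
    g <- generate_er(n, p, s)
    if (igraph::is_connected(g)) return(g)
  }
  stop("no connected sample found")
}

# ---- independent LP oracle (boot::simplex) --------------------------------

# primal transportation LP; one redundant column constraint dropped so the
# constraint matrix has full rank
lp_transport_cost <- function(cost, a, b) {
  S <- nrow(cost); T <- ncol(cost)
  A3 <- matrix(0, S + T - 1L, S * T)
  for (i in seq_len(S)) {
    for (j in seq_len(T)) {
      A3[i, (i - 1L) * T + j] <- 1
      if (j < T) A3[S + j, (i - 1L) * T + j] <- 1
    }
  }
  r <- boot::simplex(a = as.vector(t(cost)), A3 = A3, b3 = c(a, b[-T]),
                     maxi = FALSE)
  unname(r$value)
}

# dual LP: max sum a_i u_i + sum b_j v_j subject to u_i + v_j <= c_ij.
# Potentials are shifted by C = max(cost) to meet simplex's nonnegativity.
lp_transport_dual <- function(cost, a, b) {
  S <- nrow(cost); T <- ncol(cost)
  C <- max(cost)
  A1 <- matrix(0, S * T, S + T)
  rhs <- numeric(S * T)
  k <- 0L
  for (i in seq_len(S)) {
    for (j in seq_len(T)) {
      k <- k + 1L
      A1[k, i] <- 1; A1[k, S + j] <- 1
      rhs[k] <- cost[i, j] + 2 * C
    }
  }
  r <- boot::simplex(a = c(a, b), A1 = A1, b1 = rhs, maxi = TRUE)
  unname(r$value) - 2 * C
}

# ---- exhaustive integer brute force ---------------------------------------

# minimum transport cost by exhaustive recursion over all integer plans
# with row supplies A and column demands B (sum(A) == sum(B), small)
brute_force_transport <- function(cost, A, B) {
  S <- length(A); nT <- length(B)
  best <- Inf
  recurse <- function(i, rem, acc) {
    if (acc >= best) return(invisible())
    if (i > S) {
      best <<- min(best, acc)   # rem is necessarily all-zero here
      return(invisible())
    }
    # all compositions of row supply A[i] over nT columns bounded by rem
    comp <- function(j, left, rem, acc2) {
      if (acc2 >= best) return(invisible())
      if (j == nT) {
        if (left <= rem[nT]) {
          rem[nT] <- rem[nT] - left
          recurse(i + 1L, rem, acc2 + left * cost[i, nT])
        }
        return(invisible())
      }
      for (x in 0:min(left, rem[j])) {
        rem2 <- rem; rem2[j] <- rem2[j] - x
        comp(j + 1L, left - x, rem2, acc2 + x * cost[i, j])
      }
    }
    comp(1L, A[i], rem, acc)
  }
  recurse(1L, B, 0)
  best
}

# exact W1 between non-lazy neighbour measures of an edge, by scaling the
# rational masses to integers and exhausting all integer plans
brute_force_w1_edge <- function(g, e) {
  nu_ <- as.integer(igraph::neighbors(g, e[1L]))
  nv_ <- as.integer(igraph::neighbors(g, e[2L]))
  d <- igraph::distances(g, v = nu_, to = nv_, weights = NA)
  D <- length(nu_) * length(nv_)
  A <- rep(D / length(nu_), length(nu_))
  B <- rep(D / length(nv_), length(nv_))
  brute_force_transport(d, as.integer(A), as.integer(B)) / D
}

# ---- exhaustive geodesic enumeration for betweenness ----------------------

# lists every shortest path between s and t as vertex sequences
all_geodesics <- function(g, s, t) {
  d <- as.numeric(igraph::distances(g, v = s, weights = NA))
  if (!is.finite(d[t])) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == s) {
      paths[[length(paths) + 1L]] <<- rev(acc)
      return()
    }
    for (w in as.integer(igraph::neighbors(g, v))) {
      if (d[w] == d[v] - 1) walk(w, c(acc, w))
    }
  }
  walk(t, t)
  paths
}

# edge and vertex betweenness by enumerating all geodesics of all pairs
brute_force_betweenness <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  ekey <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  eb <- numeric(nrow(el)); vb <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in seq.int(s + 1L, n)) {
      paths <- all_geodesics(g, s, t)
      np <- length(paths)
      if (np == 0L) next
      for (p in paths) {
        if (length(p) > 2L) {
          inner <- p[-c(1L, length(p))]
          vb[inner] <- vb[inner] + 1 / np
        }
        a <- p[-length(p)]; b <- p[-1L]
        idx <- match(paste(pmin(a, b), pmax(a, b)), ekey)
        eb[idx] <- eb[idx] + 1 / np
      }
    }
  }
  list(edge = eb, vertex = vb)
}
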