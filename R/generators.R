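#' Model specification for a random-graph ensemble
#'
#' Bundles a generator name and its parameters so that ensemble experiments
#' can draw repeated seeded samples from the same model.
#'
#' @param model One of `"er"`, `"ws"`, `"ba"`, `"hgg"`.
#' @param n Number of vertices (all models).
#' @param p ER edge probability.
#' @param k WS lattice degree (even).
#' @param beta WS rewiring probability.
#' @param m BA edges per arriving vertex.
#' @param m0 BA seed-graph size (optional; defaults to `max(m, 2)`).
#' @param k_target HGG target average degree.
#' @param gamma HGG power-law exponent (default 2).
#' @param temp HGG temperature (only 0 is supported).
#' @return A list of class `model_spec` with fields `model` and `params`.
#' @export
model_spec <- function(model = c("er", "ws", "ba", "hgg"), n = NULL,
                       p = NULL, k = NULL, beta = NULL, m = NULL, m0 = NULL,
                       k_target = NULL, gamma = NULL, temp = NULL) {
  model <- match.arg(model)
  params <- list(n = n, p = p, k = k, beta = beta, m = m, m0 = m0,
                 k_target = k_target, gamma = gamma, temp = temp)
  params <- params[!vapply(params, is.null, TRUE)]
  required <- switch(model,
    er = c("n", "p"), ws = c("n", "k", "beta"), ba = c("n", "m"),
    hgg = c("n", "k_target"))
  missing <- setdiff(required, names(params))
  if (length(missing) > 0L) {
    stop("missing ", toupper(model), " parameter(s): ",
         paste(missing, collapse = ", "))
  }
  structure(list(model = model, params = params), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model:", toupper(x$model), " ")
  cat(paste(names(x$params), unlist(x$params), sep = "="), "\n")
  invisible(x)
}

#' Draw one seeded sample from a model specification
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed; samples are deterministic given `(spec, seed)`.
#' @return An igraph object.
#' @export
sample_network <- function(spec, seed) {
  stopifnot(inherits(spec, "model_spec"))
  p <- spec$params
  switch(spec$model,
    er  = generate_er(p$n, p$p, seed),
    ws  = generate_ws(p$n, p$k, p$beta, seed),
    ba  = if (is.null(p$m0)) generate_ba(p$n, p$m, seed)
          else generate_ba(p$n, p$m, seed, p$m0),
    hgg = generate_hgg(p$n, p$k_target,
                       gamma = if (is.null(p$gamma)) 2 else p$gamma,
                       temp = if (is.null(p$temp)) 0 else p$temp,
                       seed = seed))
}

# internal: igraph from a 2-column matrix of vertex ids on exactly n vertices
graph_from_pairs <- function(el, n) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  g
}

#' Erdos-Renyi random graph G(n, p)
#'
#' Each of the choose(n, 2) vertex pairs is included independently with
#' probability `p` under the seeded generator.
#'
#' @param n Number of vertices (>= 2).
#' @param p Edge probability in \[0, 1\].
#' @param seed Integer seed.
#' @return An igraph object with `n` vertices.
#' @export
generate_er <- function(n, p, seed) {
  stopifnot(n >= 2, p >= 0, p <= 1)
  set.seed(seed)
  # enumerate all pairs (i < j) row-wise: (1,2),(1,3),...,(1,n),(2,3),...
  u <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  v <- sequence((n - 1L):1L, from = 2:n)
  keep <- runif(length(u)) < p
  graph_from_pairs(cbind(u[keep], v[keep]), n)
}

#' Watts-Strogatz small-world graph
#'
#' Starts from a ring lattice on `n` vertices in which every vertex is
#' joined to its `k` nearest neighbours (`k` even, `n k / 2` edges). One
#' endpoint of each lattice edge -- the clockwise one -- is then rewired
#' with probability `beta` to a vertex chosen uniformly at random;
#' proposals creating self-loops or duplicate edges are redrawn (up to `n`
#' attempts, after which the edge is left in place), so the edge count
#' `n k / 2` is preserved exactly.
#'
#' @param n Number of vertices.
#' @param k Even lattice degree, `k < n`.
#' @param beta Rewiring probability in \[0, 1\].
#' @param seed Integer seed.
#' @return An igraph object with `n` vertices and `n k / 2` edges.
#' @export
generate_ws <- function(n, k, beta, seed) {
  stopifnot(n >= 2, k %% 2 == 0, k >= 2, k < n, beta >= 0, beta <= 1)
  set.seed(seed)
  half <- k %/% 2
  u <- rep(seq_len(n), each = half)
  v <- ((u - 1 + rep(seq_len(half), times = n)) %% n) + 1  # clockwise endpoint
  m <- length(u)
  # O(1) membership checks via an environment keyed on canonical pair ids
  key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  seen <- new.env(hash = TRUE, size = 2L * m)
  for (i in seq_len(m)) assign(key(u[i], v[i]), TRUE, envir = seen)
  rew <- runif(m) < beta
  for (i in which(rew)) {
    for (attempt in seq_len(n)) {
      w <- sample.int(n, 1L)
      if (w == u[i]) next
      if (exists(key(u[i], w), envir = seen, inherits = FALSE)) next
      rm(list = key(u[i], v[i]), envir = seen)
      assign(key(u[i], w), TRUE, envir = seen)
      v[i] <- w
      break
    }
  }
  graph_from_pairs(cbind(u, v), n)
}

#' Barabasi-Albert preferential-attachment graph
#'
#' Growth starts from a connected seed path on `m0` vertices
#' (`m0 = max(m, 2)` by default). Each arriving vertex attaches `m`
#' distinct edges to existing vertices drawn with probability proportional
#' to their current degree (linear preferential attachment, sampled
#' without replacement via the repeated-edge-endpoint urn).
#'
#' @param n Final number of vertices.
#' @param m Edges added per arriving vertex, `1 <= m <= m0 <= n`.
#' @param seed Integer seed.
#' @param m0 Seed-graph size; defaults to `max(m, 2)`.
#' @return An igraph object with `n` vertices and
#'   `(m0 - 1) + m (n - m0)` edges.
#' @export
generate_ba <- function(n, m, seed, m0 = max(m, 2L)) {
  stopifnot(m >= 1, m <= m0, m0 <= n)
  set.seed(seed)
  n_edges <- (m0 - 1L) + m * (n - m0)
  eu <- integer(n_edges); ev <- integer(n_edges)
  # urn of edge endpoints: vertex v appears deg(v) times
  urn <- integer(2L * n_edges)
  # seed path 1-2-...-m0
  ne <- m0 - 1L
  if (ne > 0L) {
    eu[seq_len(ne)] <- seq_len(ne)
    ev[seq_len(ne)] <- seq_len(ne) + 1L
    urn[seq_len(2L * ne)] <- c(rbind(seq_len(ne), seq_len(ne) + 1L))
  }
  top <- 2L * ne
  for (vnew in seq_len(n - m0) + m0) {
    targets <- integer(0L)
    while (length(targets) < m) {
      cand <- urn[sample.int(top, 1L)]
      if (!(cand %in% targets)) targets <- c(targets, cand)
    }
    idx <- ne + seq_len(m)
    eu[idx] <- vnew; ev[idx] <- targets
    urn[top + seq_len(2L * m)] <- c(rbind(rep(vnew, m), targets))
    top <- top + 2L * m
    ne <- ne + m
  }
  graph_from_pairs(cbind(eu, ev), n)
}

# internal: hyperbolic distance between points (r1, th1) and (r2, th2)
# on the hyperbolic plane with curvature constant zeta = 1
hyperbolic_distance <- function(r1, th1, r2, th2) {
  dth <- pi - abs(pi - abs(th1 - th2))
  arg <- cosh(r1) * cosh(r2) - sinh(r1) * sinh(r2) * cos(dth)
  acosh(pmax(arg, 1))
}

# internal: disk radius R such that expected average degree is k_target,
# estimated by Monte Carlo with common random numbers and solved by uniroot
hgg_solve_radius <- function(n, k_target, alpha, n_mc = 200000L) {
  u1 <- runif(n_mc); u2 <- runif(n_mc); dth <- runif(n_mc, 0, pi)
  expected_degree <- function(R) {
    c0 <- cosh(alpha * R) - 1
    r1 <- acosh(1 + u1 * c0) / alpha
    r2 <- acosh(1 + u2 * c0) / alpha
    (n - 1) * mean(hyperbolic_distance(r1, dth, r2, 0) <= R)
  }
  # expected degree decreases in R over the relevant range
  lo <- 1e-3; hi <- 2 * log(n)
  while (expected_degree(hi) > k_target && hi < 100) hi <- hi * 1.5
  uniroot(function(R) expected_degree(R) - k_target, c(lo, hi),
          tol = 1e-3)$root
}

#' Hyperbolic random geometric graph (T = 0)
#'
#' Places `n` vertices on a hyperbolic disk -- angular coordinate uniform
#' on \[0, 2*pi), radial coordinate with density proportional to
#' `alpha * sinh(alpha * r)` on \[0, R\] with `alpha = (gamma - 1) / 2`
#' and curvature constant 1 -- and connects every pair at hyperbolic
#' distance at most `R`. The disk radius `R` is calibrated numerically
#' (Monte-Carlo estimate of the expected degree, root-finding in `R`) so
#' that the expected average degree equals `k_target`. The resulting
#' ensemble has a power-law degree distribution with exponent `gamma` and
#' non-vanishing clustering. Only the hard-threshold `temp = 0` regime is
#' supported.
#'
#' @param n Number of vertices.
#' @param k_target Target average degree.
#' @param gamma Power-law exponent (> 1); default 2.
#' @param temp Temperature; must be 0.
#' @param seed Integer seed.
#' @return An igraph object with `n` vertices.
#' @export
generate_hgg <- function(n, k_target, gamma = 2, temp = 0, seed) {
  stopifnot(n >= 2, k_target > 0, gamma > 1)
  if (temp != 0) stop("only the temperature-0 (hard threshold) regime is supported")
  set.seed(seed)
  alpha <- (gamma - 1) / 2
  R <- hgg_solve_radius(n, k_target, alpha)
  th <- runif(n, 0, 2 * pi)
  r <- acosh(1 + runif(n) * (cosh(alpha * R) - 1)) / alpha
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- hyperbolic_distance(r[pairs[, 1L]], th[pairs[, 1L]],
                           r[pairs[, 2L]], th[pairs[, 2L]])
  el <- pairs[d <= R, , drop = FALSE]
  g <- graph_from_pairs(cbind(as.integer(el[, 1L]), as.integer(el[, 2L])), n)
  igraph::graph_attr(g, "hgg_R") <- R
  g
}
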