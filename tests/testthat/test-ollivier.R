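test_that("neighbour measures put alpha at the centre and spread the rest uniformly", {
  st <- star_graph(5)
  hub <- neighbor_measure(st, 1, alpha = 0)
  expect_setequal(hub$support, 2:6)
  expect_equal(hub$mass, rep(1 / 5, 5))

  leaf <- neighbor_measure(st, 2, alpha = 0)
  expect_equal(leaf$support, 1L)
  expect_equal(leaf$mass, 1)

  k5 <- igraph::make_full_graph(5)
  lazy <- neighbor_measure(k5, 1, alpha = 0.5)
  expect_equal(lazy$support[1], 1L)
  expect_equal(lazy$mass, c(0.5, rep(0.125, 4)))
  expect_equal(sum(lazy$mass), 1)

  iso <- igraph::add_vertices(st, 1)
  expect_error(neighbor_measure(iso, 7, 0), "isolated")
})

test_that("Wasserstein-1 matches identity, point-mass and triangle worked cases", {
  k3 <- igraph::make_full_graph(3)
  mu <- neighbor_measure(k3, 1, 0)
  expect_equal(wasserstein1(k3, mu, mu)$cost, 0)

  p4 <- path_graph(4)
  d_ab <- wasserstein1(p4,
                       structure(list(support = 1L, mass = 1), class = "prob_measure"),
                       structure(list(support = 4L, mass = 1), class = "prob_measure"))
  expect_equal(d_ab$cost, 3)

  nu <- neighbor_measure(k3, 2, 0)
  expect_equal(wasserstein1(k3, mu, nu)$cost, 0.5)

  disc <- igraph::make_graph(c(1, 2, 3, 4), directed = FALSE)
  expect_error(
    wasserstein1(disc,
                 structure(list(support = 1L, mass = 1), class = "prob_measure"),
                 structure(list(support = 3L, mass = 1), class = "prob_measure")),
    "different components")
})

test_that("transport LP equals exhaustive enumeration, independent simplex and its dual", {
  skip_if_not_installed("boot")
  set.seed(31)
  n_checked <- 0L
  for (s in 1:15) {
    g <- random_connected_graph(sample(6:12, 1), 0.3, seed = 100 + s)
    el <- igraph::as_edgelist(g, names = FALSE)
    for (i in seq_len(nrow(el))) {
      u <- el[i, 1]; v <- el[i, 2]
      mu <- neighbor_measure(g, u, 0)
      nu <- neighbor_measure(g, v, 0)
      w <- wasserstein1(g, mu, nu)
      cost <- igraph::distances(g, v = mu$support, to = nu$support, weights = NA)
      expect_equal(w$cost, lp_transport_cost(cost, mu$mass, nu$mass),
                   tolerance = 1e-9)
      expect_equal(w$cost, lp_transport_dual(cost, mu$mass, nu$mass),
                   tolerance = 1e-9)
      # exhaustive integer enumeration where the state space is small
      if (igraph::degree(g, u) * igraph::degree(g, v) <= 12) {
        expect_equal(w$cost, brute_force_w1_edge(g, c(u, v)), tolerance = 1e-9)
        n_checked <- n_checked + 1L
      }
      # plan certificates: marginals and cost attainment
      expect_equal(rowSums(w$plan), mu$mass, tolerance = 1e-9)
      expect_equal(colSums(w$plan), nu$mass, tolerance = 1e-9)
      expect_true(all(w$plan >= -1e-12))
      expect_equal(sum(w$plan * cost), w$cost, tolerance = 1e-9)
    }
  }
  expect_gte(n_checked, 30L)  # enumeration oracle actually exercised
})

test_that("W1 obeys the metric axioms on random neighbour-measure triples", {
  for (s in 1:10) {
    g <- random_connected_graph(sample(8:15, 1), 0.3, seed = 200 + s)
    vs <- sample(igraph::vcount(g), 3)
    ms <- lapply(vs, function(v) neighbor_measure(g, v, 0.3))
    d12 <- wasserstein1(g, ms[[1]], ms[[2]])$cost
    d21 <- wasserstein1(g, ms[[2]], ms[[1]])$cost
    d13 <- wasserstein1(g, ms[[1]], ms[[3]])$cost
    d23 <- wasserstein1(g, ms[[2]], ms[[3]])$cost
    expect_equal(d12, d21, tolerance = 1e-9)                  # symmetry
    expect_lte(d13, d12 + d23 + 1e-9)                         # triangle
    expect_equal(wasserstein1(g, ms[[1]], ms[[1]])$cost, 0)   # identity
  }
})

test_that("edge curvature reproduces the star, triangle and path worked examples", {
  st <- star_graph(5)
  expect_equal(ollivier_edge(st, c(1, 2), 0), 0)
  expect_equal(ollivier_curvature(st, alpha = 0)$value, rep(0, 5))

  k3 <- igraph::make_full_graph(3)
  expect_equal(ollivier_edge(k3, c(1, 2), 0), 0.5)
  expect_equal(ollivier_curvature(k3, alpha = 0)$value, rep(0.5, 3))

  p3 <- path_graph(3)
  expect_equal(ollivier_edge(p3, c(1, 2), 0), 0)

  k2 <- path_graph(2)
  expect_equal(ollivier_curvature(k2, alpha = 0)$value, 0)

  expect_error(ollivier_edge(st, c(2, 3), 0), "not an edge")
})

test_that("batch curvature equals the single-edge route and is label-invariant", {
  for (s in 1:6) {
    g <- random_connected_graph(sample(8:14, 1), 0.3, seed = 300 + s)
    for (al in c(0, 0.5)) {
      batch <- ollivier_curvature(g, alpha = al)$value
      el <- igraph::as_edgelist(g, names = FALSE)
      single <- vapply(seq_len(nrow(el)), function(i) {
        ollivier_edge(g, el[i, ], al)
      }, 1.0)
      expect_equal(batch, single, tolerance = 1e-9)
    }
  }

  # permuting vertex labels leaves the multiset of curvatures unchanged
  g <- random_connected_graph(12, 0.3, seed = 77)
  set.seed(1)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  expect_equal(sort(ollivier_curvature(g, 0.5)$value),
               sort(ollivier_curvature(g2, 0.5)$value), tolerance = 1e-9)
})

test_that("curvature is bounded in [-2, 1] at alpha 0 and grows toward 1 on complete graphs", {
  for (s in 1:8) {
    g <- random_connected_graph(sample(6:20, 1), 0.3, seed = 400 + s)
    k <- ollivier_curvature(g, alpha = 0)$value
    expect_true(all(k >= -2 - 1e-9 & k <= 1 + 1e-9))
  }
  kap <- vapply(c(3, 5, 10, 20, 40), function(n) {
    ollivier_curvature(igraph::make_full_graph(n), alpha = 0)$value[1]
  }, 1.0)
  expect_true(all(diff(kap) >= -1e-12))   # nondecreasing in n
  expect_gt(kap[3], kap[1])               # K_10 strictly above K_3
})

test_that("vertex curvature sums incident edges and satisfies the handshake identity", {
  k3 <- igraph::make_full_graph(3)
  or <- ollivier_curvature(k3, alpha = 0)
  expect_equal(vertex_curvature(k3, or)$value, rep(1, 3))

  st <- star_graph(5)
  or_st <- ollivier_curvature(st, alpha = 0)
  expect_equal(vertex_curvature(st, or_st)$value, rep(0, 6))

  g <- random_connected_graph(15, 0.25, seed = 55)
  or_g <- ollivier_curvature(g, 0.5)
  expect_equal(sum(vertex_curvature(g, or_g)$value), 2 * sum(or_g$value))
})

test_that("batch curvature refuses disconnected input", {
  disc <- igraph::make_graph(c(1, 2, 3, 4), directed = FALSE)
  expect_error(ollivier_curvature(disc, 0.5), "largest connected")
})
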