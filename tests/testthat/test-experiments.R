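test_that("rank correlation handles monotone, hand-ranked and degenerate inputs", {
  x <- c(2, 5, 9, 11)
  expect_equal(rank_correlation(x, exp(x)), 1)
  expect_equal(rank_correlation(x, -x^3), -1)
  expect_equal(rank_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(rank_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")

  # spearman is invariant under strictly monotone transforms of either input
  set.seed(8)
  a <- rnorm(40); b <- rnorm(40)
  r0 <- rank_correlation(a, b)
  expect_equal(rank_correlation(exp(a), b), r0)
  expect_equal(rank_correlation(a, atan(b)), r0)
  expect_equal(rank_correlation(2 * a + 7, b^3), r0)
  # pearson differs in general
  expect_false(isTRUE(all.equal(
    rank_correlation(exp(a), b, "pearson"),
    rank_correlation(a, b, "pearson"))))
})

test_that("ensemble correlation reports self-correlation 1 and drops degenerate samples", {
  sp <- model_spec("er", n = 40, p = 0.1)
  rep1 <- ensemble_correlation(sp, c("fr", "fr"), "edge", n_samples = 5,
                               base_seed = 3)
  expect_equal(rep1$per_sample, rep(1, 5))
  expect_equal(rep1$mean, 1)

  # a ring lattice has constant curvature: correlation undefined, all dropped
  sp2 <- model_spec("ws", n = 30, k = 4, beta = 0)
  rep2 <- ensemble_correlation(sp2, c("fr", "afr"), "edge", n_samples = 3,
                               base_seed = 1)
  expect_equal(rep2$n_dropped, 3L)

  # shared-sample batch equals independent runs with the same base seed
  sp3 <- model_spec("er", n = 60, p = 0.08)
  batch <- ensemble_correlations(
    sp3, list(list(pair = c("fr", "ebc"), level = "edge"),
              list(pair = c("deg", "bc"), level = "vertex")),
    n_samples = 4, base_seed = 11)
  solo1 <- ensemble_correlation(sp3, c("fr", "ebc"), "edge", 4, base_seed = 11)
  solo2 <- ensemble_correlation(sp3, c("deg", "bc"), "vertex", 4, base_seed = 11)
  expect_equal(batch[[1]]$per_sample, solo1$per_sample)
  expect_equal(batch[[2]]$per_sample, solo2$per_sample)
})

test_that("communication efficiency matches hand evaluations", {
  for (n in c(3, 6, 11)) {
    expect_equal(communication_efficiency(igraph::make_full_graph(n)), 0.5)
  }
  expect_equal(communication_efficiency(path_graph(3)), 5 / 12)
  empty <- igraph::make_empty_graph(4, directed = FALSE)
  expect_equal(communication_efficiency(empty), 0)
  # unreachable pairs contribute exactly zero
  two_k2 <- igraph::make_graph(c(1, 2, 3, 4), directed = FALSE)
  expect_equal(communication_efficiency(two_k2), 2 / 12)
})

test_that("removal experiments start intact, end empty and respect the ranking", {
  g <- largest_connected_component(generate_er(60, 0.08, seed = 21))
  e0 <- communication_efficiency(g)
  curve <- removal_experiment(g, "edge", "fr_asc", fractions = c(0, 0.5, 1))
  expect_equal(curve$efficiency[1], e0)
  expect_equal(curve$efficiency[3], 0)
  expect_true(all(diff(curve$efficiency) <= 1e-12))

  # K3, one edge removed by a deterministic strategy: path efficiency 5/12
  k3 <- igraph::make_full_graph(3)
  c3 <- removal_experiment(k3, "edge", "fr_asc", fractions = c(0, 1 / 3))
  expect_equal(c3$efficiency[2], 5 / 12)

  expect_error(removal_experiment(g, "edge", "deg_desc"), "unknown strategy")
  expect_error(removal_experiment(g, "vertex", "ebc_desc"), "unknown strategy")

  # vertex removal keeps the intact reference count
  cv <- removal_experiment(g, "vertex", "deg_desc", fractions = c(0, 0.5))
  expect_lt(cv$efficiency[2], e0)
})

test_that("curve AUC comparison requires a common grid and orders strategies", {
  g <- largest_connected_component(generate_er(80, 0.06, seed = 2))
  grid <- seq(0, 1, by = 0.1)
  cs <- lapply(c("ebc_desc", "random"), function(st) {
    removal_experiment(g, "edge", st, fractions = grid, seed = 5)
  })
  rep <- targeted_vs_random_gap(cs)
  expect_equal(rep$strategy[1], "ebc_desc")  # targeted disintegrates faster
  expect_equal(removal_auc(cs[[1]]), rep$auc[1])

  # duplicated curve gives identical AUC
  expect_equal(removal_auc(cs[[2]]), removal_auc(cs[[2]]))

  bad <- removal_experiment(g, "edge", "random", fractions = c(0, 1), seed = 5)
  expect_error(targeted_vs_random_gap(list(cs[[1]], bad)), "common fraction grid")
})
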