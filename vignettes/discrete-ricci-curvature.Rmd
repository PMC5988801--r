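---
title: "Discrete Ricci curvature on networks: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete Ricci curvature on networks: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riccinet)
```

## The two discretizations

In Riemannian geometry the Ricci tensor controls how geodesics disperse and
how volumes of balls grow. On a graph there is no canonical analogue, and the
two discretizations implemented here inherit *different* aspects of the
smooth notion.

**Ollivier-Ricci curvature** compares the distance between two vertices with
the optimal-transport distance between their neighbourhoods. Each vertex `x`
carries the one-step measure of a random walk with idleness `alpha`: mass
`alpha` stays at `x`, the rest is uniform on its neighbours. For an edge
`(x, y)` (graph distance 1),

$$\kappa(x,y) = 1 - W_1(m_x, m_y),$$

where $W_1$ is the Wasserstein-1 (earth mover) distance under combinatorial
hop distances: the cheapest way to morph $m_x$ into $m_y$, a linear program
over transport plans with the two measures as marginals. Neighbourhoods that
overlap (triangles, short cycles) make transport cheap and curvature
positive; tree-like separation makes it negative. $\kappa \in [-2, 1]$ at
`alpha = 0` because all support points are within three hops of each other.

**Forman-Ricci curvature** comes from a discrete Bochner–Weitzenböck
decomposition on weighted CW complexes. On an unweighted graph it collapses
to the purely local

$$F(e) = 4 - \deg(v_1) - \deg(v_2),$$

a dispersal measure blind to triangles. The **augmented** variant fills
every 3-clique with a 2-cell before applying Forman's weighted formula;
with unit weights this gives $F^{\#}(e) = F(e) + 3m$ with $m$ the number of
triangles containing $e$. Cycles of length 4 and greater are deliberately
not filled: triangles are where the two discretizations disagree most, and
the augmentation targets exactly that term. The weighted forms
(`forman_edge_weighted()`, `augmented_forman_edge_weighted()`) accept
arbitrary positive vertex/edge/face weights; face weights are materialised
lazily and only for the 3-cliques touching the requested edge.

The *parallelism* bookkeeping of the weighted augmented formula follows the
CW-complex rule: an edge sharing a vertex (common child) **and** a
triangle (common parent) with `e` is not parallel and drops out; an edge
sharing only a vertex contributes through the vertex term. With triangles
as the only 2-cells an edge can never share a face without sharing a
vertex, so the parallel set is exactly the adjacent edges not co-bounding a
triangle with `e`. For unit weights this reproduces $F + 3m$ on every edge,
which the test suite verifies on hundreds of random graphs. For general
weights the absolute value in the formula mixes face and vertex
contributions per parallel edge; we implement the classification literally
and make no claims beyond it, since no weighted worked example is available
to pin down conventions further.

**Vertex curvature** (both notions) is the sum of the curvatures of the
incident edges — the discrete scalar curvature. It therefore satisfies
$\sum_v \kappa(v) = 2 \sum_e \kappa(e)$, which the tests assert.

## Computing the transport problem exactly

`wasserstein1()` and the batch `ollivier_curvature()` solve each transport
problem *exactly* by successive shortest augmenting paths with node
potentials (Dijkstra on the bipartite residual network). No entropic or
Sinkhorn approximation is used: curvature values feed rank correlations,
where even a small systematic bias could reorder thousands of near-tied
edges. The problems are tiny — supports are the closed neighbourhoods of
the two endpoints — so exactness costs little. The batch path exploits the
fact that for an edge `(x, y)` every pair of support points is within hop
distance 3, so a depth-3 breadth-first search per support vertex yields
exact costs without an all-pairs computation.

Correctness of the solver is established in the tests by three independent
routes: an exhaustive enumeration of all integer transport plans (after
scaling the rational masses to a common denominator), an independent
simplex solver on the primal LP, and the same on the dual LP (best
potential pair), whose agreement certifies optimality by strong duality.
The returned plan is checked against its marginals and its cost.

## Idleness

The worked star/triangle/path examples assume the non-lazy walk
(`alpha = 0`), and the single-edge examples in the documentation use it.
For ensemble experiments the default is `alpha = 0.5`, the conventional
lazy random walk, matching the lazy-walk choice of the reference
implementation behind the published model-network tables. Rank correlations
are insensitive to this choice — the end-to-end tests recompute one
ensemble at `alpha = 0` and find the Spearman mean within 0.05 of the
lazy-walk value — but both knobs are exposed and every output records its
`alpha`.

## Random-graph ensembles

The four generators are seeded and deterministic given `(params, seed)`;
ensembles use consecutive seeds `base_seed + 0, 1, ...` so any sample can
be regenerated.

* **ER** `G(n, p)`: every pair independently with probability `p`.
* **WS** small worlds: ring lattice with `k` nearest neighbours
  (`nk/2` edges); with probability `beta` the *clockwise* endpoint of each
  lattice edge is rewired to a uniformly random vertex, redrawing proposals
  that would create loops or duplicates (up to `n` attempts, then the edge
  stays). Exactly one endpoint per edge is ever a rewiring candidate, and
  the edge count is conserved exactly.
* **BA** preferential attachment: the published description leaves the seed
  graph open; we use a path on `m0 = max(m, 2)` vertices, which is the
  smallest connected seed guaranteeing `m` distinct attachment targets.
  Attachment samples without replacement from the urn of edge endpoints
  (probability proportional to current degree). The convention is recorded
  in generator metadata since correlations could be mildly sensitive to it.
* **HGG** hyperbolic geometric graphs at temperature 0: angular coordinate
  uniform, radial density $\propto \alpha\sinh(\alpha r)$ with
  $\alpha = (\gamma - 1)/2$ and curvature constant 1; vertices connect iff
  their hyperbolic distance is at most the disk radius `R`. `R` is
  calibrated by root-finding on a Monte-Carlo estimate (200k pairs, common
  random numbers) of the expected average degree so that it matches
  `k_target`; the generator tests verify the realised mean degree lands
  within 15% of the target. Positive temperature regimes are out of scope.

## Comparison measures and experiments

Edge betweenness, vertex betweenness, degree and local clustering come from
igraph; betweenness is left unnormalized because Spearman/Pearson
correlations are invariant to positive scaling. Embeddedness is the
per-edge triangle count. Dispersion is the *absolute* variant: the number
of common-neighbour pairs of the edge's endpoints that are non-adjacent and
share no neighbour besides the two endpoints. The original social-network
definition admits several normalizations; the absolute form is used
throughout and correlations involving dispersion are property-tested rather
than matched to published values, which were computed with an unstated
variant.

`ensemble_correlation()` draws seeded samples, restricts each to its
largest connected component (needed for finite transport distances; we use
the same component for *both* measures of a pair so the vectors align),
computes both measures and reports per-sample Spearman (or Pearson)
correlations and their mean. Degenerate samples — e.g. a `beta = 0` ring
lattice where curvature is constant — are dropped and counted rather than
silently contributing NA.

**Robustness.** `communication_efficiency()` implements
$E = \frac{1}{n(n-1)} \sum_{i<j} 1/d_{ij}$ exactly as printed in the
source material, i.e. with unordered pairs and maximum 1/2 on complete
graphs; the more common ordered-pairs convention differs only by a factor
of 2 and would change no ordering. Unreachable pairs contribute exactly
zero, which is why unreachable distances are `Inf` sentinels rather than
large numbers. `removal_experiment()` ranks edges or vertices *once* on
the intact graph — static ranking; the published removal curves are
consistent with it and recomputation after every deletion would be a
different (and far costlier) protocol — then deletes cumulatively and
evaluates efficiency on the fraction grid, holding `n_reference` at the
intact vertex count so curves are comparable across strategies. Ties are
broken by ascending edge/vertex id for reproducibility.

## Problem sizes used in the tests

The published model-network tables average over 100 samples of
1000-vertex graphs. The end-to-end tests reproduce the ER
(`p = 0.003`), WS (`k = 10, beta = 0.5`) and BA (`m = 2`) rows at
`n = 1000` with 25 samples, which keeps the ensemble means well within
the ±0.05 band used for comparison (per-sample Spearman values on graphs
with thousands of edges have low variance, so the sampling error of a
25-sample mean is of order 0.01). Removal-curve orderings are checked on
one sample per model over a fraction grid of step 0.05; the orderings are
insensitive to the grid resolution. Oracle sweeps (enumeration, simplex,
geodesic census) run on graphs of up to 12 vertices where exhaustive
computation is feasible.

## What the synthetic ensembles do and do not show

The generators emulate the degree heterogeneity (BA, HGG), clustering
(WS, HGG) and homogeneous randomness (ER) regimes in which the
curvature-correlation phenomenology was established. They are unweighted,
simple, static graphs. Passing the ensemble tests therefore says nothing
about weighted networks (where the two curvatures treat weights through
entirely different semantics — probabilities for Ollivier, lengths for
Forman), directed networks, or real networks whose degree-triangle joint
structure differs from all four models; for real data the package reads
KONECT-style edge lists and applies the same pipeline, but no quantitative
claims are tested against real-network values.

## Known limitations

* Ollivier curvature is implemented for unweighted graphs only.
* Only 3-cliques are used as 2-cells in the augmented curvature.
* The transport LP is exact but dense per edge; on networks with very
  large hubs (degree in the thousands) the per-edge cost grows roughly
  cubically with hub degree.
* The HGG calibration matches expected average degree empirically; other
  implementations may calibrate `R` analytically and differ at small `n`.
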