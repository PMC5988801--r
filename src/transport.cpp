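#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Exact solver for the uncapacitated transportation problem
//   min sum_{ij} c_ij f_ij  s.t.  sum_j f_ij = a_i, sum_i f_ij = b_j, f >= 0
// by successive shortest augmenting paths with node potentials (Dijkstra on
// the bipartite residual network; reduced costs stay nonnegative).
// Nodes 0..S-1 are sources, S..S+T-1 sinks.
struct TransportResult {
  double cost;
  std::vector<double> flow;  // S*T, row-major
  std::vector<double> pot;   // S+T potentials
};

static TransportResult solve_transport(const std::vector<double>& c,
                                       std::vector<double> a,
                                       std::vector<double> b) {
  const int S = (int)a.size(), T = (int)b.size(), N = S + T;
  const double INF = std::numeric_limits<double>::infinity();
  const double EPS = 1e-12;
  std::vector<double> flow(S * (size_t)T, 0.0), pot(N, 0.0);
  std::vector<double> dist(N);
  std::vector<int> prev(N);
  std::vector<char> done(N);
  double total_cost = 0.0;
  double remaining = 0.0;
  for (double x : a) remaining += x;

  int guard = 0, guard_max = 2 * N * N + 64;
  while (remaining > EPS) {
    if (++guard > guard_max) Rcpp::stop("transport solver failed to converge");
    // multi-source Dijkstra over reduced costs
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(prev.begin(), prev.end(), -1);
    std::fill(done.begin(), done.end(), 0);
    for (int s = 0; s < S; ++s) if (a[s] > EPS) dist[s] = 0.0;
    for (int iter = 0; iter < N; ++iter) {
      int u = -1; double best = INF;
      for (int i = 0; i < N; ++i)
        if (!done[i] && dist[i] < best) { best = dist[i]; u = i; }
      if (u < 0) break;
      done[u] = 1;
      if (u < S) {
        // forward arcs source u -> every sink
        for (int t = 0; t < T; ++t) {
          double rc = c[u * (size_t)T + t] - pot[u] + pot[S + t];
          double nd = dist[u] + rc;
          if (nd < dist[S + t] - 1e-15) { dist[S + t] = nd; prev[S + t] = u; }
        }
      } else {
        // backward arcs sink -> source where flow is positive
        int t = u - S;
        for (int s = 0; s < S; ++s) {
          if (flow[s * (size_t)T + t] > EPS) {
            double rc = -c[s * (size_t)T + t] - pot[u] + pot[s];
            double nd = dist[u] + rc;
            if (nd < dist[s] - 1e-15) { dist[s] = nd; prev[s] = S + t; }
          }
        }
      }
    }
    // pick reachable sink with unmet demand
    int tgt = -1; double bestd = INF;
    for (int t = 0; t < T; ++t)
      if (b[t] > EPS && dist[S + t] < bestd) { bestd = dist[S + t]; tgt = S + t; }
    if (tgt < 0) Rcpp::stop("transport infeasible: demand unreachable");
    // bottleneck along the augmenting path
    double push = b[tgt - S];
    for (int v = tgt; prev[v] >= 0; v = prev[v]) {
      int u = prev[v];
      if (u < S && v >= S) {
        // forward arc: capacity limited by source remainder at path start
      } else if (u >= S && v < S) {
        push = std::min(push, flow[v * (size_t)T + (u - S)]);
      }
      if (prev[u] < 0 && u < S) push = std::min(push, a[u]);
    }
    // apply
    for (int v = tgt; prev[v] >= 0; v = prev[v]) {
      int u = prev[v];
      if (u < S && v >= S) {
        flow[u * (size_t)T + (v - S)] += push;
        total_cost += push * c[u * (size_t)T + (v - S)];
      } else {
        flow[v * (size_t)T + (u - S)] -= push;
        total_cost -= push * c[v * (size_t)T + (u - S)];
      }
      if (prev[u] < 0 && u < S) a[u] -= push;
    }
    b[tgt - S] -= push;
    remaining -= push;
    // update potentials for visited nodes
    for (int i = 0; i < N; ++i)
      if (std::isfinite(dist[i])) pot[i] -= dist[i];
  }
  TransportResult res;
  res.cost = total_cost;
  res.flow = std::move(flow);
  res.pot = std::move(pot);
  return res;
}

// [[Rcpp::export]]
List cpp_transport(NumericMatrix cost, NumericVector a, NumericVector b) {
  const int S = cost.nrow(), T = cost.ncol();
  if (a.size() != S || b.size() != T)
    stop("mass vectors do not match cost matrix dimensions");
  std::vector<double> c(S * (size_t)T);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < T; ++j) c[i * (size_t)T + j] = cost(i, j);
  TransportResult r = solve_transport(c, as<std::vector<double>>(a),
                                      as<std::vector<double>>(b));
  NumericMatrix plan(S, T);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < T; ++j) plan(i, j) = r.flow[i * (size_t)T + j];
  // dual variables: u_i = pot_i, v_j = -pot_{S+j} satisfy u_i + v_j <= c_ij
  NumericVector u(S), v(T);
  for (int i = 0; i < S; ++i) u[i] = r.pot[i];
  for (int j = 0; j < T; ++j) v[j] = -r.pot[S + j];
  return List::create(_["cost"] = r.cost, _["plan"] = plan,
                      _["u"] = u, _["v"] = v);
}

// depth-limited BFS: exact hop distances from src to vertices within
// maxdepth; fills dist (must be preset to -1) and records touched vertices
static void bfs_limited(const std::vector<std::vector<int>>& adj, int src,
                        int maxdepth, std::vector<int>& dist,
                        std::vector<int>& touched) {
  dist[src] = 0;
  touched.push_back(src);
  std::queue<int> q;
  q.push(src);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    if (dist[u] >= maxdepth) continue;
    for (int w : adj[u]) {
      if (dist[w] < 0) {
        dist[w] = dist[u] + 1;
        touched.push_back(w);
        q.push(w);
      }
    }
  }
}

// Ollivier-Ricci curvature for every edge of a connected graph.
// edges: 0-based two-column matrix. For an edge (x, y) both supports lie
// within distance 1 of an endpoint, so all pairwise support distances are
// at most 3 and depth-3 BFS yields exact costs.
// [[Rcpp::export]]
NumericVector cpp_ollivier_all(int n, IntegerMatrix edges, double alpha) {
  const int m = edges.nrow();
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < m; ++i) {
    adj[edges(i, 0)].push_back(edges(i, 1));
    adj[edges(i, 1)].push_back(edges(i, 0));
  }
  NumericVector kappa(m);
  std::vector<int> dist(n, -1), touched;
  for (int i = 0; i < m; ++i) {
    int x = edges(i, 0), y = edges(i, 1);
    std::vector<int> Sx, Sy;
    std::vector<double> ax, by;
    if (alpha > 0) { Sx.push_back(x); ax.push_back(alpha); }
    for (int w : adj[x]) { Sx.push_back(w); ax.push_back((1.0 - alpha) / adj[x].size()); }
    if (alpha > 0) { Sy.push_back(y); by.push_back(alpha); }
    for (int w : adj[y]) { Sy.push_back(w); by.push_back((1.0 - alpha) / adj[y].size()); }
    const int S = (int)Sx.size(), T = (int)Sy.size();
    std::vector<double> c(S * (size_t)T);
    for (int s = 0; s < S; ++s) {
      touched.clear();
      bfs_limited(adj, Sx[s], 3, dist, touched);
      for (int t = 0; t < T; ++t) {
        int d = dist[Sy[t]];
        if (d < 0) stop("support vertices unexpectedly far apart");
        c[s * (size_t)T + t] = (double)d;
      }
      for (int v : touched) dist[v] = -1;
    }
    TransportResult r = solve_transport(c, ax, by);
    kappa[i] = 1.0 - r.cost;
  }
  return kappa;
}
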