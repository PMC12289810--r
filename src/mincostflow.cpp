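#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact solver for the (balanced) transportation problem
//
//   minimize  sum_{s,t} C(s,t) X(s,t)
//   s.t.      sum_t X(s,t) = supply(s),  sum_s X(s,t) = demand(t),  X >= 0
//
// by successive shortest augmenting paths with Johnson potentials (all arc
// costs are nonnegative, so Dijkstra applies throughout). Arcs are
// uncapacitated, hence forward residual arcs always exist and the final
// potentials are an optimal dual solution:
//   phi_t - phi_s <= C(s,t) for every arc, with equality where X(s,t) > 0.
//
// The flat-metric and W1 duals are recovered from these potentials in R.
//
// [[Rcpp::export]]
List mcf_transport(NumericMatrix cost, NumericVector supply, NumericVector demand) {
  const int p = supply.size(), q = demand.size();
  if (cost.nrow() != p || cost.ncol() != q)
    stop("cost matrix shape does not match supply/demand");
  double tot_s = 0, tot_d = 0;
  for (int i = 0; i < p; ++i) tot_s += supply[i];
  for (int j = 0; j < q; ++j) tot_d += demand[j];
  if (std::fabs(tot_s - tot_d) > 1e-9 * std::max(1.0, std::max(tot_s, tot_d)))
    stop("supply and demand must balance");

  const double INF = std::numeric_limits<double>::infinity();
  const double eps = 1e-12 * std::max(1.0, tot_s);

  std::vector<double> srem(supply.begin(), supply.end());
  std::vector<double> drem(demand.begin(), demand.end());
  NumericMatrix flow(p, q);
  std::vector<double> phiS(p, 0.0), phiT(q, 0.0);

  const int n = p + q; // nodes: 0..p-1 sources, p..p+q-1 sinks
  std::vector<double> dist(n);
  std::vector<int> parent(n);  // predecessor node index, -1 for roots
  std::vector<char> done(n);

  while (true) {
    // recompute residual totals each round: augmentation amounts are exact
    // minima, so one side can retain a roundoff-sized residual the other
    // side can no longer absorb
    double rem_s = 0, rem_d = 0;
    for (int i = 0; i < p; ++i) rem_s += srem[i];
    for (int j = 0; j < q; ++j) rem_d += drem[j];
    if (rem_s <= eps || rem_d <= eps) break;
    const double eps_node = eps / (p + q + 1);
    // multi-source Dijkstra on the residual graph with reduced costs
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(parent.begin(), parent.end(), -1);
    std::fill(done.begin(), done.end(), 0);
    for (int i = 0; i < p; ++i) if (srem[i] > eps_node) dist[i] = 0.0;

    int target = -1;
    for (int it = 0; it < n; ++it) {
      int u = -1; double best = INF;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      if (u >= p && drem[u - p] > eps_node) { target = u; break; }
      if (u < p) {
        // forward arcs source u -> every sink
        for (int j = 0; j < q; ++j) {
          double rc = cost(u, j) + phiS[u] - phiT[j];
          if (rc < 0) rc = 0; // guard against roundoff
          double nd = dist[u] + rc;
          if (nd < dist[p + j] - 1e-15) { dist[p + j] = nd; parent[p + j] = u; }
        }
      } else {
        // reverse arcs sink (u-p) -> sources with positive flow
        int j = u - p;
        for (int i = 0; i < p; ++i) {
          if (flow(i, j) > eps) {
            double rc = -cost(i, j) + phiT[j] - phiS[i];
            if (rc < 0) rc = 0;
            double nd = dist[u] + rc;
            if (nd < dist[i] - 1e-15) { dist[i] = nd; parent[i] = p + j; }
          }
        }
      }
    }
    if (target < 0)
      stop("internal error: no augmenting path (unbalanced instance?)");

    // update potentials (cap unreached nodes at the target distance)
    double dt = dist[target];
    for (int i = 0; i < p; ++i) phiS[i] += std::min(dist[i], dt);
    for (int j = 0; j < q; ++j) phiT[j] += std::min(dist[p + j], dt);

    // bottleneck along the path
    double push = drem[target - p];
    int v = target;
    while (parent[v] != -1) {
      int u = parent[v];
      if (u < p && v >= p) {
        // forward arc, uncapacitated
      } else {
        // reverse arc u(sink) -> v(source): limited by existing flow
        push = std::min(push, (double)flow(v, u - p));
      }
      v = u;
    }
    push = std::min(push, srem[v]); // v is the originating source
    // every bottleneck candidate (root supply, target demand, reverse flow)
    // is strictly positive, so push > 0 and each round saturates one of them
    if (push <= 0)
      stop("internal error: degenerate augmentation");

    // apply
    v = target;
    while (parent[v] != -1) {
      int u = parent[v];
      if (u < p && v >= p) flow(u, v - p) += push;
      else                 flow(v, u - p) -= push;
      v = u;
    }
    srem[v] -= push;
    drem[target - p] -= push;
  }

  double total = 0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < q; ++j)
      if (flow(i, j) > 0) total += flow(i, j) * cost(i, j);

  return List::create(_["cost"] = total,
                      _["flow"] = flow,
                      _["potential_source"] = NumericVector(phiS.begin(), phiS.end()),
                      _["potential_sink"] = NumericVector(phiT.begin(), phiT.end()));
}
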