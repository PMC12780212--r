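#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Multi-source shortest-path time over a 4-connected pixel graph.
// cost: per-pixel crossing time (hours); NA = impassable barrier, except
// on source pixels where NA is read as 0 (sources are always enterable).
// sources: pixels seeding the queue at time 0.
// Edge weight between adjacent pixels a, b = (t_a + t_b) / 2.
// Returns accumulated hours; unreachable pixels are +Inf.
// [[Rcpp::export]]
NumericMatrix grid_dijkstra(NumericMatrix cost, LogicalMatrix sources) {
  const int nr = cost.nrow(), nc = cost.ncol(), n = nr * nc;
  std::vector<double> t(n), dist(n, R_PosInf);
  for (int k = 0; k < n; ++k)
    t[k] = (sources[k] && ISNAN(cost[k])) ? 0.0 : cost[k];

  typedef std::pair<double, int> P;
  std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
  for (int k = 0; k < n; ++k)
    if (sources[k]) { dist[k] = 0.0; pq.push(P(0.0, k)); }

  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    P top = pq.top(); pq.pop();
    const int k = top.second;
    const double d = top.first;
    if (d > dist[k]) continue;
    const int i = k % nr, j = k / nr;
    for (int m = 0; m < 4; ++m) {
      const int ii = i + di[m], jj = j + dj[m];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      const int kk = jj * nr + ii;
      const double ta = t[k], tb = t[kk];
      if (ISNAN(ta) || ISNAN(tb)) continue;
      const double nd = d + 0.5 * (ta + tb);
      if (nd < dist[kk]) { dist[kk] = nd; pq.push(P(nd, kk)); }
    }
  }

  NumericMatrix out(nr, nc);
  for (int k = 0; k < n; ++k) out[k] = dist[k];
  return out;
}

// Connected-component labeling of a binary mask, connectivity 4 or 8.
// Labels are 1..n_components in scan order; off pixels are 0.
// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  for (int k = 0; k < n; ++k) {
    if (!mask[k] || lab[k] != 0) continue;
    ++next;
    stack.push_back(k);
    lab[k] = next;
    while (!stack.empty()) {
      const int c = stack.back(); stack.pop_back();
      const int i = c % nr, j = c / nr;
      for (int m = 0; m < nn; ++m) {
        const int ii = i + di8[m], jj = j + dj8[m];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const int kk = jj * nr + ii;
        if (mask[kk] && lab[kk] == 0) { lab[kk] = next; stack.push_back(kk); }
      }
    }
  }
  return lab;
}
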