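#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted shortest-path betweenness by Dijkstra search plus Brandes'
// dependency accumulation, on a dense edge-distance matrix.
//
// D(i, j) is the length of edge i-j (R_PosInf when the edge is absent; the
// diagonal is ignored). Path lengths within `tol` of each other count as
// tied and share credit fractionally. Endpoints are excluded and each
// unordered pair contributes once (the two directed sweeps are halved).
// [[Rcpp::export]]
NumericVector brandes_betweenness_dense(NumericMatrix D, double tol) {
  const int n = D.nrow();
  if (D.ncol() != n) stop("distance matrix must be square");
  NumericVector bc(n);
  std::vector<double> dist(n), sigma(n), delta(n);
  std::vector<bool> done(n);
  std::vector<int> order;
  order.reserve(n);
  std::vector<std::vector<int> > pred(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(done.begin(), done.end(), false);
    for (int i = 0; i < n; ++i) pred[i].clear();
    order.clear();
    dist[s] = 0.0;
    sigma[s] = 1.0;

    for (int it = 0; it < n; ++it) {
      int u = -1;
      double best = R_PosInf;
      for (int i = 0; i < n; ++i)
        if (!done[i] && dist[i] < best) { best = dist[i]; u = i; }
      if (u < 0) break;  // remaining nodes unreachable
      done[u] = true;
      order.push_back(u);
      for (int v = 0; v < n; ++v) {
        if (v == u || done[v]) continue;
        double w = D(u, v);
        if (!R_finite(w)) continue;
        double alt = dist[u] + w;
        if (alt < dist[v] - tol) {
          dist[v] = alt;
          sigma[v] = sigma[u];
          pred[v].assign(1, u);
        } else if (std::fabs(alt - dist[v]) <= tol) {
          sigma[v] += sigma[u];
          pred[v].push_back(u);
        }
      }
    }

    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (std::size_t j = 0; j < pred[w].size(); ++j) {
        int u = pred[w][j];
        delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;  // undirected: both sweeps seen
  return bc;
}
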