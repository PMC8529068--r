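#include <Rcpp.h>
#include <queue>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Weighted edge betweenness by Brandes' accumulation over Dijkstra trees.
// Nodes and edges are 0-based; lengths must be nonnegative. Each unordered
// node pair contributes once (the two-sided accumulation is halved), and
// tied shortest paths share credit fractionally. Ties in path length are
// detected with an absolute tolerance suited to O(1) edge lengths.
// [[Rcpp::export]]
NumericVector brandes_edge_betweenness(int n_nodes, IntegerVector from,
                                       IntegerVector to, NumericVector len) {
  const int m = from.size();
  const double EPS = 1e-10;
  std::vector<std::vector<std::pair<int, int> > > adj(n_nodes);
  for (int e = 0; e < m; ++e) {
    adj[from[e]].push_back(std::make_pair(to[e], e));
    adj[to[e]].push_back(std::make_pair(from[e], e));
  }
  NumericVector bc(m);
  const double INF = std::numeric_limits<double>::infinity();
  typedef std::pair<double, int> QE;

  for (int s = 0; s < n_nodes; ++s) {
    std::vector<double> dist(n_nodes, INF), sigma(n_nodes, 0.0), delta(n_nodes, 0.0);
    std::vector<std::vector<std::pair<int, int> > > pred(n_nodes);
    std::vector<bool> done(n_nodes, false);
    std::vector<int> order;
    order.reserve(n_nodes);
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    dist[s] = 0.0;
    sigma[s] = 1.0;
    pq.push(std::make_pair(0.0, s));
    while (!pq.empty()) {
      int v = pq.top().second;
      pq.pop();
      if (done[v]) continue;
      done[v] = true;
      order.push_back(v);
      for (size_t i = 0; i < adj[v].size(); ++i) {
        int w = adj[v][i].first, e = adj[v][i].second;
        if (done[w]) continue;
        double nd = dist[v] + len[e];
        if (nd < dist[w] - EPS) {
          dist[w] = nd;
          sigma[w] = sigma[v];
          pred[w].clear();
          pred[w].push_back(std::make_pair(v, e));
          pq.push(std::make_pair(nd, w));
        } else if (std::fabs(nd - dist[w]) <= EPS) {
          sigma[w] += sigma[v];
          pred[w].push_back(std::make_pair(v, e));
        }
      }
    }
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (size_t j = 0; j < pred[w].size(); ++j) {
        int v = pred[w][j].first, e = pred[w][j].second;
        double c = sigma[v] / sigma[w] * (1.0 + delta[w]);
        bc[e] += c;
        delta[v] += c;
      }
    }
  }
  for (int e = 0; e < m; ++e) bc[e] /= 2.0;
  return bc;
}
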