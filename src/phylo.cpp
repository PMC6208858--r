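#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Saitou-Nei neighbor joining on a symmetric distance matrix.
// Node ids: tips 1..n in input row order; internal nodes n+1, n+2, ... in
// order of creation (the last one created is the central node of the final
// 3-star). Tie-breaking among minimal Q values: the pair of active nodes
// with the smallest (i, j) id pair, i.e. the first strict minimum in row-major
// order over active-node ids, which for tips follows the input label order.
// Negative branch-length estimates are clamped to zero with the deficit
// moved onto the sibling edge of the same join.
// [[Rcpp::export]]
List nj_cpp(NumericMatrix D) {
  const int n = D.nrow();
  if (n < 2) stop("need at least 2 taxa");

  std::vector<std::array<int, 2>> edges;
  std::vector<double> elen;

  if (n == 2) {
    // single internal node so downstream rooted representations work
    edges.push_back({3, 1});
    edges.push_back({3, 2});
    elen.push_back(D(0, 1) / 2.0);
    elen.push_back(D(0, 1) / 2.0);
    IntegerMatrix em(2, 2);
    NumericVector ev(2);
    for (int e = 0; e < 2; ++e) {
      em(e, 0) = edges[e][0];
      em(e, 1) = edges[e][1];
      ev[e] = elen[e];
    }
    return List::create(_["edge"] = em, _["length"] = ev,
                        _["ntip"] = 2, _["root"] = 3);
  }

  std::vector<int> id(n);
  for (int i = 0; i < n; ++i) id[i] = i + 1;
  std::vector<std::vector<double>> d(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d[i][j] = D(i, j);

  int next_id = n + 1;
  int N = n;

  while (N > 3) {
    std::vector<double> R(N, 0.0);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j) R[i] += d[i][j];

    // minimal Q with deterministic tie-break on active node ids
    double qbest = R_PosInf;
    int bi = -1, bj = -1;
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < N; ++j) {
        if (i == j) continue;
        double q = (N - 2) * d[i][j] - R[i] - R[j];
        int a = std::min(id[i], id[j]), b = std::max(id[i], id[j]);
        if (q < qbest - 1e-14) {
          qbest = q; bi = i; bj = j;
        } else if (q <= qbest + 1e-14 && bi >= 0) {
          int ca = std::min(id[bi], id[bj]), cb = std::max(id[bi], id[bj]);
          if (a < ca || (a == ca && b < cb)) { bi = i; bj = j; }
        }
      }
    }
    if (id[bi] > id[bj]) std::swap(bi, bj);

    double li = d[bi][bj] / 2.0 + (R[bi] - R[bj]) / (2.0 * (N - 2));
    double lj = d[bi][bj] - li;
    if (li < 0) { lj += li; li = 0; }
    if (lj < 0) { li += lj; lj = 0; }
    if (li < 0) li = 0;  // both estimates negative: d(i,j) < 0 input

    edges.push_back({next_id, id[bi]}); elen.push_back(li);
    edges.push_back({next_id, id[bj]}); elen.push_back(lj);

    // replace slot bi with the new node, drop slot bj
    std::vector<double> dn(N, 0.0);
    for (int k = 0; k < N; ++k) {
      if (k == bi || k == bj) continue;
      dn[k] = 0.5 * (d[bi][k] + d[bj][k] - d[bi][bj]);
    }
    for (int k = 0; k < N; ++k) {
      d[bi][k] = dn[k];
      d[k][bi] = dn[k];
    }
    d[bi][bi] = 0.0;
    id[bi] = next_id++;
    // swap bj with last and shrink
    int last = N - 1;
    if (bj != last) {
      id[bj] = id[last];
      for (int k = 0; k < N; ++k) {
        d[bj][k] = d[last][k];
        d[k][bj] = d[k][last];
      }
      d[bj][bj] = 0.0;
    }
    --N;
  }

  int center = next_id++;
  if (N == 3) {
    double l0 = 0.5 * (d[0][1] + d[0][2] - d[1][2]);
    double l1 = 0.5 * (d[0][1] + d[1][2] - d[0][2]);
    double l2 = 0.5 * (d[0][2] + d[1][2] - d[0][1]);
    if (l0 < 0) l0 = 0;
    if (l1 < 0) l1 = 0;
    if (l2 < 0) l2 = 0;
    edges.push_back({center, id[0]}); elen.push_back(l0);
    edges.push_back({center, id[1]}); elen.push_back(l1);
    edges.push_back({center, id[2]}); elen.push_back(l2);
  }

  const int m = edges.size();
  IntegerMatrix em(m, 2);
  NumericVector ev(m);
  for (int e = 0; e < m; ++e) {
    em(e, 0) = edges[e][0];
    em(e, 1) = edges[e][1];
    ev[e] = elen[e];
  }
  return List::create(_["edge"] = em, _["length"] = ev,
                      _["ntip"] = n, _["root"] = center);
}

// Leaf-to-leaf path-length matrix of an edge-weighted tree given as an
// (undirected) edge list over node ids 1..nnode with tips 1..ntip.
// [[Rcpp::export]]
NumericMatrix tree_path_dists_cpp(IntegerMatrix edge, NumericVector len,
                                  int ntip) {
  int nnode = 0;
  const int m = edge.nrow();
  for (int e = 0; e < m; ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));

  std::vector<std::vector<std::pair<int, double>>> adj(nnode + 1);
  for (int e = 0; e < m; ++e) {
    adj[edge(e, 0)].push_back({edge(e, 1), len[e]});
    adj[edge(e, 1)].push_back({edge(e, 0), len[e]});
  }

  NumericMatrix out(ntip, ntip);
  std::vector<double> dist(nnode + 1);
  std::vector<bool> seen(nnode + 1);
  for (int s = 1; s <= ntip; ++s) {
    std::fill(seen.begin(), seen.end(), false);
    dist[s] = 0.0; seen[s] = true;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (auto &pr : adj[u]) {
        if (!seen[pr.first]) {
          seen[pr.first] = true;
          dist[pr.first] = dist[u] + pr.second;
          q.push(pr.first);
        }
      }
    }
    for (int t = 1; t <= ntip; ++t) out(s - 1, t - 1) = dist[t];
  }
  return out;
}

// Worst violation of the four-point condition: max over 4-subsets of
// (largest pair-sum - middle pair-sum), with the achieving quartet.
// [[Rcpp::export]]
List four_point_scan_cpp(NumericMatrix D) {
  const int n = D.nrow();
  double worst = 0.0;
  IntegerVector wit(4, NA_INTEGER);
  if (n >= 4) {
    wit = IntegerVector::create(1, 2, 3, 4);
    for (int i = 0; i < n - 3; ++i)
      for (int j = i + 1; j < n - 2; ++j)
        for (int k = j + 1; k < n - 1; ++k)
          for (int l = k + 1; l < n; ++l) {
            double s1 = D(i, j) + D(k, l);
            double s2 = D(i, k) + D(j, l);
            double s3 = D(i, l) + D(j, k);
            double hi = std::max(s1, std::max(s2, s3));
            double lo = std::min(s1, std::min(s2, s3));
            double mid = s1 + s2 + s3 - hi - lo;
            double v = hi - mid;
            if (v > worst) {
              worst = v;
              wit[0] = i + 1; wit[1] = j + 1; wit[2] = k + 1; wit[3] = l + 1;
            }
          }
  }
  return List::create(_["worst"] = worst, _["witness"] = wit);
}

// Worst ultrametric violation: max over ordered triples of
// d(x,z) - max(d(x,y), d(y,z)), clamped below at 0.
// [[Rcpp::export]]
List ultrametric_scan_cpp(NumericMatrix D) {
  const int n = D.nrow();
  double worst = 0.0;
  IntegerVector wit(3, NA_INTEGER);
  if (n >= 3) {
    wit = IntegerVector::create(1, 2, 3);
    for (int x = 0; x < n; ++x)
      for (int y = 0; y < n; ++y)
        for (int z = 0; z < n; ++z) {
          if (x == y || y == z || x == z) continue;
          double v = D(x, z) - std::max(D(x, y), D(y, z));
          if (v > worst) {
            worst = v;
            wit[0] = x + 1; wit[1] = y + 1; wit[2] = z + 1;
          }
        }
  }
  return List::create(_["worst"] = worst, _["witness"] = wit);
}

// Worst triangle-inequality violation: max over ordered triples of
// d(x,z) - d(x,y) - d(y,z), clamped below at 0.
// [[Rcpp::export]]
List triangle_scan_cpp(NumericMatrix D) {
  const int n = D.nrow();
  double worst = 0.0;
  IntegerVector wit(3, NA_INTEGER);
  if (n >= 3) {
    wit = IntegerVector::create(1, 2, 3);
    for (int x = 0; x < n; ++x)
      for (int y = 0; y < n; ++y)
        for (int z = 0; z < n; ++z) {
          if (x == y || y == z || x == z) continue;
          double v = D(x, z) - D(x, y) - D(y, z);
          if (v > worst) {
            worst = v;
            wit[0] = x + 1; wit[1] = y + 1; wit[2] = z + 1;
          }
        }
  }
  return List::create(_["worst"] = worst, _["witness"] = wit);
}
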