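#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling of a binary image by breadth-first search.
// mask: logical matrix (row = y, col = x). connectivity: 4 or 8.
// Returns integer matrix of labels, 0 = background, components numbered
// 1..n in raster-scan order of their first pixel.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = { 0, 0,-1, 1, -1,  1,-1, 1};
  int nnb = connectivity;
  int cur = 0;
  std::queue<std::pair<int,int> > q;
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      lab(y, x) = ++cur;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int k = 0; k < nnb; ++k) {
          int yy = p.first + dy8[k], xx = p.second + dx8[k];
          if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
          if (mask(yy, xx) && lab(yy, xx) == 0) {
            lab(yy, xx) = cur;
            q.push(std::make_pair(yy, xx));
          }
        }
      }
    }
  }
  return lab;
}

// Zhang-Suen thinning of a binary image down to a 1-px skeleton.
// [[Rcpp::export(name = ".thin_mask")]]
LogicalMatrix thin_mask(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  // pad-free implementation: treat out-of-range as background
  std::vector<unsigned char> img(nr * nc);
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y)
      img[y + (size_t)x * nr] = mask(y, x) ? 1 : 0;
  auto at = [&](int y, int x) -> unsigned char {
    if (y < 0 || y >= nr || x < 0 || x >= nc) return 0;
    return img[y + (size_t)x * nr];
  };
  bool changed = true;
  std::vector<size_t> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int x = 0; x < nc; ++x) {
        for (int y = 0; y < nr; ++y) {
          if (!at(y, x)) continue;
          // neighbours p2..p9 clockwise starting north
          unsigned char p2 = at(y - 1, x),     p3 = at(y - 1, x + 1),
                        p4 = at(y, x + 1),     p5 = at(y + 1, x + 1),
                        p6 = at(y + 1, x),     p7 = at(y + 1, x - 1),
                        p8 = at(y, x - 1),     p9 = at(y - 1, x - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(y + (size_t)x * nr);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i) img[kill[i]] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y)
      out(y, x) = img[y + (size_t)x * nr] != 0;
  return out;
}

// Geodesic diameter of a binary skeleton: the longest shortest path
// between any two foreground pixels, with 8-neighbour moves weighted
// 1 (axial) and sqrt(2) (diagonal), in pixel units. Exact all-pairs
// Dijkstra when the skeleton is small; double-sweep otherwise.
// Returns 0 for a single pixel, -1 for an empty mask.
// [[Rcpp::export(name = ".geodesic_diameter")]]
double geodesic_diameter(LogicalMatrix skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  std::vector<int> ys, xs;
  IntegerMatrix idx(nr, nc);
  std::fill(idx.begin(), idx.end(), -1);
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y)
      if (skel(y, x)) { idx(y, x) = (int)ys.size(); ys.push_back(y); xs.push_back(x); }
  int n = (int)ys.size();
  if (n == 0) return -1.0;
  if (n == 1) return 0.0;
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = { 0, 0,-1, 1, -1,  1,-1, 1};
  const double w8[8] = {1, 1, 1, 1, M_SQRT2, M_SQRT2, M_SQRT2, M_SQRT2};
  // adjacency
  std::vector<std::vector<std::pair<int,double> > > adj(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 8; ++k) {
      int yy = ys[i] + dy8[k], xx = xs[i] + dx8[k];
      if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
      int j = idx(yy, xx);
      if (j >= 0) adj[i].push_back(std::make_pair(j, w8[k]));
    }
  }
  std::vector<double> dist(n);
  typedef std::pair<double,int> Node;
  auto sweep = [&](int src, int &far) -> double {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
    dist[src] = 0; pq.push(std::make_pair(0.0, src));
    double best = 0; far = src;
    while (!pq.empty()) {
      Node t = pq.top(); pq.pop();
      int u = t.second;
      if (t.first > dist[u]) continue;
      if (dist[u] > best && R_finite(dist[u])) { best = dist[u]; far = u; }
      for (size_t e = 0; e < adj[u].size(); ++e) {
        int v = adj[u][e].first;
        double nd = dist[u] + adj[u][e].second;
        if (nd < dist[v]) { dist[v] = nd; pq.push(std::make_pair(nd, v)); }
      }
    }
    return best;
  };
  int far;
  if (n <= 2000) {
    double best = 0;
    for (int s = 0; s < n; ++s) {
      double d = sweep(s, far);
      if (d > best) best = d;
    }
    return best;
  }
  // double sweep: exact on trees, good lower bound otherwise
  sweep(0, far);
  int far2;
  return sweep(far, far2);
}
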