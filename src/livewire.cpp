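#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Live-wire core: Dijkstra shortest-path-first on an 8-connected pixel grid.
// Matrices are indexed [z, x] (row = depth, column = lateral position), 0-based
// here; R wrappers convert. Edge weight between neighbouring pixels a, b is
// (cost_a + cost_b)/2, scaled by sqrt(2) for diagonal moves.
//
// Determinism: the priority queue orders by (dist, z, x); on equal distance the
// node with smaller (z, x) lexicographic order is popped first, and the
// predecessor is updated only on strict improvement, so identical inputs give
// bit-identical paths.

struct QNode {
  double dist;
  int z, x;
};

struct QNodeCmp {
  // std::priority_queue pops the *largest*, so invert.
  bool operator()(const QNode &a, const QNode &b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    if (a.z != b.z) return a.z > b.z;
    return a.x > b.x;
  }
};

static const int DZ[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export(name = ".lw_dijkstra")]]
List lw_dijkstra(NumericMatrix cost, int src_z, int src_x, int dst_z, int dst_x) {
  const int H = cost.nrow(), W = cost.ncol();
  if (src_z < 0 || src_z >= H || src_x < 0 || src_x >= W ||
      dst_z < 0 || dst_z >= H || dst_x < 0 || dst_x >= W)
    stop("path endpoints outside the cost image");
  const double SQ2 = std::sqrt(2.0);
  std::vector<double> dist((size_t)H * W, R_PosInf);
  std::vector<int> prev((size_t)H * W, -1);
  std::vector<char> done((size_t)H * W, 0);

  auto idx = [W](int z, int x) { return (size_t)z * W + x; };

  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  dist[idx(src_z, src_x)] = 0.0;
  pq.push({0.0, src_z, src_x});

  while (!pq.empty()) {
    QNode cur = pq.top();
    pq.pop();
    size_t ci = idx(cur.z, cur.x);
    if (done[ci]) continue;
    done[ci] = 1;
    if (cur.z == dst_z && cur.x == dst_x) break;
    double c0 = cost(cur.z, cur.x);
    for (int k = 0; k < 8; ++k) {
      int nz = cur.z + DZ[k], nx = cur.x + DX[k];
      if (nz < 0 || nz >= H || nx < 0 || nx >= W) continue;
      size_t ni = idx(nz, nx);
      if (done[ni]) continue;
      double w = 0.5 * (c0 + cost(nz, nx));
      if (DZ[k] != 0 && DX[k] != 0) w *= SQ2;
      double nd = dist[ci] + w;
      if (nd < dist[ni]) {  // strict improvement only
        dist[ni] = nd;
        prev[ni] = (int)ci;
        pq.push({nd, nz, nx});
      }
    }
  }

  size_t di = idx(dst_z, dst_x);
  if (!std::isfinite(dist[di])) stop("destination unreachable");

  std::vector<int> rz, rx;
  int cur = (int)di;
  while (cur >= 0) {
    rz.push_back(cur / W);
    rx.push_back(cur % W);
    cur = (cur == (int)idx(src_z, src_x)) ? -1 : prev[cur];
  }
  const int n = (int)rz.size();
  IntegerVector pz(n), px(n);
  for (int i = 0; i < n; ++i) {  // reverse: src first
    pz[i] = rz[n - 1 - i];
    px[i] = rx[n - 1 - i];
  }
  return List::create(_["z"] = pz, _["x"] = px, _["total_cost"] = dist[di]);
}

// 8-connected labelling of a binary mask (row-major BFS flood fill).
// [[Rcpp::export(name = ".lw_label8")]]
IntegerMatrix lw_label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int z = 0; z < H; ++z) {
    for (int x = 0; x < W; ++x) {
      if (!mask(z, x) || lab(z, x) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(z * W + x);
      lab(z, x) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pz = p / W, px = p % W;
        for (int k = 0; k < 8; ++k) {
          int nz = pz + DZ[k], nx = px + DX[k];
          if (nz < 0 || nz >= H || nx < 0 || nx >= W) continue;
          if (mask(nz, nx) && lab(nz, nx) == 0) {
            lab(nz, nx) = next;
            stack.push_back(nz * W + nx);
          }
        }
      }
    }
  }
  return lab;
}
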