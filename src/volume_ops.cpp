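#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Volumes arrive as R arrays with dim (Z, Y, X), column-major: the linear
// index of voxel (z, y, x) (0-based) is z + Z*(y + Y*x). 6-connectivity
// throughout: +/-1 in exactly one of z, y, x.

static inline void push_neighbours(int idx, int Z, int Y, int X,
                                   std::vector<int> &out) {
  out.clear();
  int z = idx % Z;
  int rest = idx / Z;
  int y = rest % Y;
  int x = rest / Y;
  if (z > 0)     out.push_back(idx - 1);
  if (z < Z - 1) out.push_back(idx + 1);
  if (y > 0)     out.push_back(idx - Z);
  if (y < Y - 1) out.push_back(idx + Z);
  if (x > 0)     out.push_back(idx - Z * Y);
  if (x < X - 1) out.push_back(idx + Z * Y);
}

// Label 6-connected components of a binary mask. Labels are assigned in
// scan order, so output is deterministic.
// [[Rcpp::export(name = ".cc_label6")]]
IntegerVector cc_label6(LogicalVector mask, IntegerVector dims) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  int n = Z * Y * X;
  IntegerVector lab(n, 0);
  std::vector<int> nb;
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      push_neighbours(cur, Z, Y, X, nb);
      for (int j : nb) {
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

struct QItem {
  double prio;
  long long order;
  int idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // min-heap on priority
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Marker-controlled flood ("watershed") on a relief restricted to a mask:
// voxels are conquered in ascending relief order starting from the markers;
// each mask voxel inherits the label of the first marker region to reach it.
// Deterministic: ties resolved by insertion order.
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerVector watershed_flood(NumericVector relief, IntegerVector markers,
                              LogicalVector mask, IntegerVector dims) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  int n = Z * Y * X;
  IntegerVector lab(n, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long long counter = 0;
  for (int i = 0; i < n; ++i) {
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push({relief[i], counter++, i});
    }
  }
  std::vector<int> nb;
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    push_neighbours(it.idx, Z, Y, X, nb);
    for (int j : nb) {
      if (mask[j] && lab[j] == 0) {
        lab[j] = lab[it.idx];
        double p = relief[j] > it.prio ? relief[j] : it.prio;
        pq.push({p, counter++, j});
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Local maxima of a response volume within an anisotropic Chebyshev window
// (radius rz, ry, rx). A voxel is a maximum when no voxel in its window has
// a strictly larger response and it is the scan-order-first voxel among
// window ties, so plateaus yield a single seed.
// [[Rcpp::export(name = ".local_maxima3d")]]
LogicalVector local_maxima3d(NumericVector resp, IntegerVector dims,
                             int rz, int ry, int rx, double thresh) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  int n = Z * Y * X;
  LogicalVector out(n, false);
  for (int x = 0; x < X; ++x) {
    for (int y = 0; y < Y; ++y) {
      for (int z = 0; z < Z; ++z) {
        int idx = z + Z * (y + Y * x);
        double v = resp[idx];
        if (v <= thresh) continue;
        bool is_max = true;
        for (int dx = -rx; dx <= rx && is_max; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= X) continue;
          for (int dy = -ry; dy <= ry && is_max; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= Y) continue;
            for (int dz = -rz; dz <= rz; ++dz) {
              int zz = z + dz;
              if (zz < 0 || zz >= Z) continue;
              int jdx = zz + Z * (yy + Y * xx);
              if (jdx == idx) continue;
              double w = resp[jdx];
              if (w > v || (w == v && jdx < idx)) {
                is_max = false;
                break;
              }
            }
          }
        }
        if (is_max) out[idx] = true;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
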