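#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
using namespace Rcpp;

// Images are passed as flat vectors in R's column-major (z, y, x) layout:
// index = z + nz*(y + ny*x).  With nz == 1 the 26-neighbourhood reduces to
// 8-connectivity in the (y, x) plane, which is the 2D contract.

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  // first-unvisited-pixel order in the linear layout defines label order
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int cz = cur % nz, rem = cur / nz;
      int cy = rem % ny, cx = rem / ny;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int z = cz + dz, y = cy + dy, x = cx + dx;
            if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx)
              continue;
            int j = idx3(z, y, x, nz, ny);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}

struct WsEntry {
  double elev;
  long order;   // insertion counter: deterministic tie-break
  int idx;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.order > b.order;
  }
};

// Priority-flood watershed constrained to stay within the region id of the
// seed; pixels with region == 0 are never visited.
// [[Rcpp::export(name = ".ws_flood")]]
IntegerVector ws_flood(NumericVector elev, IntegerVector seeds,
                       IntegerVector region, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  if (elev.size() != n || seeds.size() != n || region.size() != n)
    stop("elev/seeds/region length does not match dims");
  IntegerVector out(n, 0);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long counter = 0;
  for (int i = 0; i < n; ++i) {
    if (seeds[i] > 0) {
      out[i] = seeds[i];
      pq.push({elev[i], counter++, i});
    }
  }
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    int cur = e.idx;
    int cz = cur % nz, rem = cur / nz;
    int cy = rem % ny, cx = rem / ny;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int z = cz + dz, y = cy + dy, x = cx + dx;
          if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx)
            continue;
          int j = idx3(z, y, x, nz, ny);
          if (out[j] == 0 && region[j] != 0 && region[j] == region[cur]) {
            out[j] = out[cur];
            pq.push({elev[j], counter++, j});
          }
        }
  }
  return out;
}
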