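#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Shared helper: move from linear index `idx` (0-based) by integer offset
// (dx,dy,dz); returns -1 when the move leaves the grid.
static inline int shift_index(int idx, int dx, int dy, int dz,
                              int nx, int ny, int nz) {
  int x = idx % nx;
  int y = (idx / nx) % ny;
  int z = idx / (nx * ny);
  x += dx; y += dy; z += dz;
  if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return -1;
  return x + nx * (y + ny * z);
}

// Count voxels reachable from `seed` (1-based linear index) by repeated
// moves through `offsets` (rows of integer dx,dy,dz), stepping only onto
// voxels flagged TRUE in `candidate`. The seed itself is always passable
// and is excluded from the count. Used for region-growing short-range FCD.
// [[Rcpp::export(name = ".flood_count_cpp")]]
int flood_count_cpp(LogicalVector candidate, IntegerVector dims,
                    int seed, IntegerMatrix offsets) {
  if (offsets.nrow() == 0) stop("empty neighbourhood offset set");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if (candidate.size() != n) stop("candidate length does not match dims");
  int s = seed - 1;
  if (s < 0 || s >= n) stop("seed index out of range");
  std::vector<char> visited(n, 0);
  std::queue<int> q;
  visited[s] = 1;
  q.push(s);
  int count = 0;
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    for (int k = 0; k < offsets.nrow(); ++k) {
      int nb = shift_index(cur, offsets(k, 0), offsets(k, 1), offsets(k, 2),
                           nx, ny, nz);
      if (nb < 0 || visited[nb]) continue;
      if (candidate[nb]) {
        visited[nb] = 1;
        ++count;
        q.push(nb);
      }
    }
  }
  return count;
}

// Label connected components of TRUE voxels under the given offset
// neighbourhood. Returns an integer vector of the same length: 0 outside,
// 1..K inside, labelled in first-encounter order (scan order), so labels
// are deterministic.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   IntegerMatrix offsets) {
  if (offsets.nrow() == 0) stop("empty neighbourhood offset set");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  int next_label = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    q.push(i);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      for (int k = 0; k < offsets.nrow(); ++k) {
        int nb = shift_index(cur, offsets(k, 0), offsets(k, 1), offsets(k, 2),
                             nx, ny, nz);
        if (nb < 0) continue;
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next_label;
          q.push(nb);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
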