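#include <Rcpp.h>
#include <functional>
#include <map>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 3D connectivity helpers, connected components, grayscale reconstruction
// (for h-maxima), regional maxima, and seeded priority-flood watershed.

static int neigh_offsets(int conn, const int nx, const int ny, const int nz,
                         int* dx, int* dy, int* dz) {
  int m = 0;
  for (int a = -1; a <= 1; a++)
    for (int b = -1; b <= 1; b++)
      for (int c = -1; c <= 1; c++) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (conn == 6 && manh > 1) continue;
        dx[m] = a; dy[m] = b; dz[m] = c; m++;
      }
  (void)nx; (void)ny; (void)nz;
  return m;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int conn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  int dx[26], dy[26], dz[26];
  const int m = neigh_offsets(conn, nx, ny, nz, dx, dy, dz);

  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back(); stack.pop_back();
      const int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / sz);
      for (int q = 0; q < m; q++) {
        const int xx = x + dx[q], yy = y + dy[q], zz = z + dz[q];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t w = xx + sy * yy + sz * zz;
        if (mask[w] && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Morphological reconstruction by dilation of `marker` under `ceiling`
// (marker <= ceiling everywhere), FIFO propagation.
// [[Rcpp::export]]
NumericVector cpp_reconstruct(NumericVector marker, NumericVector ceiling,
                              IntegerVector dim, int conn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  int dx[26], dy[26], dz[26];
  const int m = neigh_offsets(conn, nx, ny, nz, dx, dy, dz);

  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; i++)
    g[i] = std::min(marker[i], ceiling[i]);

  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; i++) q.push(i);
  std::vector<char> inq(n, 1);
  while (!q.empty()) {
    const R_xlen_t v = q.front(); q.pop(); inq[v] = 0;
    const int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / sz);
    for (int t = 0; t < m; t++) {
      const int xx = x + dx[t], yy = y + dy[t], zz = z + dz[t];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const R_xlen_t w = xx + sy * yy + sz * zz;
      const double cand = std::min(g[v], ceiling[w]);
      if (cand > g[w]) {
        g[w] = cand;
        if (!inq[w]) { q.push(w); inq[w] = 1; }
      }
    }
  }
  return g;
}

// Regional maxima of `f` restricted to `mask`: plateaus with no strictly
// greater neighbor inside the mask. Returns a logical vector.
// [[Rcpp::export]]
LogicalVector cpp_regional_maxima(NumericVector f, LogicalVector mask,
                                  IntegerVector dim, int conn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  int dx[26], dy[26], dz[26];
  const int m = neigh_offsets(conn, nx, ny, nz, dx, dy, dz);

  LogicalVector out(n);
  std::vector<char> visited(n, 0);
  std::vector<R_xlen_t> stack, plateau;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || visited[s]) continue;
    // flood the equal-value plateau containing s
    const double v0 = f[s];
    bool is_max = true;
    stack.clear(); plateau.clear();
    stack.push_back(s); visited[s] = 1;
    while (!stack.empty()) {
      const R_xlen_t v = stack.back(); stack.pop_back();
      plateau.push_back(v);
      const int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / sz);
      for (int t = 0; t < m; t++) {
        const int xx = x + dx[t], yy = y + dy[t], zz = z + dz[t];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t w = xx + sy * yy + sz * zz;
        if (!mask[w]) continue;
        if (f[w] > v0) is_max = false;
        else if (f[w] == v0 && !visited[w]) { visited[w] = 1; stack.push_back(w); }
      }
    }
    if (is_max)
      for (R_xlen_t v : plateau) out[v] = true;
  }
  return out;
}

// Seeded watershed by priority flood: highest `priority` first; ties broken
// by lower linear index (deterministic). Unlabeled in-mask voxels adopt the
// label of the neighbor that dequeues them.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dim, int conn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  int dx[26], dy[26], dz[26];
  const int m = neigh_offsets(conn, nx, ny, nz, dx, dy, dz);

  IntegerVector lab = clone(seeds);
  typedef std::pair<double, R_xlen_t> Node;  // (priority, -index) max-heap
  auto cmp = [](const Node& a, const Node& b) {
    if (a.first != b.first) return a.first < b.first;
    return a.second > b.second;
  };
  std::priority_queue<Node, std::vector<Node>, decltype(cmp)> pq(cmp);
  for (R_xlen_t i = 0; i < n; i++)
    if (lab[i] > 0 && mask[i]) pq.push(Node(priority[i], i));

  while (!pq.empty()) {
    const R_xlen_t v = pq.top().second; pq.pop();
    const int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / sz);
    for (int t = 0; t < m; t++) {
      const int xx = x + dx[t], yy = y + dy[t], zz = z + dz[t];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const R_xlen_t w = xx + sy * yy + sz * zz;
      if (!mask[w] || lab[w] != 0) continue;
      lab[w] = lab[v];
      pq.push(Node(priority[w], w));
    }
  }
  return lab;
}

// Union-find over mesh triangles sharing vertices; returns per-triangle
// 1-based component ids.
// [[Rcpp::export]]
IntegerVector cpp_mesh_components(IntegerMatrix tri, int nv) {
  std::vector<int> parent(nv + 1);
  for (int i = 0; i <= nv; i++) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  const int nt = tri.nrow();
  for (int t = 0; t < nt; t++) {
    int a = find(tri(t, 0)), b = find(tri(t, 1)), c = find(tri(t, 2));
    parent[b] = a; parent[find(c)] = find(a);
  }
  IntegerVector out(nt);
  std::map<int, int> remap;
  for (int t = 0; t < nt; t++) {
    int r = find(tri(t, 0));
    auto it = remap.find(r);
    if (it == remap.end()) { int id = (int)remap.size() + 1; remap[r] = id; out[t] = id; }
    else out[t] = it->second;
  }
  return out;
}
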