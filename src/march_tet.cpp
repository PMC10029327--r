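#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Zero level-set triangulation by marching tetrahedra on the Freudenthal
// 6-tetrahedra decomposition of each grid cell (all cells split around the
// same main diagonal, so shared faces are triangulated identically and the
// mesh is watertight away from the domain boundary). Vertices are placed by
// linear interpolation along tetrahedron edges and deduplicated per edge.
// Convention: phi >= 0 is inside. Cells at the domain boundary are simply
// not closed (no cap triangles).

struct Key {
  R_xlen_t a, b;
  bool operator==(const Key& o) const { return a == o.a && b == o.b; }
};
struct KeyHash {
  size_t operator()(const Key& k) const {
    return std::hash<R_xlen_t>()(k.a) * 1000003u ^ std::hash<R_xlen_t>()(k.b);
  }
};

// the six tetrahedra: monotone bit-paths 0 -> 7 through the cube corners
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

// [[Rcpp::export]]
List cpp_march_tets(NumericVector phi, IntegerVector dim, double spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;

  std::vector<double> vx, vy, vzc;
  std::vector<int> tri;
  std::unordered_map<Key, int, KeyHash> vmap;

  R_xlen_t corner[8];
  double val[8];

  auto edge_vertex = [&](int ca, int cb) -> int {
    R_xlen_t ia = corner[ca], ib = corner[cb];
    if (ia > ib) std::swap(ia, ib);
    Key key{ia, ib};
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    const double pa = phi[ia], pb = phi[ib];
    double t = pa / (pa - pb);  // pa, pb have opposite signs
    if (t < 0) t = 0; if (t > 1) t = 1;
    const double ax = (double)(ia % nx), ay = (double)((ia / nx) % ny),
                 az = (double)(ia / sz);
    const double bx2 = (double)(ib % nx), by2 = (double)((ib / nx) % ny),
                 bz2 = (double)(ib / sz);
    vx.push_back((ax + t * (bx2 - ax)) * spacing);
    vy.push_back((ay + t * (by2 - ay)) * spacing);
    vzc.push_back((az + t * (bz2 - az)) * spacing);
    const int id = (int)vx.size();  // 1-based
    vmap.emplace(key, id);
    return id;
  };

  auto emit = [&](int a, int b, int c) {
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  };

  for (int k = 0; k + 1 < nz; k++)
    for (int j = 0; j + 1 < ny; j++)
      for (int i = 0; i + 1 < nx; i++) {
        for (int c = 0; c < 8; c++) {
          const int cx = i + (c & 1), cy = j + ((c >> 1) & 1),
                    cz = k + ((c >> 2) & 1);
          corner[c] = cx + sy * cy + sz * cz;
          val[c] = phi[corner[c]];
        }
        for (int t = 0; t < 6; t++) {
          const int* T = TETS[t];
          int inmask = 0;
          for (int q = 0; q < 4; q++)
            if (val[T[q]] >= 0) inmask |= (1 << q);
          if (inmask == 0 || inmask == 15) continue;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int q = 0; q < 4; q++) {
            if (inmask & (1 << q)) ins[ni++] = T[q]; else outs[no++] = T[q];
          }
          if (ni == 1) {
            emit(edge_vertex(ins[0], outs[0]),
                 edge_vertex(ins[0], outs[1]),
                 edge_vertex(ins[0], outs[2]));
          } else if (ni == 3) {
            emit(edge_vertex(ins[0], outs[0]),
                 edge_vertex(ins[2], outs[0]),
                 edge_vertex(ins[1], outs[0]));
          } else {  // ni == 2: quad split into two triangles
            const int v00 = edge_vertex(ins[0], outs[0]);
            const int v01 = edge_vertex(ins[0], outs[1]);
            const int v10 = edge_vertex(ins[1], outs[0]);
            const int v11 = edge_vertex(ins[1], outs[1]);
            emit(v00, v01, v11);
            emit(v00, v11, v10);
          }
        }
      }

  const int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int q = 0; q < nv; q++) { V(q, 0) = vx[q]; V(q, 1) = vy[q]; V(q, 2) = vzc[q]; }
  const int nt = (int)(tri.size() / 3);
  IntegerMatrix Fm(nt, 3);
  for (int q = 0; q < nt; q++) {
    Fm(q, 0) = tri[3 * q]; Fm(q, 1) = tri[3 * q + 1]; Fm(q, 2) = tri[3 * q + 2];
  }
  return List::create(_["vertices"] = V, _["triangles"] = Fm);
}
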