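// Geometry kernels: isosurface extraction (marching tetrahedra), 26-connected
// flood fill, watertight-mesh voxelization by ray parity, phantom implicit
// solid evaluation. All coordinates are world millimetres; grids are
// column-major (R array layout), voxel (i,j,k) centre = origin + (i,j,k)*spacing.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <functional>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Kuhn decomposition of the unit cube into 6 tetrahedra, all sharing the main
// diagonal corner0-corner7 (corner index bit0->x, bit1->y, bit2->z). Face
// diagonals induced on cube faces are consistent between neighbouring cubes.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

struct MeshAcc {
  std::vector<double> V;                       // xyz triplets
  std::vector<int> T;                          // 0-based vertex triples
  std::unordered_map<uint64_t, int> edge2v;    // grid-edge -> vertex id
};

// Vertex on the grid edge (na, nb); interpolation is canonicalised so both
// traversal directions yield the bit-identical point.
static int edge_vertex(MeshAcc &acc, int na, int nb, double va, double vb,
                       const double *pa, const double *pb, double level) {
  if (na > nb) { std::swap(na, nb); std::swap(va, vb); std::swap(pa, pb); }
  uint64_t key = ((uint64_t)(uint32_t)na << 32) | (uint32_t)nb;
  auto it = acc.edge2v.find(key);
  if (it != acc.edge2v.end()) return it->second;
  double t = (level - va) / (vb - va);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  int id = (int)(acc.V.size() / 3);
  acc.V.push_back(pa[0] + t * (pb[0] - pa[0]));
  acc.V.push_back(pa[1] + t * (pb[1] - pa[1]));
  acc.V.push_back(pa[2] + t * (pb[2] - pa[2]));
  acc.edge2v.emplace(key, id);
  return id;
}

static void push_tri(MeshAcc &acc, int a, int b, int c, const double d[3]) {
  // orient so the normal points from the inside region toward the outside
  const double *p0 = &acc.V[3 * a], *p1 = &acc.V[3 * b], *p2 = &acc.V[3 * c];
  double e1x = p1[0] - p0[0], e1y = p1[1] - p0[1], e1z = p1[2] - p0[2];
  double e2x = p2[0] - p0[0], e2y = p2[1] - p0[1], e2z = p2[2] - p0[2];
  double nx = e1y * e2z - e1z * e2y;
  double ny = e1z * e2x - e1x * e2z;
  double nz = e1x * e2y - e1y * e2x;
  if (nx * d[0] + ny * d[1] + nz * d[2] < 0.0) std::swap(b, c);
  acc.T.push_back(a); acc.T.push_back(b); acc.T.push_back(c);
}

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims,
                    NumericVector origin, NumericVector spacing, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  MeshAcc acc;
  int ids[8];
  double vals[8], pos[8][3];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          int id = ci + nx * (cj + ny * ck);
          ids[c] = id;
          vals[c] = field[id];
          if (vals[c] >= level) ++nin;
          pos[c][0] = ox + ci * sx;
          pos[c][1] = oy + cj * sy;
          pos[c][2] = oz + ck * sz;
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) {
            int c = TETS[t][v];
            if (vals[c] >= level) in_idx[ni++] = c; else out_idx[no++] = c;
          }
          if (ni == 0 || ni == 4) continue;
          double d[3];  // outside centroid minus inside centroid
          for (int q = 0; q < 3; ++q) {
            double ci = 0.0, co = 0.0;
            for (int v = 0; v < ni; ++v) ci += pos[in_idx[v]][q];
            for (int v = 0; v < no; ++v) co += pos[out_idx[v]][q];
            d[q] = co / no - ci / ni;
          }
          if (ni == 1) {
            int A = in_idx[0];
            int a = edge_vertex(acc, ids[A], ids[out_idx[0]], vals[A], vals[out_idx[0]], pos[A], pos[out_idx[0]], level);
            int b = edge_vertex(acc, ids[A], ids[out_idx[1]], vals[A], vals[out_idx[1]], pos[A], pos[out_idx[1]], level);
            int c = edge_vertex(acc, ids[A], ids[out_idx[2]], vals[A], vals[out_idx[2]], pos[A], pos[out_idx[2]], level);
            push_tri(acc, a, b, c, d);
          } else if (ni == 3) {
            int A = out_idx[0];
            int a = edge_vertex(acc, ids[A], ids[in_idx[0]], vals[A], vals[in_idx[0]], pos[A], pos[in_idx[0]], level);
            int b = edge_vertex(acc, ids[A], ids[in_idx[1]], vals[A], vals[in_idx[1]], pos[A], pos[in_idx[1]], level);
            int c = edge_vertex(acc, ids[A], ids[in_idx[2]], vals[A], vals[in_idx[2]], pos[A], pos[in_idx[2]], level);
            push_tri(acc, a, b, c, d);
          } else {  // 2 in, 2 out -> quad split into two triangles
            int A = in_idx[0], B = in_idx[1], C = out_idx[0], D = out_idx[1];
            int q0 = edge_vertex(acc, ids[A], ids[C], vals[A], vals[C], pos[A], pos[C], level);
            int q1 = edge_vertex(acc, ids[A], ids[D], vals[A], vals[D], pos[A], pos[D], level);
            int q2 = edge_vertex(acc, ids[B], ids[D], vals[B], vals[D], pos[B], pos[D], level);
            int q3 = edge_vertex(acc, ids[B], ids[C], vals[B], vals[C], pos[B], pos[C], level);
            push_tri(acc, q0, q1, q2, d);
            push_tri(acc, q0, q2, q3, d);
          }
        }
      }
    }
  }
  int nv = (int)(acc.V.size() / 3), nt = (int)(acc.T.size() / 3);
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v)
    for (int q = 0; q < 3; ++q) verts(v, q) = acc.V[3 * v + q];
  IntegerMatrix tris(nt, 3);
  for (int t = 0; t < nt; ++t)
    for (int q = 0; q < 3; ++q) tris(t, q) = acc.T[3 * t + q] + 1;  // 1-based
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}

// [[Rcpp::export]]
LogicalVector cpp_flood26(LogicalVector mask, IntegerVector dims, int seed0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  if (seed0 < 0 || seed0 >= n || !mask[seed0]) return out;
  std::vector<int> stack;
  stack.push_back(seed0);
  out[seed0] = true;
  while (!stack.empty()) {
    int cur = stack.back();
    stack.pop_back();
    int i = cur % nx, j = (cur / nx) % ny, k = cur / (nx * ny);
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          int nb = ii + nx * (jj + ny * kk);
          if (mask[nb] && !out[nb]) {
            out[nb] = true;
            stack.push_back(nb);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_mesh_components(int n_vertices, IntegerMatrix tris) {
  // union-find over vertices joined by triangle edges; returns 1-based labels
  std::vector<int> parent(n_vertices);
  for (int i = 0; i < n_vertices; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int t = 0; t < tris.nrow(); ++t) {
    int a = find(tris(t, 0) - 1), b = find(tris(t, 1) - 1), c = find(tris(t, 2) - 1);
    if (b != a) parent[b] = a;
    int a2 = find(a);
    if (find(c) != a2) parent[find(c)] = a2;
  }
  std::unordered_map<int, int> relabel;
  IntegerVector out(n_vertices);
  for (int i = 0; i < n_vertices; ++i) {
    int r = find(i);
    auto it = relabel.find(r);
    if (it == relabel.end()) { relabel.emplace(r, (int)relabel.size() + 1); }
    out[i] = relabel[r];
  }
  return out;
}

// Ray-parity voxelization. Columns of voxel centres run along +z; grazing hits
// (a barycentric coordinate within tolerance of zero) trigger a deterministic
// jitter-retry of the whole column.
// [[Rcpp::export]]
List cpp_voxelize(NumericMatrix verts, IntegerMatrix tris,
                  NumericVector c0, NumericVector spacing, IntegerVector ndim) {
  const int nx = ndim[0], ny = ndim[1], nz = ndim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const int nt = tris.nrow();
  // per-column candidate triangle lists
  std::vector<std::vector<int>> cols((size_t)nx * ny);
  for (int t = 0; t < nt; ++t) {
    double xmin = 1e300, xmax = -1e300, ymin = 1e300, ymax = -1e300;
    for (int v = 0; v < 3; ++v) {
      double x = verts(tris(t, v) - 1, 0), y = verts(tris(t, v) - 1, 1);
      xmin = std::min(xmin, x); xmax = std::max(xmax, x);
      ymin = std::min(ymin, y); ymax = std::max(ymax, y);
    }
    int i0 = std::max(0, (int)std::ceil((xmin - c0[0]) / sx - 1.0));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - c0[0]) / sx + 1.0));
    int j0 = std::max(0, (int)std::ceil((ymin - c0[1]) / sy - 1.0));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - c0[1]) / sy + 1.0));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        cols[(size_t)i + (size_t)nx * j].push_back(t);
  }
  static const double JX[6] = {0.0, 0.0123, -0.0157, 0.0231, -0.0271, 0.0313};
  static const double JY[6] = {0.0, -0.0149, 0.0187, -0.0209, 0.0257, -0.0301};
  LogicalVector mask((R_xlen_t)nx * ny * nz, false);
  R_xlen_t count = 0;
  std::vector<double> cross;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const std::vector<int> &cand = cols[(size_t)i + (size_t)nx * j];
      if (cand.empty()) continue;
      bool ok = false;
      for (int a = 0; a < 6 && !ok; ++a) {
        double px = c0[0] + i * sx + JX[a] * sx;
        double py = c0[1] + j * sy + JY[a] * sy;
        cross.clear();
        bool graze = false;
        for (size_t q = 0; q < cand.size() && !graze; ++q) {
          int t = cand[q];
          const int v1 = tris(t, 0) - 1, v2 = tris(t, 1) - 1, v3 = tris(t, 2) - 1;
          double x1 = verts(v1, 0), y1 = verts(v1, 1), z1 = verts(v1, 2);
          double x2 = verts(v2, 0), y2 = verts(v2, 1), z2 = verts(v2, 2);
          double x3 = verts(v3, 0), y3 = verts(v3, 1), z3 = verts(v3, 2);
          double wa = (x2 - px) * (y3 - py) - (x3 - px) * (y2 - py);
          double wb = (x3 - px) * (y1 - py) - (x1 - px) * (y3 - py);
          double wc = (x1 - px) * (y2 - py) - (x2 - px) * (y1 - py);
          double den = wa + wb + wc;  // 2 * signed projected area
          double scale = std::fabs(wa) + std::fabs(wb) + std::fabs(wc);
          if (std::fabs(den) <= 1e-12 * std::max(1.0, scale)) continue;  // vertical facet
          double ba = wa / den, bb = wb / den, bc = wc / den;
          double bmin = std::min(ba, std::min(bb, bc));
          if (bmin > 1e-9) {
            cross.push_back(ba * z1 + bb * z2 + bc * z3);
          } else if (bmin > -1e-9) {
            graze = true;  // on or nearly on an edge: retry jittered
          }
        }
        if (graze) continue;
        if (cross.size() % 2 != 0) continue;  // inconsistent parity: retry
        ok = true;
        std::sort(cross.begin(), cross.end());
        for (size_t m = 0; m + 1 < cross.size(); m += 2) {
          double zlo = cross[m], zhi = cross[m + 1];
          int k0 = (int)std::ceil((zlo - c0[2]) / sz);
          while (c0[2] + k0 * sz <= zlo) ++k0;
          for (int k = std::max(0, k0); k < nz; ++k) {
            double cz = c0[2] + k * sz;
            if (cz >= zhi) break;
            R_xlen_t lin = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            if (!mask[lin]) { mask[lin] = true; ++count; }
          }
        }
      }
    }
  }
  return List::create(_["mask"] = mask, _["count"] = (double)count);
}

// Implicit phantom solid: static LA sphere (radius prm[0], centred at origin)
// united with a scalable appendage = neck cylinder along +x (x in [prm[1],
// prm[2]], radius prm[3]) plus a lobed ellipsoid (centre (prm[4],0,0),
// semiaxes prm[5..7], prm[8] lobes of amplitude prm[9] mm). The appendage is
// scaled by prm[10] about (prm[11], 0, 0).
static inline bool phantom_inside(double x, double y, double z, const double *p) {
  if (x * x + y * y + z * z <= p[0] * p[0]) return true;  // LA body, static
  double s = p[10], cx = p[11];
  double qx = cx + (x - cx) / s, qy = y / s, qz = z / s;
  if (qx >= p[1] && qx <= p[2] && qy * qy + qz * qz <= p[3] * p[3]) return true;
  double u = (qx - p[4]) / p[5], v = qy / p[6], w = qz / p[7];
  double rho = std::sqrt(u * u + v * v + w * w);
  if (rho <= 1e-12) return true;
  double theta = std::atan2(qz, qy);
  double ref = 0.5 * (p[6] + p[7]);
  double f = 1.0 + (p[9] / ref) * std::cos(p[8] * theta);
  return rho <= f;
}

// [[Rcpp::export]]
LogicalVector cpp_phantom_grid(NumericVector xs, NumericVector ys,
                               NumericVector zs, NumericVector prm) {
  const int nx = xs.size(), ny = ys.size(), nz = zs.size();
  const double *p = prm.begin();
  LogicalVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx)
        out[idx] = phantom_inside(xs[i], ys[j], zs[k], p);
  return out;
}

// [[Rcpp::export]]
double cpp_phantom_count(NumericVector xs, NumericVector ys,
                         NumericVector zs, NumericVector prm) {
  const double *p = prm.begin();
  double count = 0.0;
  for (int k = 0; k < zs.size(); ++k)
    for (int j = 0; j < ys.size(); ++j)
      for (int i = 0; i < xs.size(); ++i)
        if (phantom_inside(xs[i], ys[j], zs[k], p)) count += 1.0;
  return count;
}
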