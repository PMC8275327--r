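#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Wyvill soft-object kernel on squared distance: (1 - d^2/R^2)^3 inside the
// influence radius, identically 0 outside (compact support).
static inline double wyvill2(double d2, double R2) {
  if (d2 >= R2) return 0.0;
  double u = 1.0 - d2 / R2;
  return u * u * u;
}

// [[Rcpp::export]]
NumericVector cpp_kernel_value(NumericVector distance, double influence_radius) {
  const double R2 = influence_radius * influence_radius;
  NumericVector out(distance.size());
  for (R_xlen_t i = 0; i < distance.size(); ++i)
    out[i] = wyvill2(distance[i] * distance[i], R2);
  return out;
}

// Accumulate the summed metaball field on an axis-aligned node grid.
// Near-linear: each ball only touches nodes inside its own support box.
// [[Rcpp::export]]
NumericVector cpp_accumulate_field(NumericMatrix centers, NumericVector influence,
                                   NumericVector origin, double spacing,
                                   IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nn = (R_xlen_t)nx * ny * nz;
  NumericVector values(nn);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int nb = centers.nrow();
  for (int b = 0; b < nb; ++b) {
    const double cx = centers(b, 0), cy = centers(b, 1), cz = centers(b, 2);
    const double R = influence[b], R2 = R * R;
    int i0 = (int)std::ceil((cx - R - ox) / spacing);
    int i1 = (int)std::floor((cx + R - ox) / spacing);
    int j0 = (int)std::ceil((cy - R - oy) / spacing);
    int j1 = (int)std::floor((cy + R - oy) / spacing);
    int k0 = (int)std::ceil((cz - R - oz) / spacing);
    int k1 = (int)std::floor((cz + R - oz) / spacing);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = oz + k * spacing - cz, dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = oy + j * spacing - cy, d2yz = dy * dy + dz2;
        if (d2yz >= R2) continue;
        const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          const double dx = ox + i * spacing - cx;
          const double d2 = dx * dx + d2yz;
          if (d2 < R2) values[base + i] += wyvill2(d2, R2);
        }
      }
    }
  }
  return values;
}

// Maximum field value over the six boundary faces of the grid (padding check).
// [[Rcpp::export]]
double cpp_boundary_max(NumericVector values, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double m = 0.0;
  auto at = [&](int i, int j, int k) {
    return values[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      if (at(0, j, k) > m) m = at(0, j, k);
      if (at(nx - 1, j, k) > m) m = at(nx - 1, j, k);
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      if (at(i, 0, k) > m) m = at(i, 0, k);
      if (at(i, ny - 1, k) > m) m = at(i, ny - 1, k);
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (at(i, j, 0) > m) m = at(i, j, 0);
      if (at(i, j, nz - 1) > m) m = at(i, j, nz - 1);
    }
  return m;
}

// Field value at arbitrary query points: brute-force summation or a uniform
// hash grid over ball centers (cell edge = max influence radius). The two
// paths must agree to floating tolerance; the index is a performance contract.
// [[Rcpp::export]]
NumericVector cpp_field_at_points(NumericMatrix centers, NumericVector influence,
                                  NumericMatrix pts, bool use_index) {
  const int nb = centers.nrow(), np = pts.nrow();
  NumericVector out(np);
  if (nb == 0) return out;
  if (!use_index) {
    for (int p = 0; p < np; ++p) {
      double s = 0.0;
      const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
      for (int b = 0; b < nb; ++b) {
        const double dx = px - centers(b, 0), dy = py - centers(b, 1),
                     dz = pz - centers(b, 2);
        const double R = influence[b];
        s += wyvill2(dx * dx + dy * dy + dz * dz, R * R);
      }
      out[p] = s;
    }
    return out;
  }
  double h = 0.0;
  for (int b = 0; b < nb; ++b) if (influence[b] > h) h = influence[b];
  if (h <= 0.0) stop("non-positive influence radius");
  double mx = centers(0, 0), my = centers(0, 1), mz = centers(0, 2);
  for (int b = 0; b < nb; ++b) {
    if (centers(b, 0) < mx) mx = centers(b, 0);
    if (centers(b, 1) < my) my = centers(b, 1);
    if (centers(b, 2) < mz) mz = centers(b, 2);
  }
  auto cellkey = [&](double x, double y, double z) {
    int64_t ci = (int64_t)std::floor((x - mx) / h);
    int64_t cj = (int64_t)std::floor((y - my) / h);
    int64_t ck = (int64_t)std::floor((z - mz) / h);
    return (uint64_t)(ci & 0x1FFFFF) | ((uint64_t)(cj & 0x1FFFFF) << 21) |
           ((uint64_t)(ck & 0x1FFFFF) << 42);
  };
  std::unordered_map<uint64_t, std::vector<int> > grid;
  grid.reserve(nb * 2);
  for (int b = 0; b < nb; ++b)
    grid[cellkey(centers(b, 0), centers(b, 1), centers(b, 2))].push_back(b);
  for (int p = 0; p < np; ++p) {
    const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double s = 0.0;
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk) {
          uint64_t key = cellkey(px + di * h, py + dj * h, pz + dk * h);
          auto it = grid.find(key);
          if (it == grid.end()) continue;
          for (int b : it->second) {
            const double dx = px - centers(b, 0), dy = py - centers(b, 1),
                         dz = pz - centers(b, 2);
            const double R = influence[b];
            s += wyvill2(dx * dx + dy * dy + dz * dz, R * R);
          }
        }
    out[p] = s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on the Freudenthal (Kuhn) 6-tetrahedra decomposition of
// each grid cell. The decomposition is globally consistent across shared cube
// faces, and a tetrahedron has no ambiguous sign configurations, so the
// extracted isosurface is a closed 2-manifold whenever the field is below the
// iso-level on all boundary nodes: every interior triangle edge is shared by
// exactly two triangles.
// ---------------------------------------------------------------------------

// Cube corner c has offsets (c&1, (c>>1)&1, (c>>2)&1). The 6 tetrahedra are
// the monotone lattice paths from corner 0 to corner 7.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector values, IntegerVector dims,
                       NumericVector origin, double spacing, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  // values within tol of the iso-level are nudged above it so no crossing
  // lands exactly on a grid node; keeps every interpolation parameter well
  // inside (0,1) and bounds sliver-triangle degeneracy away from zero
  const double tol = 1e-4 * std::max(1.0, std::fabs(iso));

  // geometric orientation sign of each tetrahedron in the unit cube
  int tet_sign[6];
  for (int t = 0; t < 6; ++t) {
    double P[4][3];
    for (int v = 0; v < 4; ++v) {
      int c = TETS[t][v];
      P[v][0] = c & 1; P[v][1] = (c >> 1) & 1; P[v][2] = (c >> 2) & 1;
    }
    double a[3], b[3], c3[3];
    for (int d = 0; d < 3; ++d) {
      a[d] = P[1][d] - P[0][d];
      b[d] = P[2][d] - P[0][d];
      c3[d] = P[3][d] - P[0][d];
    }
    double det = a[0] * (b[1] * c3[2] - b[2] * c3[1])
               - a[1] * (b[0] * c3[2] - b[2] * c3[0])
               + a[2] * (b[0] * c3[1] - b[1] * c3[0]);
    tet_sign[t] = det > 0 ? 1 : -1;
  }

  auto fval = [&](R_xlen_t n) {
    double v = values[n];
    if (std::fabs(v - iso) < tol) v = iso + tol;  // avoid on-node crossings
    return v;
  };

  std::unordered_map<uint64_t, int> evmap;
  evmap.reserve(1 << 16);
  std::vector<double> VX, VY, VZ;
  std::vector<int> tris;

  auto node_pos = [&](R_xlen_t n, double *p) {
    int i = (int)(n % nx);
    int j = (int)((n / nx) % ny);
    int k = (int)(n / ((R_xlen_t)nx * ny));
    p[0] = ox + i * spacing; p[1] = oy + j * spacing; p[2] = oz + k * spacing;
  };

  auto edge_vertex = [&](R_xlen_t na, R_xlen_t nb) -> int {
    uint64_t lo = (uint64_t)std::min(na, nb), hi = (uint64_t)std::max(na, nb);
    uint64_t key = (lo << 32) | hi;
    auto it = evmap.find(key);
    if (it != evmap.end()) return it->second;
    double fa = fval(na), fb = fval(nb);
    double t = (iso - fa) / (fb - fa);
    if (t < 0.0) t = 0.0; if (t > 1.0) t = 1.0;
    double pa[3], pb[3];
    node_pos(na, pa); node_pos(nb, pb);
    int id = (int)VX.size();
    VX.push_back(pa[0] + t * (pb[0] - pa[0]));
    VY.push_back(pa[1] + t * (pb[1] - pa[1]));
    VZ.push_back(pa[2] + t * (pb[2] - pa[2]));
    evmap.emplace(key, id);
    return id;
  };

  auto emit = [&](int a, int b, int c, bool flip) {
    if (flip) { tris.push_back(a); tris.push_back(c); tris.push_back(b); }
    else      { tris.push_back(a); tris.push_back(b); tris.push_back(c); }
  };

  // permutation parity: number of inversions of a 4-permutation
  auto odd_perm = [](const int *p) {
    int inv = 0;
    for (int i = 0; i < 4; ++i)
      for (int j = i + 1; j < 4; ++j)
        if (p[i] > p[j]) ++inv;
    return (inv & 1) == 1;
  };

  R_xlen_t corner_off[8];
  for (int c = 0; c < 8; ++c)
    corner_off[c] = (c & 1) + (R_xlen_t)nx * (((c >> 1) & 1) + (R_xlen_t)ny * ((c >> 2) & 1));

  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      R_xlen_t rowbase = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx - 1; ++i) {
        R_xlen_t n0 = rowbase + i;
        double f[8];
        R_xlen_t nid[8];
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          nid[c] = n0 + corner_off[c];
          f[c] = fval(nid[c]);
          if (f[c] >= iso) ++nin;
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int inside[4], outside[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) {
            if (f[T[v]] >= iso) inside[ni++] = v; else outside[no++] = v;
          }
          if (ni == 0 || ni == 4) continue;
          bool neg = tet_sign[t] < 0;
          if (ni == 1 || ni == 3) {
            int a = (ni == 1) ? inside[0] : outside[0];
            int oth[3], m = 0;
            for (int v = 0; v < 4; ++v) if (v != a) oth[m++] = v;
            int e0 = edge_vertex(nid[T[a]], nid[T[oth[0]]]);
            int e1 = edge_vertex(nid[T[a]], nid[T[oth[1]]]);
            int e2 = edge_vertex(nid[T[a]], nid[T[oth[2]]]);
            // moving a to front costs `a` adjacent swaps
            bool flip = ((a & 1) == 1) ^ neg ^ (ni == 3);
            emit(e0, e1, e2, flip);
          } else {  // 2 in, 2 out
            int a = inside[0], b = inside[1], c = outside[0], d = outside[1];
            int perm[4] = {a, b, c, d};
            bool flip = odd_perm(perm) ^ neg;
            int A = edge_vertex(nid[T[a]], nid[T[c]]);
            int B = edge_vertex(nid[T[a]], nid[T[d]]);
            int C = edge_vertex(nid[T[b]], nid[T[d]]);
            int D = edge_vertex(nid[T[b]], nid[T[c]]);
            emit(A, B, C, flip);
            emit(A, C, D, flip);
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  const int nv = (int)VX.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = VX[v]; V(v, 1) = VY[v]; V(v, 2) = VZ[v];
  }
  const int nf = (int)(tris.size() / 3);
  IntegerMatrix F(nf, 3);
  for (int fI = 0; fI < nf; ++fI) {
    F(fI, 0) = tris[3 * fI] + 1;      // 1-based for R
    F(fI, 1) = tris[3 * fI + 1] + 1;
    F(fI, 2) = tris[3 * fI + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
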