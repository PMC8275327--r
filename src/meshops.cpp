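#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t ekey(int a, int b) {
  uint64_t lo = (uint64_t)std::min(a, b), hi = (uint64_t)std::max(a, b);
  return (lo << 32) | hi;
}

// ---- connected components of faces through shared vertices -----------------

struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};

// [[Rcpp::export]]
IntegerVector cpp_face_components(IntegerMatrix F, int nv) {
  UF uf(nv);
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    uf.unite(F(f, 0) - 1, F(f, 1) - 1);
    uf.unite(F(f, 0) - 1, F(f, 2) - 1);
  }
  std::unordered_map<int, int> relabel;
  IntegerVector comp(nf);
  for (int f = 0; f < nf; ++f) {
    int r = uf.find(F(f, 0) - 1);
    auto it = relabel.find(r);
    int id;
    if (it == relabel.end()) { id = (int)relabel.size() + 1; relabel[r] = id; }
    else id = it->second;
    comp[f] = id;
  }
  return comp;
}

// ---- edge incidence statistics ---------------------------------------------

// [[Rcpp::export]]
List cpp_edge_stats(IntegerMatrix F) {
  std::unordered_map<uint64_t, int> cnt;
  cnt.reserve(F.nrow() * 3);
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f)
    for (int e = 0; e < 3; ++e)
      cnt[ekey(F(f, e), F(f, (e + 1) % 3))]++;
  int nb = 0, nnm = 0, maxinc = 0;
  std::vector<int> bsrc, bdst, nmsrc, nmdst;
  for (auto &kv : cnt) {
    int a = (int)(kv.first >> 32), b = (int)(kv.first & 0xFFFFFFFFULL);
    if (kv.second > maxinc) maxinc = kv.second;
    if (kv.second == 1) { ++nb; bsrc.push_back(a); bdst.push_back(b); }
    else if (kv.second > 2) { ++nnm; nmsrc.push_back(a); nmdst.push_back(b); }
  }
  IntegerMatrix BE(nb, 2), NME(nnm, 2);
  for (int i = 0; i < nb; ++i) { BE(i, 0) = bsrc[i]; BE(i, 1) = bdst[i]; }
  for (int i = 0; i < nnm; ++i) { NME(i, 0) = nmsrc[i]; NME(i, 1) = nmdst[i]; }
  return List::create(_["n_edges"] = (int)cnt.size(),
                      _["n_boundary"] = nb, _["n_nonmanifold"] = nnm,
                      _["max_incidence"] = maxinc,
                      _["boundary_edges"] = BE, _["nonmanifold_edges"] = NME);
}

// ---- non-manifold vertices --------------------------------------------------
// A vertex is manifold when its incident faces form one edge-connected fan
// (cycle for interior vertices, single path along a boundary) and no incident
// edge has more than two faces.

// [[Rcpp::export]]
IntegerVector cpp_nonmanifold_vertices(IntegerMatrix F, int nv) {
  const int nf = F.nrow();
  std::vector<std::vector<int> > vf(nv);
  for (int f = 0; f < nf; ++f)
    for (int e = 0; e < 3; ++e) vf[F(f, e) - 1].push_back(f);
  std::vector<int> bad;
  std::vector<int> mark(nf, -1);
  for (int v = 0; v < nv; ++v) {
    const std::vector<int> &fs = vf[v];
    if (fs.empty()) continue;
    // local edges at v: map other-endpoint -> incident local faces
    std::unordered_map<int, std::vector<int> > le;
    for (size_t s = 0; s < fs.size(); ++s) {
      int f = fs[s];
      for (int e = 0; e < 3; ++e) {
        int w = F(f, e) - 1;
        if (w != v) le[w].push_back((int)s);
      }
    }
    bool nm = false;
    for (auto &kv : le) if (kv.second.size() > 2) { nm = true; break; }
    if (!nm) {
      // connected components of the local face graph (faces adjacent when
      // they share an edge through v)
      std::vector<std::vector<int> > adj(fs.size());
      for (auto &kv : le)
        if (kv.second.size() == 2) {
          adj[kv.second[0]].push_back(kv.second[1]);
          adj[kv.second[1]].push_back(kv.second[0]);
        }
      std::vector<char> seen(fs.size(), 0);
      std::vector<int> stack;
      stack.push_back(0);
      seen[0] = 1;
      size_t cnt = 1;
      while (!stack.empty()) {
        int c = stack.back(); stack.pop_back();
        for (int nb2 : adj[c])
          if (!seen[nb2]) { seen[nb2] = 1; ++cnt; stack.push_back(nb2); }
      }
      if (cnt != fs.size()) nm = true;
    }
    if (nm) bad.push_back(v + 1);
  }
  return wrap(bad);
}

// ---- coherent orientation ----------------------------------------------------
// Breadth-first propagation across manifold edges; two faces sharing an edge
// are coherently oriented when they traverse it in opposite directions.

// [[Rcpp::export]]
List cpp_orient_coherent(IntegerMatrix Fin) {
  IntegerMatrix F = clone(Fin);
  const int nf = F.nrow();
  std::unordered_map<uint64_t, std::vector<int> > ef;
  ef.reserve(nf * 3);
  for (int f = 0; f < nf; ++f)
    for (int e = 0; e < 3; ++e)
      ef[ekey(F(f, e), F(f, (e + 1) % 3))].push_back(f);
  auto dir = [&](int f, int a, int b) {
    // +1 if face f contains directed edge a->b, -1 if b->a, 0 otherwise
    for (int e = 0; e < 3; ++e) {
      int u = F(f, e), v = F(f, (e + 1) % 3);
      if (u == a && v == b) return 1;
      if (u == b && v == a) return -1;
    }
    return 0;
  };
  std::vector<char> seen(nf, 0);
  int flipped = 0;
  bool consistent = true;
  for (int f0 = 0; f0 < nf; ++f0) {
    if (seen[f0]) continue;
    seen[f0] = 1;
    std::queue<int> q;
    q.push(f0);
    while (!q.empty()) {
      int f = q.front(); q.pop();
      for (int e = 0; e < 3; ++e) {
        int a = F(f, e), b = F(f, (e + 1) % 3);
        auto &fl = ef[ekey(a, b)];
        if (fl.size() != 2) continue;  // boundary or non-manifold: skip
        int g = fl[0] == f ? fl[1] : fl[0];
        int need_opposite = dir(f, a, b);
        int got = dir(g, a, b);
        if (!seen[g]) {
          if (got == need_opposite) {  // same direction -> flip g
            int tmp = F(g, 1); F(g, 1) = F(g, 2); F(g, 2) = tmp;
            ++flipped;
          }
          seen[g] = 1;
          q.push(g);
        } else if (got == need_opposite) {
          consistent = false;
        }
      }
    }
  }
  return List::create(_["faces"] = F, _["n_flipped"] = flipped,
                      _["consistent"] = consistent);
}

// ---- closest point on triangle (Ericson, Real-Time Collision Detection) ----

static void closest_on_tri(const double *p, const double *a, const double *b,
                           const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// ---- point-to-mesh distance with a uniform triangle grid --------------------

// [[Rcpp::export]]
List cpp_point_mesh(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  const int np = pts.nrow(), nf = F.nrow();
  NumericVector dist(np);
  NumericMatrix closest(np, 3);
  IntegerVector fid(np);
  if (nf == 0) stop("empty mesh");
  double mn[3], mx[3];
  for (int d = 0; d < 3; ++d) { mn[d] = R_PosInf; mx[d] = R_NegInf; }
  for (int v = 0; v < V.nrow(); ++v)
    for (int d = 0; d < 3; ++d) {
      if (V(v, d) < mn[d]) mn[d] = V(v, d);
      if (V(v, d) > mx[d]) mx[d] = V(v, d);
    }
  double diag = std::sqrt((mx[0]-mn[0])*(mx[0]-mn[0]) + (mx[1]-mn[1])*(mx[1]-mn[1])
                          + (mx[2]-mn[2])*(mx[2]-mn[2]));
  if (diag <= 0) diag = 1.0;
  // aim for a few triangles per occupied cell
  double h = diag / std::max(4.0, std::cbrt((double)nf) * 2.0);
  int gd[3];
  for (int d = 0; d < 3; ++d) {
    gd[d] = std::max(1, (int)std::ceil((mx[d] - mn[d]) / h) + 1);
    if (gd[d] > 512) gd[d] = 512;
  }
  double hh[3];
  for (int d = 0; d < 3; ++d)
    hh[d] = std::max((mx[d] - mn[d]) / gd[d], 1e-12);
  auto cell = [&](double x, int d) {
    int c = (int)std::floor((x - mn[d]) / hh[d]);
    if (c < 0) c = 0; if (c > gd[d] - 1) c = gd[d] - 1;
    return c;
  };
  std::vector<std::vector<int> > grid((size_t)gd[0] * gd[1] * gd[2]);
  auto gidx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)gd[0] * (j + (size_t)gd[1] * k);
  };
  for (int f = 0; f < nf; ++f) {
    double tmn[3] = {R_PosInf, R_PosInf, R_PosInf},
           tmx[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int e = 0; e < 3; ++e) {
      int v = F(f, e) - 1;
      for (int d = 0; d < 3; ++d) {
        if (V(v, d) < tmn[d]) tmn[d] = V(v, d);
        if (V(v, d) > tmx[d]) tmx[d] = V(v, d);
      }
    }
    int i0 = cell(tmn[0], 0), i1 = cell(tmx[0], 0);
    int j0 = cell(tmn[1], 1), j1 = cell(tmx[1], 1);
    int k0 = cell(tmn[2], 2), k1 = cell(tmx[2], 2);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          grid[gidx(i, j, k)].push_back(f);
  }
  double hmin = std::min(hh[0], std::min(hh[1], hh[2]));
  int rmax = gd[0] + gd[1] + gd[2];
  for (int p = 0; p < np; ++p) {
    double P[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    int ci = cell(P[0], 0), cj = cell(P[1], 1), ck = cell(P[2], 2);
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int bestf = -1;
    for (int r = 0; r <= rmax; ++r) {
      if (bestf >= 0 && (double)(r - 1) * hmin > best) break;
      bool any = false;
      int i0 = std::max(0, ci - r), i1 = std::min(gd[0] - 1, ci + r);
      int j0 = std::max(0, cj - r), j1 = std::min(gd[1] - 1, cj + r);
      int k0 = std::max(0, ck - r), k1 = std::min(gd[2] - 1, ck + r);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            int cheb = std::max(std::abs(i - ci),
                       std::max(std::abs(j - cj), std::abs(k - ck)));
            if (cheb != r) continue;  // only the new shell
            any = true;
            for (int f : grid[gidx(i, j, k)]) {
              const double *a = &V(F(f, 0) - 1, 0);
              // column-major access: gather explicitly
              double A[3], B[3], C[3], q[3];
              for (int d = 0; d < 3; ++d) {
                A[d] = V(F(f, 0) - 1, d);
                B[d] = V(F(f, 1) - 1, d);
                C[d] = V(F(f, 2) - 1, d);
              }
              (void)a;
              closest_on_tri(P, A, B, C, q);
              double dd = (q[0]-P[0])*(q[0]-P[0]) + (q[1]-P[1])*(q[1]-P[1])
                        + (q[2]-P[2])*(q[2]-P[2]);
              if (dd < best) {
                best = dd; bestf = f;
                bestpt[0] = q[0]; bestpt[1] = q[1]; bestpt[2] = q[2];
              }
            }
          }
      if (!any && bestf >= 0 && r > 0 && i0 == 0 && j0 == 0 && k0 == 0 &&
          i1 == gd[0] - 1 && j1 == gd[1] - 1 && k1 == gd[2] - 1)
        break;  // grid exhausted
    }
    dist[p] = std::sqrt(best);
    fid[p] = bestf + 1;
    closest(p, 0) = bestpt[0]; closest(p, 1) = bestpt[1]; closest(p, 2) = bestpt[2];
    if ((p & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["face"] = fid);
}

// ---- triangle-triangle intersection (Moller interval test) ------------------

static inline void cross3(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static bool seg2_intersect(const double *p1, const double *q1,
                           const double *p2, const double *q2) {
  auto orient = [](const double *a, const double *b, const double *c) {
    return (b[0] - a[0]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[0] - a[0]);
  };
  double d1 = orient(p2, q2, p1), d2 = orient(p2, q2, q1);
  double d3 = orient(p1, q1, p2), d4 = orient(p1, q1, q2);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return true;
  return false;
}

static bool point_in_tri2(const double *p, const double *a, const double *b,
                          const double *c) {
  auto orient = [](const double *u, const double *v, const double *w) {
    return (v[0] - u[0]) * (w[1] - u[1]) - (v[1] - u[1]) * (w[0] - u[0]);
  };
  double d1 = orient(a, b, p), d2 = orient(b, c, p), d3 = orient(c, a, p);
  bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
  bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
  return !(neg && pos);
}

static bool coplanar_overlap(const double T1[3][3], const double T2[3][3],
                             const double *n) {
  // project onto the dominant axis plane
  int ax = 0;
  double an[3] = {std::fabs(n[0]), std::fabs(n[1]), std::fabs(n[2])};
  if (an[1] > an[ax]) ax = 1;
  if (an[2] > an[ax]) ax = 2;
  int u = (ax + 1) % 3, v = (ax + 2) % 3;
  double A[3][2], B[3][2];
  for (int i = 0; i < 3; ++i) {
    A[i][0] = T1[i][u]; A[i][1] = T1[i][v];
    B[i][0] = T2[i][u]; B[i][1] = T2[i][v];
  }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      if (seg2_intersect(A[i], A[(i + 1) % 3], B[j], B[(j + 1) % 3]))
        return true;
  if (point_in_tri2(A[0], B[0], B[1], B[2])) return true;
  if (point_in_tri2(B[0], A[0], A[1], A[2])) return true;
  return false;
}

static bool tri_tri_intersect(const double T1[3][3], const double T2[3][3]) {
  // scale-relative tolerance: triangle pairs whose penetration depth is below
  // ~1e-7 of their own size are classified as touching, not intersecting
  double size = 0.0;
  for (int d = 0; d < 3; ++d) {
    double lo = T1[0][d], hi = T1[0][d];
    for (int v = 1; v < 3; ++v) {
      lo = std::min(lo, T1[v][d]); hi = std::max(hi, T1[v][d]);
    }
    for (int v = 0; v < 3; ++v) {
      lo = std::min(lo, T2[v][d]); hi = std::max(hi, T2[v][d]);
    }
    size = std::max(size, hi - lo);
  }
  const double EPS = 1e-7 * std::max(size, 1e-30);
  double e1[3], e2[3], n1[3];
  for (int i = 0; i < 3; ++i) {
    e1[i] = T1[1][i] - T1[0][i];
    e2[i] = T1[2][i] - T1[0][i];
  }
  cross3(e1, e2, n1);
  double nl = std::sqrt(dot3(n1, n1));
  if (nl < 1e-30) return false;  // degenerate triangle
  for (int i = 0; i < 3; ++i) n1[i] /= nl;
  double d1 = -dot3(n1, T1[0]);
  double du[3];
  for (int i = 0; i < 3; ++i) {
    du[i] = dot3(n1, T2[i]) + d1;  // true distances to T1's plane
    if (std::fabs(du[i]) < EPS) du[i] = 0.0;
  }
  if ((du[0] > 0 && du[1] > 0 && du[2] > 0) ||
      (du[0] < 0 && du[1] < 0 && du[2] < 0))
    return false;
  double n2[3];
  for (int i = 0; i < 3; ++i) {
    e1[i] = T2[1][i] - T2[0][i];
    e2[i] = T2[2][i] - T2[0][i];
  }
  cross3(e1, e2, n2);
  nl = std::sqrt(dot3(n2, n2));
  if (nl < 1e-30) return false;
  for (int i = 0; i < 3; ++i) n2[i] /= nl;
  double d2 = -dot3(n2, T2[0]);
  double dv[3];
  for (int i = 0; i < 3; ++i) {
    dv[i] = dot3(n2, T1[i]) + d2;
    if (std::fabs(dv[i]) < EPS) dv[i] = 0.0;
  }
  if ((dv[0] > 0 && dv[1] > 0 && dv[2] > 0) ||
      (dv[0] < 0 && dv[1] < 0 && dv[2] < 0))
    return false;
  if (du[0] == 0 && du[1] == 0 && du[2] == 0)
    return coplanar_overlap(T1, T2, n1);
  // penetration requires each triangle to strictly straddle the other's
  // plane; grazing contacts (a vertex or edge in the plane, rest one-sided)
  // are touches, not intersections
  auto straddles = [](const double *w) {
    bool pos = w[0] > 0 || w[1] > 0 || w[2] > 0;
    bool neg = w[0] < 0 || w[1] < 0 || w[2] < 0;
    return pos && neg;
  };
  if (!straddles(du) || !straddles(dv)) return false;

  double D[3];
  cross3(n1, n2, D);
  int ax = 0;
  double ad[3] = {std::fabs(D[0]), std::fabs(D[1]), std::fabs(D[2])};
  if (ad[1] > ad[ax]) ax = 1;
  if (ad[2] > ad[ax]) ax = 2;

  auto interval = [&](const double T[3][3], const double *dv_, double *t) -> bool {
    double p[3] = {T[0][ax], T[1][ax], T[2][ax]};
    // arrange so that vertex `solo` is on one side, the others opposite/zero
    int solo = -1;
    if (dv_[0] * dv_[1] > 0) solo = 2;
    else if (dv_[0] * dv_[2] > 0) solo = 1;
    else if (dv_[1] * dv_[2] > 0) solo = 0;
    else {
      // some zeros: pick a vertex with nonzero sign if any, else degenerate
      if (dv_[0] != 0) solo = 0;
      else if (dv_[1] != 0) solo = 1;
      else if (dv_[2] != 0) solo = 2;
      else return false;
    }
    int o1 = (solo + 1) % 3, o2 = (solo + 2) % 3;
    double denom1 = dv_[solo] - dv_[o1];
    double denom2 = dv_[solo] - dv_[o2];
    t[0] = p[solo] + (p[o1] - p[solo]) * (denom1 != 0 ? dv_[solo] / denom1 : 0.0);
    t[1] = p[solo] + (p[o2] - p[solo]) * (denom2 != 0 ? dv_[solo] / denom2 : 0.0);
    if (t[0] > t[1]) std::swap(t[0], t[1]);
    return true;
  };
  double i1[2], i2[2];
  if (!interval(T1, dv, i1)) return false;
  if (!interval(T2, du, i2)) return false;
  return (i1[0] < i2[1] - EPS) && (i2[0] < i1[1] - EPS);
}

// [[Rcpp::export]]
List cpp_self_intersections(NumericMatrix V, IntegerMatrix F, bool brute) {
  const int nf = F.nrow();
  auto share_vertex = [&](int f, int g) {
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        if (F(f, i) == F(g, j)) return true;
    return false;
  };
  auto load = [&](int f, double T[3][3]) {
    for (int e = 0; e < 3; ++e)
      for (int d = 0; d < 3; ++d) T[e][d] = V(F(f, e) - 1, d);
  };
  std::vector<int> pi, pj;
  long count = 0;
  if (brute) {
    for (int f = 0; f < nf; ++f) {
      double T1[3][3];
      load(f, T1);
      for (int g = f + 1; g < nf; ++g) {
        if (share_vertex(f, g)) continue;
        double T2[3][3];
        load(g, T2);
        if (tri_tri_intersect(T1, T2)) {
          ++count; pi.push_back(f + 1); pj.push_back(g + 1);
        }
      }
      if ((f & 255) == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    // sparse hash grid; cell edge ~ 2x the mean triangle extent so each cell
    // holds O(1) triangles even on huge meshes
    std::vector<double> bmn(3 * nf), bmx(3 * nf);
    double ext = 0.0;
    for (int f = 0; f < nf; ++f) {
      for (int d = 0; d < 3; ++d) {
        double lo = R_PosInf, hi = R_NegInf;
        for (int e = 0; e < 3; ++e) {
          double x = V(F(f, e) - 1, d);
          if (x < lo) lo = x;
          if (x > hi) hi = x;
        }
        bmn[3 * f + d] = lo;
        bmx[3 * f + d] = hi;
        if (hi - lo > 0) ext += (hi - lo);
      }
    }
    double h = std::max(2.0 * ext / (3.0 * std::max(nf, 1)), 1e-9);
    auto cellc = [&](double x) { return (int64_t)std::floor(x / h); };
    auto key3 = [](int64_t i, int64_t j, int64_t k) {
      return (uint64_t)(i & 0x1FFFFF) | ((uint64_t)(j & 0x1FFFFF) << 21) |
             ((uint64_t)(k & 0x1FFFFF) << 42);
    };
    std::unordered_map<uint64_t, std::vector<int> > grid;
    grid.reserve(nf * 2);
    std::vector<int64_t> c0(3 * nf), c1(3 * nf);
    for (int f = 0; f < nf; ++f) {
      for (int d = 0; d < 3; ++d) {
        c0[3 * f + d] = cellc(bmn[3 * f + d]);
        c1[3 * f + d] = cellc(bmx[3 * f + d]);
      }
      for (int64_t k = c0[3 * f + 2]; k <= c1[3 * f + 2]; ++k)
        for (int64_t j = c0[3 * f + 1]; j <= c1[3 * f + 1]; ++j)
          for (int64_t i = c0[3 * f]; i <= c1[3 * f]; ++i)
            grid[key3(i, j, k)].push_back(f);
    }
    long done = 0;
    for (auto &kv : grid) {
      auto &cl = kv.second;
      for (size_t x = 0; x < cl.size(); ++x)
        for (size_t y = x + 1; y < cl.size(); ++y) {
          int f = std::min(cl[x], cl[y]), g = std::max(cl[x], cl[y]);
          // test each pair only in the canonical (lowest common) cell
          int64_t ci = std::max(c0[3 * f], c0[3 * g]);
          int64_t cj = std::max(c0[3 * f + 1], c0[3 * g + 1]);
          int64_t ck = std::max(c0[3 * f + 2], c0[3 * g + 2]);
          if (kv.first != key3(ci, cj, ck)) continue;
          // quick bbox overlap reject
          bool sep = false;
          for (int d = 0; d < 3; ++d)
            if (bmn[3 * f + d] > bmx[3 * g + d] ||
                bmn[3 * g + d] > bmx[3 * f + d]) { sep = true; break; }
          if (sep) continue;
          if (share_vertex(f, g)) continue;
          double T1[3][3], T2[3][3];
          load(f, T1);
          load(g, T2);
          if (tri_tri_intersect(T1, T2)) {
            ++count; pi.push_back(f + 1); pj.push_back(g + 1);
          }
        }
      if (((++done) & 16383) == 0) Rcpp::checkUserInterrupt();
    }
  }
  IntegerMatrix P(pi.size(), 2);
  for (size_t i = 0; i < pi.size(); ++i) { P(i, 0) = pi[i]; P(i, 1) = pj[i]; }
  return List::create(_["count"] = (double)count, _["pairs"] = P);
}
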