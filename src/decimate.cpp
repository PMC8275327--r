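#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Quadric error metric edge-collapse decimation (Garland & Heckbert style).
// Collapses are rejected when they would break manifoldness (link condition)
// or flip a face normal, so a closed manifold stays a closed manifold.

namespace {

struct Quadric {
  // symmetric 4x4, upper triangle: a11 a12 a13 a14 a22 a23 a24 a33 a34 a44
  double q[10];
  Quadric() { for (int i = 0; i < 10; ++i) q[i] = 0; }
  void add_plane(double nx, double ny, double nz, double d, double w) {
    q[0] += w * nx * nx; q[1] += w * nx * ny; q[2] += w * nx * nz;
    q[3] += w * nx * d;  q[4] += w * ny * ny; q[5] += w * ny * nz;
    q[6] += w * ny * d;  q[7] += w * nz * nz; q[8] += w * nz * d;
    q[9] += w * d * d;
  }
  void add(const Quadric &o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(const double *p) const {
    double x = p[0], y = p[1], z = p[2];
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z + q[9];
  }
  bool optimal(double *p) const {
    double a = q[0], b = q[1], c = q[2], d = q[4], e = q[5], f = q[7];
    double det = a*(d*f - e*e) - b*(b*f - e*c) + c*(b*e - d*c);
    if (std::fabs(det) < 1e-12) return false;
    double rx = -q[3], ry = -q[6], rz = -q[8];
    double ix = (rx*(d*f - e*e) - b*(ry*f - e*rz) + c*(ry*e - d*rz)) / det;
    double iy = (a*(ry*f - rz*e) - rx*(b*f - e*c) + c*(b*rz - ry*c)) / det;
    double iz = (a*(d*rz - ry*e) - b*(b*rz - ry*c) + rx*(b*e - d*c)) / det;
    p[0] = ix; p[1] = iy; p[2] = iz;
    return true;
  }
};

struct HeapItem {
  double cost;
  int v1, v2;
  uint64_t stamp;
  bool operator<(const HeapItem &o) const { return cost > o.cost; }  // min-heap
};

}  // namespace

// [[Rcpp::export]]
List cpp_decimate_qem(NumericMatrix Vin, IntegerMatrix Fin, int target_faces) {
  const int nv = Vin.nrow(), nf0 = Fin.nrow();
  std::vector<double> P(3 * nv);
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) P[3 * v + d] = Vin(v, d);
  std::vector<int> Fa(3 * nf0);
  for (int f = 0; f < nf0; ++f)
    for (int e = 0; e < 3; ++e) Fa[3 * f + e] = Fin(f, e) - 1;
  std::vector<char> face_alive(nf0, 1), vert_alive(nv, 1);
  std::vector<std::unordered_set<int> > vfaces(nv);
  for (int f = 0; f < nf0; ++f)
    for (int e = 0; e < 3; ++e) vfaces[Fa[3 * f + e]].insert(f);

  auto face_normal = [&](const double *a, const double *b, const double *c,
                         double *n) {
    double u[3], w[3];
    for (int d = 0; d < 3; ++d) { u[d] = b[d] - a[d]; w[d] = c[d] - a[d]; }
    n[0] = u[1] * w[2] - u[2] * w[1];
    n[1] = u[2] * w[0] - u[0] * w[2];
    n[2] = u[0] * w[1] - u[1] * w[0];
  };

  std::vector<Quadric> Q(nv);
  std::unordered_map<uint64_t, int> edge_count;
  edge_count.reserve(nf0 * 3);
  auto ek = [](int a, int b) {
    return ((uint64_t)std::min(a, b) << 32) | (uint64_t)std::max(a, b);
  };
  for (int f = 0; f < nf0; ++f) {
    const double *a = &P[3 * Fa[3 * f]], *b = &P[3 * Fa[3 * f + 1]],
                 *c = &P[3 * Fa[3 * f + 2]];
    double n[3];
    face_normal(a, b, c, n);
    double len = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    if (len < 1e-30) continue;
    double area = 0.5 * len;
    for (int d = 0; d < 3; ++d) n[d] /= len;
    double dpl = -(n[0]*a[0] + n[1]*a[1] + n[2]*a[2]);
    for (int e = 0; e < 3; ++e) {
      Q[Fa[3 * f + e]].add_plane(n[0], n[1], n[2], dpl, area);
      edge_count[ek(Fa[3 * f + e], Fa[3 * f + (e + 1) % 3])]++;
    }
  }
  // boundary constraint planes (perpendicular to the face, through the edge)
  for (int f = 0; f < nf0; ++f) {
    for (int e = 0; e < 3; ++e) {
      int a = Fa[3 * f + e], b = Fa[3 * f + (e + 1) % 3];
      if (edge_count[ek(a, b)] != 1) continue;
      int c = Fa[3 * f + (e + 2) % 3];
      double n[3];
      face_normal(&P[3 * a], &P[3 * b], &P[3 * c], n);
      double ed[3] = {P[3*b] - P[3*a], P[3*b+1] - P[3*a+1], P[3*b+2] - P[3*a+2]};
      double cn[3] = {ed[1]*n[2] - ed[2]*n[1], ed[2]*n[0] - ed[0]*n[2],
                      ed[0]*n[1] - ed[1]*n[0]};
      double len = std::sqrt(cn[0]*cn[0] + cn[1]*cn[1] + cn[2]*cn[2]);
      if (len < 1e-30) continue;
      for (int d = 0; d < 3; ++d) cn[d] /= len;
      double dpl = -(cn[0]*P[3*a] + cn[1]*P[3*a+1] + cn[2]*P[3*a+2]);
      double elen2 = ed[0]*ed[0] + ed[1]*ed[1] + ed[2]*ed[2];
      Q[a].add_plane(cn[0], cn[1], cn[2], dpl, 1e3 * elen2);
      Q[b].add_plane(cn[0], cn[1], cn[2], dpl, 1e3 * elen2);
    }
  }

  std::vector<uint64_t> version(nv, 0);
  std::priority_queue<HeapItem> heap;

  auto best_position = [&](int v1, int v2, double *p, double *cost) {
    Quadric Qs = Q[v1];
    Qs.add(Q[v2]);
    double cand[4][3];
    int nc = 0;
    if (Qs.optimal(cand[nc])) ++nc;
    for (int d = 0; d < 3; ++d) cand[nc][d] = P[3 * v1 + d];
    ++nc;
    for (int d = 0; d < 3; ++d) cand[nc][d] = P[3 * v2 + d];
    ++nc;
    for (int d = 0; d < 3; ++d)
      cand[nc][d] = 0.5 * (P[3 * v1 + d] + P[3 * v2 + d]);
    ++nc;
    double bc = R_PosInf;
    for (int i = 0; i < nc; ++i) {
      double c = Qs.eval(cand[i]);
      if (c < bc) { bc = c; for (int d = 0; d < 3; ++d) p[d] = cand[i][d]; }
    }
    *cost = bc;
  };

  auto push_edge = [&](int v1, int v2) {
    if (v1 == v2) return;
    double p[3], cost;
    best_position(v1, v2, p, &cost);
    heap.push(HeapItem{cost, v1, v2, version[v1] + version[v2]});
  };

  for (auto &kv : edge_count) {
    int a = (int)(kv.first >> 32), b = (int)(kv.first & 0xFFFFFFFFULL);
    push_edge(a, b);
  }

  int alive_faces = 0;
  for (int f = 0; f < nf0; ++f) if (face_alive[f]) ++alive_faces;

  auto neighbors = [&](int v, std::unordered_set<int> &out) {
    out.clear();
    for (int f : vfaces[v])
      for (int e = 0; e < 3; ++e)
        if (Fa[3 * f + e] != v) out.insert(Fa[3 * f + e]);
  };

  std::unordered_set<int> n1, n2;
  long guard = 0;
  while (alive_faces > target_faces && !heap.empty()) {
    if (((++guard) & 2047) == 0) Rcpp::checkUserInterrupt();
    HeapItem it = heap.top();
    heap.pop();
    int v1 = it.v1, v2 = it.v2;
    if (!vert_alive[v1] || !vert_alive[v2]) continue;
    if (it.stamp != version[v1] + version[v2]) continue;
    // still an edge?
    std::vector<int> shared;
    for (int f : vfaces[v1])
      if (vfaces[v2].count(f)) shared.push_back(f);
    if (shared.empty()) continue;
    if ((int)shared.size() > 2) continue;  // non-manifold edge: leave it
    // link condition: common neighbours must be exactly the opposite
    // vertices of the shared faces
    neighbors(v1, n1);
    neighbors(v2, n2);
    std::unordered_set<int> opp;
    for (int f : shared)
      for (int e = 0; e < 3; ++e) {
        int w = Fa[3 * f + e];
        if (w != v1 && w != v2) opp.insert(w);
      }
    bool ok = true;
    for (int w : n1)
      if (w != v2 && n2.count(w) && !opp.count(w)) { ok = false; break; }
    if (!ok) continue;
    double p[3], cost;
    best_position(v1, v2, p, &cost);
    // flip / degeneracy check on surviving faces
    double old1[3] = {P[3*v1], P[3*v1+1], P[3*v1+2]};
    double old2[3] = {P[3*v2], P[3*v2+1], P[3*v2+2]};
    for (int pass = 0; pass < 2 && ok; ++pass) {
      int v = pass == 0 ? v1 : v2;
      for (int f : vfaces[v]) {
        bool is_shared = false;
        for (int s : shared) if (s == f) { is_shared = true; break; }
        if (is_shared) continue;
        double A[3][3], B[3][3];
        for (int e = 0; e < 3; ++e) {
          int w = Fa[3 * f + e];
          for (int d = 0; d < 3; ++d) {
            A[e][d] = P[3 * w + d];
            B[e][d] = (w == v1 || w == v2) ? p[d] : P[3 * w + d];
          }
        }
        double na[3], nb[3];
        face_normal(A[0], A[1], A[2], na);
        face_normal(B[0], B[1], B[2], nb);
        double la2 = na[0]*na[0] + na[1]*na[1] + na[2]*na[2];
        double lb2 = nb[0]*nb[0] + nb[1]*nb[1] + nb[2]*nb[2];
        if (lb2 < 1e-24 ||
            (na[0]*nb[0] + na[1]*nb[1] + na[2]*nb[2]) <=
                1e-6 * std::sqrt(la2 * lb2)) {
          ok = false;
          break;
        }
      }
    }
    if (!ok) continue;
    // ---- perform collapse: v2 merges into v1 at p -------------------------
    for (int d = 0; d < 3; ++d) P[3 * v1 + d] = p[d];
    (void)old1; (void)old2;
    Q[v1].add(Q[v2]);
    for (int f : shared) {
      if (!face_alive[f]) continue;
      face_alive[f] = 0;
      --alive_faces;
      for (int e = 0; e < 3; ++e) vfaces[Fa[3 * f + e]].erase(f);
    }
    std::vector<int> move(vfaces[v2].begin(), vfaces[v2].end());
    for (int f : move) {
      for (int e = 0; e < 3; ++e)
        if (Fa[3 * f + e] == v2) Fa[3 * f + e] = v1;
      vfaces[v2].erase(f);
      vfaces[v1].insert(f);
    }
    vert_alive[v2] = 0;
    ++version[v1];
    ++version[v2];
    neighbors(v1, n1);
    for (int w : n1) {
      ++version[w];  // invalidate stale heap entries around the collapse
      push_edge(std::min(v1, w), std::max(v1, w));
    }
    // re-push surviving neighbourhood edges not incident to v1
    for (int f : vfaces[v1])
      for (int e = 0; e < 3; ++e) {
        int a = Fa[3 * f + e], b = Fa[3 * f + (e + 1) % 3];
        if (a != v1 && b != v1) push_edge(std::min(a, b), std::max(a, b));
      }
  }

  // compact output
  std::vector<int> vmap(nv, -1);
  int nvout = 0;
  for (int v = 0; v < nv; ++v)
    if (vert_alive[v] && !vfaces[v].empty()) vmap[v] = nvout++;
  NumericMatrix Vout(nvout, 3);
  for (int v = 0; v < nv; ++v)
    if (vmap[v] >= 0)
      for (int d = 0; d < 3; ++d) Vout(vmap[v], d) = P[3 * v + d];
  int nfout = 0;
  for (int f = 0; f < nf0; ++f) if (face_alive[f]) ++nfout;
  IntegerMatrix Fout(nfout, 3);
  int fi = 0;
  for (int f = 0; f < nf0; ++f) {
    if (!face_alive[f]) continue;
    for (int e = 0; e < 3; ++e) Fout(fi, e) = vmap[Fa[3 * f + e]] + 1;
    ++fi;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout,
                      _["achieved_faces"] = nfout);
}
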