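#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// hash-grid neighbourhood tools for point clouds (uniform cell = radius)

namespace {
struct PGrid {
  double h, mn[3];
  std::unordered_map<uint64_t, std::vector<int> > cells;
  uint64_t key(double x, double y, double z) const {
    int64_t i = (int64_t)std::floor((x - mn[0]) / h);
    int64_t j = (int64_t)std::floor((y - mn[1]) / h);
    int64_t k = (int64_t)std::floor((z - mn[2]) / h);
    return (uint64_t)(i & 0x1FFFFF) | ((uint64_t)(j & 0x1FFFFF) << 21) |
           ((uint64_t)(k & 0x1FFFFF) << 42);
  }
  PGrid(NumericMatrix P, double radius) : h(radius) {
    for (int d = 0; d < 3; ++d) mn[d] = P(0, d);
    for (int i = 0; i < P.nrow(); ++i)
      for (int d = 0; d < 3; ++d) if (P(i, d) < mn[d]) mn[d] = P(i, d);
    for (int i = 0; i < P.nrow(); ++i)
      cells[key(P(i, 0), P(i, 1), P(i, 2))].push_back(i);
  }
};
}  // namespace

// short-range repulsion displacements: for each point, sum (1 - d/radius)
// directions away from neighbours closer than radius, scaled by step.
// [[Rcpp::export]]
NumericMatrix cpp_repulse(NumericMatrix P, double radius, double step) {
  const int n = P.nrow();
  NumericMatrix D(n, 3);
  PGrid g(P, radius);
  for (int i = 0; i < n; ++i) {
    double fx = 0, fy = 0, fz = 0;
    const double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk) {
          auto it = g.cells.find(g.key(px + di * radius, py + dj * radius,
                                       pz + dk * radius));
          if (it == g.cells.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            double dx = px - P(j, 0), dy = py - P(j, 1), dz = pz - P(j, 2);
            double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (d >= radius || d < 1e-12) continue;
            double w = (1.0 - d / radius) / d;
            fx += w * dx; fy += w * dy; fz += w * dz;
          }
        }
    D(i, 0) = step * fx; D(i, 1) = step * fy; D(i, 2) = step * fz;
  }
  return D;
}

// nearest-neighbour distance per point (expanding hash-grid search)
// [[Rcpp::export]]
NumericVector cpp_nn_distance(NumericMatrix P) {
  const int n = P.nrow();
  NumericVector out(n);
  if (n < 2) { if (n == 1) out[0] = R_PosInf; return out; }
  // estimate a radius from the bounding box
  double mn[3], mx[3];
  for (int d = 0; d < 3; ++d) { mn[d] = mx[d] = P(0, d); }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (P(i, d) < mn[d]) mn[d] = P(i, d);
      if (P(i, d) > mx[d]) mx[d] = P(i, d);
    }
  double vol = 1.0;
  for (int d = 0; d < 3; ++d) vol *= std::max(mx[d] - mn[d], 1e-9);
  double h = std::cbrt(vol / n) * 2.0 + 1e-9;
  PGrid g(P, h);
  for (int i = 0; i < n; ++i) {
    const double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    double best = R_PosInf;
    for (int ring = 1; ring <= 64; ++ring) {
      int r = ring - 1;
      for (int di = -r; di <= r; ++di)
        for (int dj = -r; dj <= r; ++dj)
          for (int dk = -r; dk <= r; ++dk) {
            if (std::max(std::abs(di), std::max(std::abs(dj), std::abs(dk)))
                != r) continue;
            auto it = g.cells.find(g.key(px + di * h, py + dj * h,
                                         pz + dk * h));
            if (it == g.cells.end()) continue;
            for (int j : it->second) {
              if (j == i) continue;
              double dx = px - P(j, 0), dy = py - P(j, 1), dz = pz - P(j, 2);
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) best = d2;
            }
          }
      if (std::isfinite(best) && std::sqrt(best) <= (double)r * h) break;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
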