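#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Spatial-hash cell list over one point set. Keys pack the 3 integer cell
// coordinates (offset to stay non-negative) into a single 64-bit value.
namespace {

struct CellList {
  double cell;
  double ox, oy, oz;
  std::unordered_map<int64_t, std::vector<int> > cells;

  static int64_t key(int ix, int iy, int iz) {
    return (static_cast<int64_t>(ix) << 42) |
           (static_cast<int64_t>(iy) << 21) |
            static_cast<int64_t>(iz);
  }

  CellList(const NumericMatrix& pts, double cell_size) : cell(cell_size) {
    ox = oy = oz = R_PosInf;
    const int n = pts.nrow();
    for (int i = 0; i < n; ++i) {
      if (pts(i, 0) < ox) ox = pts(i, 0);
      if (pts(i, 1) < oy) oy = pts(i, 1);
      if (pts(i, 2) < oz) oz = pts(i, 2);
    }
    for (int i = 0; i < n; ++i) {
      int ix = static_cast<int>(std::floor((pts(i, 0) - ox) / cell));
      int iy = static_cast<int>(std::floor((pts(i, 1) - oy) / cell));
      int iz = static_cast<int>(std::floor((pts(i, 2) - oz) / cell));
      cells[key(ix, iy, iz)].push_back(i);
    }
  }

  // visit indices in the 27-cell neighborhood of point p
  template <typename F>
  void neighbors(double px, double py, double pz, F fn) const {
    int ix = static_cast<int>(std::floor((px - ox) / cell));
    int iy = static_cast<int>(std::floor((py - oy) / cell));
    int iz = static_cast<int>(std::floor((pz - oz) / cell));
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
            cells.find(key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (size_t k = 0; k < it->second.size(); ++k) fn(it->second[k]);
        }
  }
};

inline double dist3(const NumericMatrix& a, int i,
                    const NumericMatrix& b, int j) {
  const double dx = a(i, 0) - b(j, 0);
  const double dy = a(i, 1) - b(j, 1);
  const double dz = a(i, 2) - b(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

} // namespace

// All cross pairs (i in a, j in b) with distance strictly below cutoff.
// Returns 1-based indices plus the distance. Cost ~ O(n + m + pairs).
// [[Rcpp::export]]
DataFrame cpp_pairs_within(NumericMatrix a, NumericMatrix b, double cutoff) {
  CellList cl(b, cutoff);
  std::vector<int> ia, jb;
  std::vector<double> dd;
  const int n = a.nrow();
  for (int i = 0; i < n; ++i) {
    const double px = a(i, 0), py = a(i, 1), pz = a(i, 2);
    cl.neighbors(px, py, pz, [&](int j) {
      double d = dist3(a, i, b, j);
      if (d < cutoff) {
        ia.push_back(i + 1);
        jb.push_back(j + 1);
        dd.push_back(d);
      }
    });
  }
  return DataFrame::create(_["i"] = ia, _["j"] = jb, _["dist"] = dd);
}

// Minimum cross-set distance. A coarse upper bound from a strided scan
// fixes the cell size, after which one grid pass finds the true minimum.
// [[Rcpp::export]]
NumericVector cpp_min_pairwise(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  double best = R_PosInf;
  int bi = 0, bj = 0;
  const int stride = std::max(1, n / 32);
  for (int i = 0; i < n; i += stride) {
    for (int j = 0; j < m; ++j) {
      double d = dist3(a, i, b, j);
      if (d < best) { best = d; bi = i; bj = j; }
    }
  }
  if (best > 0) {
    CellList cl(b, best);
    for (int i = 0; i < n; ++i) {
      cl.neighbors(a(i, 0), a(i, 1), a(i, 2), [&](int j) {
        double d = dist3(a, i, b, j);
        if (d < best) { best = d; bi = i; bj = j; }
      });
    }
  }
  return NumericVector::create(_["i"] = bi + 1, _["j"] = bj + 1,
                               _["dist"] = best);
}

// Shrake-Rupley accessible surface area. Sample points come from the
// deterministic golden-spiral construction; a point is occluded only if
// strictly inside a neighbor's probe-expanded sphere, so exactly coincident
// spheres do not occlude each other.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector area(n);

  // unit sphere points, golden spiral
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    sx[k] = r * std::cos(phi);
    sy[k] = r * std::sin(phi);
    sz[k] = z;
  }

  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  const double reach = 2.0 * rmax + 2.0 * probe;
  CellList cl(coords, std::max(reach, 1e-6));

  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    std::vector<int> nb;
    cl.neighbors(coords(i, 0), coords(i, 1), coords(i, 2), [&](int j) {
      if (j == i) return;
      double d = dist3(coords, i, coords, j);
      if (d < ri + radii[j] + probe) nb.push_back(j);
    });
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      const double px = coords(i, 0) + ri * sx[k];
      const double py = coords(i, 1) + ri * sy[k];
      const double pz = coords(i, 2) + ri * sz[k];
      bool occluded = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = px - coords(j, 0);
        const double dy = py - coords(j, 1);
        const double dz = pz - coords(j, 2);
        const double rj = radii[j] + probe;
        // strict interiority with a relative guard so points lying on a
        // neighbor's surface (e.g. exactly coincident spheres) stay exposed
        if (dx * dx + dy * dy + dz * dz < rj * rj * (1.0 - 1e-10)) {
          occluded = true;
          break;
        }
      }
      if (!occluded) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri * ri * exposed / n_points;
  }
  return area;
}
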