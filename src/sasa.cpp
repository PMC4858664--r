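// Shrake-Rupley solvent accessible surface area with a deterministic
// golden-spiral point lattice.  Exposed to R via sasa_cpp(); neighbour
// search is a simple cutoff prefilter (adequate at the few-hundred-atom
// scale this package works at).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector area(n);
  if (n == 0) return area;

  // golden-spiral unit sphere lattice (deterministic for fixed n_points)
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }

  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  std::vector<int> neigh;
  neigh.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double ri = er[i];
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    neigh.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - xi;
      const double dy = coords(j, 1) - yi;
      const double dz = coords(j, 2) - zi;
      const double lim = ri + er[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) neigh.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      const double qx = xi + ri * px[k];
      const double qy = yi + ri * py[k];
      const double qz = zi + ri * pz[k];
      bool occluded = false;
      for (size_t m = 0; m < neigh.size(); ++m) {
        const int j = neigh[m];
        const double dx = qx - coords(j, 0);
        const double dy = qy - coords(j, 1);
        const double dz = qz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) {
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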