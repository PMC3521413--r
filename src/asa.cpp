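#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley accessible surface area: deterministic golden-spiral point
// set on each atom's solvent-expanded sphere, occlusion tested against
// neighbouring atoms' expanded spheres.

// [[Rcpp::export(name = ".shrake_rupley_cpp")]]
NumericVector shrake_rupley_cpp(NumericMatrix coords, NumericVector radii,
                                double probe, int n_points) {
  const int n = coords.nrow();
  if (n < 1) stop("need at least one atom");
  if (n_points < 1) stop("n_points must be positive");

  // deterministic golden-spiral unit sphere points
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

  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  NumericVector asa(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j,0)-coords(i,0);
      double dy = coords(j,1)-coords(i,1);
      double dz = coords(j,2)-coords(i,2);
      double lim = R[i] + R[j];
      if (dx*dx + dy*dy + dz*dz < lim*lim) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = coords(i,0) + R[i] * sx[k];
      double py = coords(i,1) + R[i] * sy[k];
      double pz = coords(i,2) + R[i] * sz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = px - coords(j,0);
        double dy = py - coords(j,1);
        double dz = pz - coords(j,2);
        if (dx*dx + dy*dy + dz*dz < R[j]*R[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    asa[i] = 4.0 * M_PI * R[i] * R[i] * ((double)acc / n_points);
  }
  return asa;
}
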