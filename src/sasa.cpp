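#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
// Test points are placed on a deterministic golden-spiral lattice on each
// atom's expanded sphere (r_vdw + probe); a point is buried if it falls
// inside any neighbour's expanded sphere. Per-atom SASA =
// (exposed points / total points) * 4 * pi * (r_vdw + probe)^2.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       double probe, int npoints) {
  const int n = xyz.nrow();
  const double GA = M_PI * (3.0 - std::sqrt(5.0));  // golden angle
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  for (int k = 0; k < npoints; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / npoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = GA * k;
    px[k] = r * std::cos(phi);
    py[k] = r * std::sin(phi);
    pz[k] = z;
  }
  NumericVector out(n);
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double Ri = radii[i] + probe;
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      double dz = xyz(j, 2) - xyz(i, 2);
      double cut = Ri + radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < cut * cut) nbr.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < npoints; ++k) {
      double tx = xyz(i, 0) + Ri * px[k];
      double ty = xyz(i, 1) + Ri * py[k];
      double tz = xyz(i, 2) + Ri * pz[k];
      bool free_pt = true;
      for (size_t q = 0; q < nbr.size(); ++q) {
        int j = nbr[q];
        double Rj = radii[j] + probe;
        double dx = tx - xyz(j, 0);
        double dy = ty - xyz(j, 1);
        double dz = tz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { free_pt = false; break; }
      }
      if (free_pt) ++exposed;
    }
    out[i] = (double)exposed / npoints * 4.0 * M_PI * Ri * Ri;
  }
  return out;
}
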