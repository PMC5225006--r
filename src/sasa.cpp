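#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley accessible surface area.
// coords: n x 3, radii: vdW radii per atom, probe: probe radius,
// sphere: m x 3 unit vectors (deterministic lattice, shared by all atoms).
// Each atom's lattice is rotated into a local frame built from its two
// nearest neighbours, so the test points co-rotate with the structure and
// the computed areas are exactly invariant under rigid-body motion (the
// per-residue exposure-change signal then carries no rotational noise).
// An atom's test point is exposed when it lies outside every neighbour's
// expanded sphere (r_j + probe). Neighbour search is cut off at
// r_i + r_j + 2*probe.
// [[Rcpp::export]]
NumericVector sasa_kernel(NumericMatrix coords, NumericVector radii,
                          double probe, NumericMatrix sphere) {
  const int n = coords.nrow();
  const int m = sphere.nrow();
  NumericVector area(n);
  std::vector<int> nbr;
  nbr.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    nbr.clear();
    int j1 = -1, j2 = -1;          // two nearest neighbours
    double d1 = R_PosInf, d2 = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double cut = ri + radii[j] + probe;
      const double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
                   dz = coords(j, 2) - zi;
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < cut * cut) nbr.push_back(j);
      if (dd < d1) { d2 = d1; j2 = j1; d1 = dd; j1 = j; }
      else if (dd < d2) { d2 = dd; j2 = j; }
    }
    // local frame: e1 toward the nearest neighbour, e2 from the nearest
    // atom that is not collinear with e1 (searched outward by distance);
    // isolated atoms keep the lab frame (no occlusion, area exact) and a
    // fully collinear environment keeps an axis-symmetric completion
    double e1[3] = {1, 0, 0}, e2[3] = {0, 1, 0}, e3[3] = {0, 0, 1};
    if (j1 >= 0) {
      double v1[3] = {coords(j1, 0) - xi, coords(j1, 1) - yi,
                      coords(j1, 2) - zi};
      double nv = std::sqrt(v1[0] * v1[0] + v1[1] * v1[1] + v1[2] * v1[2]);
      for (int a = 0; a < 3; ++a) e1[a] = v1[a] / nv;
      // order all other atoms by distance, take the first non-collinear
      std::vector<std::pair<double, int> > byd;
      byd.reserve(n - 1);
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
                     dz = coords(j, 2) - zi;
        byd.push_back(std::make_pair(dx * dx + dy * dy + dz * dz, j));
      }
      std::sort(byd.begin(), byd.end());
      bool have_e2 = false;
      for (size_t q = 0; q < byd.size() && !have_e2; ++q) {
        const int j = byd[q].second;
        double v2[3] = {coords(j, 0) - xi, coords(j, 1) - yi,
                        coords(j, 2) - zi};
        double dot = v2[0] * e1[0] + v2[1] * e1[1] + v2[2] * e1[2];
        double w[3] = {v2[0] - dot * e1[0], v2[1] - dot * e1[1],
                       v2[2] - dot * e1[2]};
        double nw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
        if (nw > 0.05 * std::sqrt(byd[q].first)) {  // > ~3 deg off-axis
          for (int a = 0; a < 3; ++a) e2[a] = w[a] / nw;
          have_e2 = true;
        }
      }
      if (!have_e2) {
        int s = (std::fabs(e1[0]) < 0.9) ? 0 : 1;
        double axis[3] = {0, 0, 0};
        axis[s] = 1.0;
        double dot = axis[0] * e1[0] + axis[1] * e1[1] + axis[2] * e1[2];
        double w[3] = {axis[0] - dot * e1[0], axis[1] - dot * e1[1],
                       axis[2] - dot * e1[2]};
        double nw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
        for (int a = 0; a < 3; ++a) e2[a] = w[a] / nw;
      }
      e3[0] = e1[1] * e2[2] - e1[2] * e2[1];
      e3[1] = e1[2] * e2[0] - e1[0] * e2[2];
      e3[2] = e1[0] * e2[1] - e1[1] * e2[0];
    }
    int exposed = 0;
    for (int k = 0; k < m; ++k) {
      const double sx = sphere(k, 0), sy = sphere(k, 1), sz = sphere(k, 2);
      const double px = xi + ri * (sx * e1[0] + sy * e2[0] + sz * e3[0]);
      const double py = yi + ri * (sx * e1[1] + sy * e2[1] + sz * e3[1]);
      const double pz = zi + ri * (sx * e1[2] + sy * e2[2] + sz * e3[2]);
      bool free_pt = true;
      for (size_t q = 0; q < nbr.size(); ++q) {
        const int j = nbr[q];
        const double rj = radii[j] + probe;
        const double dx = px - coords(j, 0), dy = py - coords(j, 1),
                     dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++exposed;
    }
    area[i] = (4.0 * M_PI * ri * ri) * exposed / m;
  }
  return area;
}
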