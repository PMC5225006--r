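#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Label grid cells as protein (1) when the cell centre lies within
// radius[i] of atom i (radius already includes the probe). labels are 0
// (solvent) on input.
// [[Rcpp::export]]
IntegerVector grid_mark_protein(IntegerVector dims, NumericVector origin,
                                double spacing, NumericMatrix coords,
                                NumericVector radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(nx * ny * nz, 0);
  for (int a = 0; a < coords.nrow(); ++a) {
    const double r = radius[a], r2 = r * r;
    const double x = coords(a, 0), y = coords(a, 1), z = coords(a, 2);
    int i0 = std::max(0, (int)std::floor((x - r - origin[0]) / spacing));
    int i1 = std::min(nx - 1, (int)std::ceil((x + r - origin[0]) / spacing));
    int j0 = std::max(0, (int)std::floor((y - r - origin[1]) / spacing));
    int j1 = std::min(ny - 1, (int)std::ceil((y + r - origin[1]) / spacing));
    int k0 = std::max(0, (int)std::floor((z - r - origin[2]) / spacing));
    int k1 = std::min(nz - 1, (int)std::ceil((z + r - origin[2]) / spacing));
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing - z;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing - y;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing - x;
          if (dx * dx + dy * dy + dz * dz <= r2)
            lab[i + nx * (j + (long)ny * k)] = 1;
        }
      }
    }
  }
  return lab;
}

// LIGSITE-style protein-solvent-protein scan. For each solvent cell,
// count in how many of the 7 scan directions (x, y, z and the 4 cube
// diagonals) the line through the cell hits protein on BOTH sides. Cells
// with count >= min_psp become pocket (2).
// [[Rcpp::export]]
IntegerVector psp_scan_kernel(IntegerVector lab, IntegerVector dims,
                              int min_psp) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int dirs[7][3] = {{1,0,0},{0,1,0},{0,0,1},
                          {1,1,1},{1,1,-1},{1,-1,1},{-1,1,1}};
  IntegerVector out = clone(lab);
  auto at = [&](int i, int j, int k) {
    return lab[i + nx * (j + (long)ny * k)];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (at(i, j, k) != 0) continue;
        int npsp = 0;
        for (int d = 0; d < 7 && npsp < min_psp; ++d) {
          bool hit_plus = false, hit_minus = false;
          int ii = i + dirs[d][0], jj = j + dirs[d][1], kk = k + dirs[d][2];
          while (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz) {
            if (at(ii, jj, kk) == 1) { hit_plus = true; break; }
            ii += dirs[d][0]; jj += dirs[d][1]; kk += dirs[d][2];
          }
          if (!hit_plus) continue;
          ii = i - dirs[d][0]; jj = j - dirs[d][1]; kk = k - dirs[d][2];
          while (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz) {
            if (at(ii, jj, kk) == 1) { hit_minus = true; break; }
            ii -= dirs[d][0]; jj -= dirs[d][1]; kk -= dirs[d][2];
          }
          if (hit_minus) ++npsp;
        }
        if (npsp >= min_psp) out[i + nx * (j + (long)ny * k)] = 2;
      }
  return out;
}

// Face-connected (6-neighbour) components of pocket cells (label 2).
// Returns component id per cell (0 = not pocket).
// [[Rcpp::export]]
IntegerVector pocket_components(IntegerVector lab, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  IntegerVector comp(n, 0);
  int next_id = 0;
  const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  std::queue<long> q;
  for (long s = 0; s < n; ++s) {
    if (lab[s] != 2 || comp[s] != 0) continue;
    comp[s] = ++next_id;
    q.push(s);
    while (!q.empty()) {
      long c = q.front(); q.pop();
      int i = c % nx, j = (c / nx) % ny, k = c / ((long)nx * ny);
      for (int d = 0; d < 6; ++d) {
        int ii = i + step[d][0], jj = j + step[d][1], kk = k + step[d][2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        long t = ii + nx * (jj + (long)ny * kk);
        if (lab[t] == 2 && comp[t] == 0) { comp[t] = next_id; q.push(t); }
      }
    }
  }
  return comp;
}
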