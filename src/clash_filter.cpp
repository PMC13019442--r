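#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Uniform cell grid over receptor atoms, cell edge = max cutoff. A ligand
// atom can only violate a cutoff against receptor atoms in its own or the
// 26 neighboring cells, so each pose test touches a constant-size
// neighborhood instead of all receptor atoms.

static inline std::int64_t cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices
  const std::int64_t B = 1 << 20;
  return ((std::int64_t)(ix + B) << 42) | ((std::int64_t)(iy + B) << 21) |
         (std::int64_t)(iz + B);
}

// receptor: P x 3; poses: (B*L) x 3 stacked pose blocks; cutoffs: P x L.
// Returns logical vector length B: TRUE when the pose is clash-free
// (d_ij >= c_ij for all pairs with c_ij > 0).
// [[Rcpp::export(name = ".clash_filter_poses_cpp")]]
LogicalVector clash_filter_poses_cpp(NumericMatrix receptor,
                                     NumericMatrix poses,
                                     NumericMatrix cutoffs,
                                     int n_ligand_atoms) {
  const int P = receptor.nrow();
  const int L = n_ligand_atoms;
  if (cutoffs.nrow() != P || cutoffs.ncol() != L)
    stop("cutoff matrix shape does not match atom counts");
  if (poses.nrow() % L != 0)
    stop("pose block size is not a multiple of the ligand atom count");
  const int B = poses.nrow() / L;

  double cmax = 0.0;
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < L; ++j)
      if (cutoffs(i, j) > cmax) cmax = cutoffs(i, j);

  LogicalVector ok(B);
  if (cmax <= 0.0) {  // no interacting pairs: everything passes
    for (int b = 0; b < B; ++b) ok[b] = true;
    return ok;
  }
  const double cell = cmax;
  const double cmax2 = cmax * cmax;

  std::unordered_map<std::int64_t, std::vector<int> > grid;
  grid.reserve(P * 2);
  for (int i = 0; i < P; ++i) {
    int ix = (int)std::floor(receptor(i, 0) / cell);
    int iy = (int)std::floor(receptor(i, 1) / cell);
    int iz = (int)std::floor(receptor(i, 2) / cell);
    grid[cell_key(ix, iy, iz)].push_back(i);
  }

  for (int b = 0; b < B; ++b) {
    bool pass = true;
    const int off = b * L;
    for (int j = 0; j < L && pass; ++j) {
      const double x = poses(off + j, 0);
      const double y = poses(off + j, 1);
      const double z = poses(off + j, 2);
      const int ix = (int)std::floor(x / cell);
      const int iy = (int)std::floor(y / cell);
      const int iz = (int)std::floor(z / cell);
      for (int dx = -1; dx <= 1 && pass; ++dx)
        for (int dy = -1; dy <= 1 && pass; ++dy)
          for (int dz = -1; dz <= 1 && pass; ++dz) {
            auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
            if (it == grid.end()) continue;
            for (int i : it->second) {
              const double ddx = receptor(i, 0) - x;
              const double ddy = receptor(i, 1) - y;
              const double ddz = receptor(i, 2) - z;
              const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 >= cmax2) continue;
              const double c = cutoffs(i, j);
              if (c > 0.0 && d2 < c * c) { pass = false; break; }
            }
          }
    }
    ok[b] = pass;
  }
  return ok;
}
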