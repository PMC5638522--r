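#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cell-list contact counting: atoms of B are binned into cubic cells of edge
// `cutoff`; for each atom of A only the 27 neighbouring cells are scanned.
// Contacts are strict (< cutoff), matching the documented convention.

static inline long long cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices into one 64-bit key
  const long long off = 1 << 20;
  return (((long long)(ix + off)) << 42) | (((long long)(iy + off)) << 21) |
         ((long long)(iz + off));
}

// [[Rcpp::export(name = ".cpp_count_contacts")]]
double cpp_count_contacts(NumericMatrix A, NumericMatrix B, double cutoff) {
  const double c2 = cutoff * cutoff;
  const int nb = B.nrow(), na = A.nrow();
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(nb * 2);
  for (int j = 0; j < nb; ++j) {
    int ix = (int)std::floor(B(j, 0) / cutoff);
    int iy = (int)std::floor(B(j, 1) / cutoff);
    int iz = (int)std::floor(B(j, 2) / cutoff);
    grid[cell_key(ix, iy, iz)].push_back(j);
  }
  double count = 0;
  for (int i = 0; i < na; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    int ix = (int)std::floor(ax / cutoff);
    int iy = (int)std::floor(ay / cutoff);
    int iz = (int)std::floor(az / cutoff);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
            grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          const std::vector<int>& cell = it->second;
          for (size_t k = 0; k < cell.size(); ++k) {
            int j = cell[k];
            double ddx = ax - B(j, 0), ddy = ay - B(j, 1), ddz = az - B(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < c2) count += 1;
          }
        }
  }
  return count;
}

// [[Rcpp::export(name = ".cpp_any_contact")]]
bool cpp_any_contact(NumericMatrix A, NumericMatrix B, double cutoff) {
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < A.nrow(); ++i)
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
             dz = A(i, 2) - B(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) return true;
    }
  return false;
}

// [[Rcpp::export(name = ".cpp_min_dist")]]
double cpp_min_dist(NumericMatrix A, NumericMatrix B) {
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i)
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
             dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}
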