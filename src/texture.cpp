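#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// The 13 unique 3D lattice directions at Chebyshev distance 1 (one per
// +/- pair).
static const int NDIR = 13;
static const int DIRS[NDIR][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int lin_index(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Directed co-occurrence counts at displacement +dir; the R side
// symmetrizes (adds the transpose) and normalizes. levels holds gray
// levels 1..d with 0 outside the mask. Returns a d x d x 13 array.
// [[Rcpp::export]]
NumericVector glcm_pair_counts_cpp(IntegerVector levels, IntegerVector dim,
                                   int d) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(static_cast<R_xlen_t>(d) * d * NDIR);
  for (int dir = 0; dir < NDIR; ++dir) {
    const int ox = DIRS[dir][0], oy = DIRS[dir][1], oz = DIRS[dir][2];
    const R_xlen_t base = static_cast<R_xlen_t>(d) * d * dir;
    for (int z = 0; z < nz; ++z) {
      const int z2 = z + oz;
      if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        const int y2 = y + oy;
        if (y2 < 0 || y2 >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          const int x2 = x + ox;
          if (x2 < 0 || x2 >= nx) continue;
          const int g1 = levels[lin_index(x, y, z, nx, ny)];
          if (g1 == 0) continue;
          const int g2 = levels[lin_index(x2, y2, z2, nx, ny)];
          if (g2 == 0) continue;
          out[base + (g1 - 1) + static_cast<R_xlen_t>(d) * (g2 - 1)] += 1.0;
        }
      }
    }
  }
  return out;
}

// Maximal same-level runs confined to the mask, per direction.
// Returns a d x Lmax x 13 array of run counts, Lmax = max grid extent.
// [[Rcpp::export]]
NumericVector glrlm_run_counts_cpp(IntegerVector levels, IntegerVector dim,
                                   int d) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int lmax = std::max(nx, std::max(ny, nz));
  NumericVector out(static_cast<R_xlen_t>(d) * lmax * NDIR);
  for (int dir = 0; dir < NDIR; ++dir) {
    const int ox = DIRS[dir][0], oy = DIRS[dir][1], oz = DIRS[dir][2];
    const R_xlen_t base = static_cast<R_xlen_t>(d) * lmax * dir;
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const int g = levels[lin_index(x, y, z, nx, ny)];
          if (g == 0) continue;
          // run start: predecessor along -dir is outside grid/mask or
          // holds a different level
          const int xp = x - ox, yp = y - oy, zp = z - oz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              levels[lin_index(xp, yp, zp, nx, ny)] == g)
            continue;
          int len = 1;
          int xc = x + ox, yc = y + oy, zc = z + oz;
          while (xc >= 0 && xc < nx && yc >= 0 && yc < ny &&
                 zc >= 0 && zc < nz &&
                 levels[lin_index(xc, yc, zc, nx, ny)] == g) {
            ++len;
            xc += ox; yc += oy; zc += oz;
          }
          out[base + (g - 1) + static_cast<R_xlen_t>(d) * (len - 1)] += 1.0;
        }
      }
    }
  }
  return out;
}

// 26-connected zones of equal level within the mask. Returns a two-column
// matrix (level, size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix glszm_zones_cpp(IntegerVector levels, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zone_level, zone_size, stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (seen[start] || levels[start] == 0) continue;
    const int g = levels[start];
    int size = 0;
    stack.clear();
    stack.push_back(static_cast<int>(start));
    seen[start] = 1;
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      ++size;
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int oz = -1; oz <= 1; ++oz) {
        const int z2 = z + oz;
        if (z2 < 0 || z2 >= nz) continue;
        for (int oy = -1; oy <= 1; ++oy) {
          const int y2 = y + oy;
          if (y2 < 0 || y2 >= ny) continue;
          for (int ox = -1; ox <= 1; ++ox) {
            if (ox == 0 && oy == 0 && oz == 0) continue;
            const int x2 = x + ox;
            if (x2 < 0 || x2 >= nx) continue;
            const int w = lin_index(x2, y2, z2, nx, ny);
            if (!seen[w] && levels[w] == g) {
              seen[w] = 1;
              stack.push_back(w);
            }
          }
        }
      }
    }
    zone_level.push_back(g);
    zone_size.push_back(size);
  }
  IntegerMatrix out(zone_level.size(), 2);
  for (size_t i = 0; i < zone_level.size(); ++i) {
    out(i, 0) = zone_level[i];
    out(i, 1) = zone_size[i];
  }
  return out;
}

// Per-level occurrence counts n_i and neighborhood-difference sums
// s_i = sum over voxels of level i of |i - mean(26-neighborhood levels)|,
// neighborhoods restricted to in-mask voxels. Voxels with no in-mask
// neighbor are excluded (n_valid counts the rest).
// [[Rcpp::export]]
List ngtdm_stats_cpp(IntegerVector levels, IntegerVector dim, int d) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector n_i(d), s_i(d);
  double n_valid = 0;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int g = levels[lin_index(x, y, z, nx, ny)];
        if (g == 0) continue;
        double sum = 0;
        int cnt = 0;
        for (int oz = -1; oz <= 1; ++oz) {
          const int z2 = z + oz;
          if (z2 < 0 || z2 >= nz) continue;
          for (int oy = -1; oy <= 1; ++oy) {
            const int y2 = y + oy;
            if (y2 < 0 || y2 >= ny) continue;
            for (int ox = -1; ox <= 1; ++ox) {
              if (ox == 0 && oy == 0 && oz == 0) continue;
              const int x2 = x + ox;
              if (x2 < 0 || x2 >= nx) continue;
              const int g2 = levels[lin_index(x2, y2, z2, nx, ny)];
              if (g2 == 0) continue;
              sum += g2;
              ++cnt;
            }
          }
        }
        if (cnt == 0) continue;
        n_valid += 1;
        n_i[g - 1] += 1;
        s_i[g - 1] += std::fabs(g - sum / cnt);
      }
    }
  }
  return List::create(_["n"] = n_i, _["s"] = s_i, _["n_valid"] = n_valid);
}
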