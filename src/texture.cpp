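#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 13 unique 3D direction offsets at distance 1 (one per +/- pair).
static const int OFF[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// lev: nx*ny*nz integer vector, 0 = outside mask, 1..ng inside.

// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix M(ng, ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int g = lev[lin(x, y, z, nx, ny)];
        if (!g) continue;
        for (int d = 0; d < 13; ++d) {
          int x2 = x + OFF[d][0], y2 = y + OFF[d][1], z2 = z + OFF[d][2];
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int h = lev[lin(x2, y2, z2, nx, ny)];
          if (!h) continue;
          M(g - 1, h - 1) += 1.0;
          M(h - 1, g - 1) += 1.0;
        }
      }
  return M;
}

// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int rmax = std::max(nx, std::max(ny, nz));
  NumericMatrix M(ng, rmax);
  for (int d = 0; d < 13; ++d) {
    int dx = OFF[d][0], dy = OFF[d][1], dz = OFF[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int g = lev[lin(x, y, z, nx, ny)];
          if (!g) continue;
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz
              && lev[lin(xp, yp, zp, nx, ny)] == g)
            continue; // not a run start
          int r = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (xn >= 0 && xn < nx && yn >= 0 && yn < ny && zn >= 0 &&
                 zn < nz && lev[lin(xn, yn, zn, nx, ny)] == g) {
            ++r;
            xn += dx; yn += dy; zn += dz;
          }
          M(g - 1, r - 1) += 1.0;
        }
  }
  return M;
}

// Zones: 26-connected components of constant level. Returns a matrix
// with one row per zone: (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector lev, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zlev, zsize, stack;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || lev[start] == 0) continue;
    int g = lev[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                z2 >= nz)
              continue;
            int w = lin(x2, y2, z2, nx, ny);
            if (!seen[w] && lev[w] == g) {
              seen[w] = 1;
              stack.push_back(w);
            }
          }
    }
    zlev.push_back(g);
    zsize.push_back(size);
  }
  IntegerMatrix Z(zlev.size(), 2);
  for (size_t i = 0; i < zlev.size(); ++i) {
    Z(i, 0) = zlev[i];
    Z(i, 1) = zsize[i];
  }
  return Z;
}

// Neighborhood gray-tone differences: for each in-mask voxel with at
// least one in-mask 26-neighbor, accumulate |level - neighborhood mean|
// into s[level] and count the voxel in N[level].
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector s(ng), N(ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int g = lev[lin(x, y, z, nx, ny)];
        if (!g) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              int h = lev[lin(x2, y2, z2, nx, ny)];
              if (h) {
                sum += h;
                ++cnt;
              }
            }
        if (cnt > 0) {
          s[g - 1] += std::fabs(g - sum / cnt);
          N[g - 1] += 1.0;
        }
      }
  return List::create(Named("s") = s, Named("N") = N);
}
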