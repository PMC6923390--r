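#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gray-level matrix builders for 3D quantized ROIs. Conventions:
//  - `levels` is a 3D integer array (column-major, dims nx*ny*nz) with 0
//    outside the ROI and values 1..ng inside.
//  - 13 unique direction vectors (26-neighborhood up to sign) for GLCM and
//    GLRLM; full 26-neighborhood for GLSZM zones, NGLDM and NGTDM.
//  - Counts are returned unnormalized except the GLCM, which is
//    symmetrized and normalized to unit mass.

static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix m(ng, ng);
  double total = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        for (int d = 0; d < 13; ++d) {
          const int xx = x + DIR13[d][0], yy = y + DIR13[d][1], zz = z + DIR13[d][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          const int lj = levels[idx3(xx, yy, zz, nx, ny)];
          if (lj == 0) continue;
          m(li - 1, lj - 1) += 1.0;
          m(lj - 1, li - 1) += 1.0;
          total += 2.0;
        }
      }
  if (total > 0) {
    for (int i = 0; i < ng; ++i)
      for (int j = 0; j < ng; ++j) m(i, j) /= total;
  }
  return m;
}

// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int maxlen = std::max(nx, std::max(ny, nz));
  NumericMatrix m(ng, maxlen);
  int longest = 1;
  for (int d = 0; d < 13; ++d) {
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int li = levels[idx3(x, y, z, nx, ny)];
          if (li == 0) continue;
          // run start: predecessor out of bounds, outside ROI, or other level
          const int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz &&
              levels[idx3(px, py, pz, nx, ny)] == li) continue;
          int len = 1;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          while (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz &&
                 levels[idx3(xx, yy, zz, nx, ny)] == li) {
            ++len; xx += dx; yy += dy; zz += dz;
          }
          m(li - 1, len - 1) += 1.0;
          if (len > longest) longest = len;
        }
  }
  return m(Range(0, ng - 1), Range(0, longest - 1));
}

// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<char> visited(n, 0);
  std::vector<int> stack;
  std::vector<std::pair<int,int> > zones; // (level, size)
  int largest = 1;
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        const int start = idx3(x0, y0, z0, nx, ny);
        const int li = levels[start];
        if (li == 0 || visited[start]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(start);
        visited[start] = 1;
        while (!stack.empty()) {
          const int cur = stack.back(); stack.pop_back();
          ++size;
          const int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                const int xx = cx + dx, yy = cy + dy, zz = cz + dz;
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
                const int nb = idx3(xx, yy, zz, nx, ny);
                if (!visited[nb] && levels[nb] == li) {
                  visited[nb] = 1;
                  stack.push_back(nb);
                }
              }
        }
        zones.push_back(std::make_pair(li, size));
        if (size > largest) largest = size;
      }
  NumericMatrix m(ng, largest);
  for (size_t k = 0; k < zones.size(); ++k)
    m(zones[k].first - 1, zones[k].second - 1) += 1.0;
  return m;
}

// [[Rcpp::export]]
NumericMatrix cpp_ngldm(IntegerVector levels, IntegerVector dim, int ng, int alpha) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix m(ng, 27); // dependence count k in 0..26 -> column k+1
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
              const int lj = levels[idx3(xx, yy, zz, nx, ny)];
              if (lj != 0 && std::abs(lj - li) <= alpha) ++k;
            }
        m(li - 1, k) += 1.0;
      }
  return m;
}

// Returns an ng x 2 matrix: column 1 the voxel counts n_i (restricted to
// voxels with at least one in-ROI neighbor), column 2 the summed absolute
// deviations s_i from the neighborhood mean level.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix m(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
              const int lj = levels[idx3(xx, yy, zz, nx, ny)];
              if (lj != 0) { sum += lj; ++cnt; }
            }
        if (cnt == 0) continue; // no valid neighborhood: voxel excluded
        m(li - 1, 0) += 1.0;
        m(li - 1, 1) += std::fabs((double)li - sum / cnt);
      }
  return m;
}
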