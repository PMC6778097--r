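// Low-level 3D image kernels: median filtering, squared Euclidean distance
// transform, separable convolution, region growing, trilinear resampling,
// 2D component labelling and tube rasterization. All volumes are passed as
// numeric vectors in R's column-major (x fastest) layout with dims (nx,ny,nz).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dims, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = k / 2;
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((size_t)k * k * k);
  const size_t m = (size_t)k * k * k;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        buf.clear();
        for (int dz = -r; dz <= r; ++dz) {
          const int zz = clampi(z + dz, 0, nz - 1);
          for (int dy = -r; dy <= r; ++dy) {
            const int yy = clampi(y + dy, 0, ny - 1);
            const size_t base = (size_t)zz * nx * ny + (size_t)yy * nx;
            for (int dx = -r; dx <= r; ++dx) {
              const int xx = clampi(x + dx, 0, nx - 1);
              buf.push_back(vol[base + xx]);
            }
          }
        }
        // median of k^3 values (k odd -> middle element after partial sort)
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        double med = buf[m / 2];
        if (m % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m / 2 - 1,
                           buf.begin() + m / 2);
          med = 0.5 * (med + buf[m / 2 - 1]);
        }
        out[(size_t)z * nx * ny + (size_t)y * nx + x] = med;
      }
    }
  }
  return out;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& zb) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from every voxel to the nearest
// foreground (nonzero) voxel. Voxels with no foreground anywhere -> Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e18;
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = mask[i] ? 0.0 : INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const size_t base = (size_t)z * nx * ny + (size_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      f.resize(nx); d.resize(nx);
      edt1d(f, d, v, zb);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
      f.resize(nmax); d.resize(nmax);
    }
  // along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const size_t base = (size_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (size_t)y * nx];
      f.resize(ny); d.resize(ny);
      edt1d(f, d, v, zb);
      for (int y = 0; y < ny; ++y) out[base + (size_t)y * nx] = d[y];
      f.resize(nmax); d.resize(nmax);
    }
  // along z
  const size_t nxy = (size_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const size_t base = (size_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (size_t)z * nxy];
      f.resize(nz); d.resize(nz);
      edt1d(f, d, v, zb);
      for (int z = 0; z < nz; ++z) out[base + (size_t)z * nxy] = d[z];
      f.resize(nmax); d.resize(nmax);
    }
  return out;
}

// Separable convolution along one axis (0=x,1=y,2=z) with an odd-length
// kernel; borders replicate the edge sample.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kl = kernel.size();
  const int r = kl / 2;
  NumericVector out(vol.size());
  const size_t nxy = (size_t)nx * ny;
  const int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)nx : nxy;
  std::vector<double> line(n);
  const int n1 = (axis == 0) ? ny : nx;
  const int n2 = (axis == 2) ? ny : nz;
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      size_t base;
      if (axis == 0) base = (size_t)b * nxy + (size_t)a * nx;
      else if (axis == 1) base = (size_t)b * nxy + a;
      else base = (size_t)b * nx + a;
      for (int i = 0; i < n; ++i) line[i] = vol[base + (size_t)i * stride];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j)
          acc += kernel[j + r] * line[clampi(i + j, 0, n - 1)];
        out[base + (size_t)i * stride] = acc;
      }
    }
  }
  return out;
}

// 26-connected region growing from seed voxels (1-based coordinates) through
// voxels with |intensity - ref| <= tol.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dims,
                              IntegerMatrix seeds, double ref, double tol) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nxy = (size_t)nx * ny;
  LogicalVector out(vol.size());
  std::queue<size_t> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    const int x = seeds(s, 0) - 1, y = seeds(s, 1) - 1, z = seeds(s, 2) - 1;
    const size_t idx = (size_t)z * nxy + (size_t)y * nx + x;
    if (!out[idx] && std::fabs(vol[idx] - ref) <= tol) {
      out[idx] = true;
      q.push(idx);
    }
  }
  while (!q.empty()) {
    const size_t idx = q.front();
    q.pop();
    const int z = (int)(idx / nxy);
    const int y = (int)((idx - (size_t)z * nxy) / nx);
    const int x = (int)(idx - (size_t)z * nxy - (size_t)y * nx);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          const int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          const size_t j = (size_t)zz * nxy + (size_t)yy * nx + xx;
          if (!out[j] && std::fabs(vol[j] - ref) <= tol) {
            out[j] = true;
            q.push(j);
          }
        }
  }
  return out;
}

// Trilinear interpolation at continuous positions (1-based voxel-center
// coordinates, n x 3 matrix); positions outside the grid sample as 0.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nxy = (size_t)nx * ny;
  const int n = pts.nrow();
  NumericVector out(n);
  const double eps = 1e-9;  // tolerate round-off on the boundary planes
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0) - 1.0, y = pts(i, 1) - 1.0, z = pts(i, 2) - 1.0;
    if (x < -eps || y < -eps || z < -eps || x > nx - 1 + eps ||
        y > ny - 1 + eps || z > nz - 1 + eps) {
      out[i] = 0.0;
      continue;
    }
    x = std::min(std::max(x, 0.0), (double)(nx - 1));
    y = std::min(std::max(y, 0.0), (double)(ny - 1));
    z = std::min(std::max(z, 0.0), (double)(nz - 1));
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 == nx - 1) --x0;
    if (y0 == ny - 1) --y0;
    if (z0 == nz - 1) --z0;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
    const double c000 = vol[(size_t)z0 * nxy + (size_t)y0 * nx + x0];
    const double c100 = vol[(size_t)z0 * nxy + (size_t)y0 * nx + x1];
    const double c010 = vol[(size_t)z0 * nxy + (size_t)y1 * nx + x0];
    const double c110 = vol[(size_t)z0 * nxy + (size_t)y1 * nx + x1];
    const double c001 = vol[(size_t)z1 * nxy + (size_t)y0 * nx + x0];
    const double c101 = vol[(size_t)z1 * nxy + (size_t)y0 * nx + x1];
    const double c011 = vol[(size_t)z1 * nxy + (size_t)y1 * nx + x0];
    const double c111 = vol[(size_t)z1 * nxy + (size_t)y1 * nx + x1];
    const double c00 = c000 * (1 - fx) + c100 * fx;
    const double c10 = c010 * (1 - fx) + c110 * fx;
    const double c01 = c001 * (1 - fx) + c101 * fx;
    const double c11 = c011 * (1 - fx) + c111 * fx;
    out[i] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
             (c01 * (1 - fy) + c11 * fy) * fz;
  }
  return out;
}

// 8-connected labelling of a binary 2D image (column-major, dims (nr,nc)).
// [[Rcpp::export]]
IntegerVector cpp_label2d(LogicalVector img, IntegerVector dims) {
  const int nr = dims[0], nc = dims[1];
  IntegerVector lab(img.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      const int idx = c * nr + r;
      if (!img[idx] || lab[idx]) continue;
      ++next;
      lab[idx] = next;
      q.push(idx);
      while (!q.empty()) {
        const int i = q.front();
        q.pop();
        const int rc = i % nr, cc = i / nr;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            const int rr = rc + dr, c2 = cc + dc;
            if (rr < 0 || c2 < 0 || rr >= nr || c2 >= nc) continue;
            const int j = c2 * nr + rr;
            if (img[j] && !lab[j]) {
              lab[j] = next;
              q.push(j);
            }
          }
      }
    }
  return lab;
}

// Rasterize a tube as a union of capsules: voxel foreground iff its center
// lies within the locally interpolated radius of the polyline through the
// curve samples. Exact for the continuous curve (no chord-sampling
// artifacts). Samples are 1-based continuous coordinates.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_tube(NumericMatrix pts, NumericVector radii,
                                 IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nxy = (size_t)nx * ny;
  LogicalVector out((size_t)nx * ny * nz);
  const int ns = pts.nrow();
  for (int s = 0; s < ns - 1; ++s) {
    const double ax = pts(s, 0), ay = pts(s, 1), az = pts(s, 2);
    const double bx = pts(s + 1, 0), by = pts(s + 1, 1), bz = pts(s + 1, 2);
    const double ra = radii[s], rb = radii[s + 1];
    const double rmax = std::max(ra, rb);
    const double ux = bx - ax, uy = by - ay, uz = bz - az;
    const double len2 = ux * ux + uy * uy + uz * uz;
    const int x0 = clampi((int)std::ceil(std::min(ax, bx) - rmax), 1, nx);
    const int x1 = clampi((int)std::floor(std::max(ax, bx) + rmax), 1, nx);
    const int y0 = clampi((int)std::ceil(std::min(ay, by) - rmax), 1, ny);
    const int y1 = clampi((int)std::floor(std::max(ay, by) + rmax), 1, ny);
    const int z0 = clampi((int)std::ceil(std::min(az, bz) - rmax), 1, nz);
    const int z1 = clampi((int)std::floor(std::max(az, bz) + rmax), 1, nz);
    for (int z = z0; z <= z1; ++z) {
      for (int y = y0; y <= y1; ++y) {
        const size_t base = (size_t)(z - 1) * nxy + (size_t)(y - 1) * nx;
        for (int x = x0; x <= x1; ++x) {
          if (out[base + (x - 1)]) continue;
          const double vx = x - ax, vy = y - ay, vz = z - az;
          double t = len2 > 0 ? (vx * ux + vy * uy + vz * uz) / len2 : 0.0;
          t = t < 0 ? 0 : (t > 1 ? 1 : t);
          const double dx = vx - t * ux, dy = vy - t * uy, dz = vz - t * uz;
          const double r = ra + t * (rb - ra);
          if (dx * dx + dy * dy + dz * dz <= r * r)
            out[base + (x - 1)] = true;
        }
      }
    }
  }
  return out;
}
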