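// Voxel kernels for the 3D segmentation pipeline.
//
// Arrays arrive as R numeric vectors with dim c(ny, nx, nz): linear index
// i = y + ny * (x + nx * z), 0-based here.  All scan orders and tie-breaks
// are defined over (z, y, x) so results are bit-reproducible.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// symmetric (half-sample) reflection: -1 -> 0, n -> n-1
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export(name = ".median3d_cpp")]]
NumericVector median3d_cpp(NumericVector data, IntegerVector dim,
                           IntegerVector radii) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const int rx = radii[0], ry = radii[1], rz = radii[2];
  NumericVector out(data.size());
  const int m = (2 * rx + 1) * (2 * ry + 1) * (2 * rz + 1);
  std::vector<double> buf(m);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int k = 0;
        for (int dz = -rz; dz <= rz; ++dz) {
          const int zz = reflect(z + dz, nz);
          for (int dx = -rx; dx <= rx; ++dx) {
            const int xx = reflect(x + dx, nx);
            const R_xlen_t base = (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz);
            for (int dy = -ry; dy <= ry; ++dy)
              buf[k++] = data[reflect(y + dy, ny) + base];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z)] = buf[m / 2];
      }
  out.attr("dim") = dim;
  return out;
}

// Local maxima above cutoff B in a (2rx+1)x(2ry+1)x(2rz+1) box; connected
// plateaus of equal maxima (linked with `conn`-neighbourhood) reduce to the
// plateau voxel with the lowest (z, y, x).  Returns an n x 3 matrix of
// 1-based (y, x, z) indices ordered by (z, y, x).
// [[Rcpp::export(name = ".detect_seeds_cpp")]]
IntegerMatrix detect_seeds_cpp(NumericVector data, IntegerVector dim,
                               double B, IntegerVector radii, int conn) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const int rx = radii[0], ry = radii[1], rz = radii[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  std::vector<char> cand(n, 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t i = y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z);
        const double v = data[i];
        if (!(v > B)) continue;
        bool ismax = true;
        for (int dz = -rz; dz <= rz && ismax; ++dz) {
          const int zz = reflect(z + dz, nz);
          for (int dx = -rx; dx <= rx && ismax; ++dx) {
            const int xx = reflect(x + dx, nx);
            for (int dy = -ry; dy <= ry; ++dy) {
              const double w =
                  data[reflect(y + dy, ny) + (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz)];
              if (w > v) { ismax = false; break; }
            }
          }
        }
        if (ismax) cand[i] = 1;
      }

  // plateau reduction: flood equal-valued candidate components
  std::vector<char> seen(n, 0);
  std::vector<R_xlen_t> seeds;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t i = y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z);
        if (!cand[i] || seen[i]) continue;
        const double v = data[i];
        // scan order is (z, y, x) ascending, so the first voxel met in a
        // component is its lowest (z, y, x): record it as the seed.
        seeds.push_back(i);
        seen[i] = 1;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          const R_xlen_t c = stack.back();
          stack.pop_back();
          const int cy = (int)(c % ny), cx = (int)((c / ny) % nx),
                    cz = (int)(c / ((R_xlen_t)ny * nx));
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (dz == 0 && dy == 0 && dx == 0) continue;
                if (conn == 6 && std::abs(dz) + std::abs(dy) + std::abs(dx) != 1)
                  continue;
                const int zz = cz + dz, yy = cy + dy, xx = cx + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                  continue;
                const R_xlen_t j = yy + (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz);
                if (cand[j] && !seen[j] && data[j] == v) {
                  seen[j] = 1;
                  stack.push_back(j);
                }
              }
        }
      }
  IntegerMatrix out((int)seeds.size(), 3);
  for (size_t k = 0; k < seeds.size(); ++k) {
    const R_xlen_t i = seeds[k];
    out(k, 0) = (int)(i % ny) + 1;
    out(k, 1) = (int)((i / ny) % nx) + 1;
    out(k, 2) = (int)(i / ((R_xlen_t)ny * nx)) + 1;
  }
  return out;
}

struct QItem {
  double value;
  unsigned long long counter;
  R_xlen_t idx;
};
struct QLess {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.value != b.value) return a.value < b.value;  // max-heap on value
    return a.counter > b.counter;                      // FIFO among ties
  }
};

// Seeded watershed by descending-intensity priority flood.  Seeds: n x 3
// 1-based (y, x, z), labelled 1..n in row order.  Voxels with value > B
// reachable from a seed are labelled; neighbour scan order is (dz, dy, dx)
// ascending; a voxel is labelled the moment it is first reached.
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerVector watershed_cpp(NumericVector data, IntegerVector dim,
                            IntegerMatrix seeds, double B, int conn) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector labels(n, 0);
  std::priority_queue<QItem, std::vector<QItem>, QLess> pq;
  unsigned long long counter = 0;
  for (int s = 0; s < seeds.nrow(); ++s) {
    const int y = seeds(s, 0) - 1, x = seeds(s, 1) - 1, z = seeds(s, 2) - 1;
    if (y < 0 || y >= ny || x < 0 || x >= nx || z < 0 || z >= nz)
      stop("seed outside grid");
    const R_xlen_t i = y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z);
    if (!(data[i] > B)) stop("seed intensity not above background cutoff");
    if (labels[i] != 0) stop("duplicate seed voxel");
    labels[i] = s + 1;
    pq.push(QItem{data[i], counter++, i});
  }
  while (!pq.empty()) {
    const QItem cur = pq.top();
    pq.pop();
    const int cy = (int)(cur.idx % ny), cx = (int)((cur.idx / ny) % nx),
              cz = (int)(cur.idx / ((R_xlen_t)ny * nx));
    const int lab = labels[cur.idx];
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dz == 0 && dy == 0 && dx == 0) continue;
          if (conn == 6 && std::abs(dz) + std::abs(dy) + std::abs(dx) != 1)
            continue;
          const int zz = cz + dz, yy = cy + dy, xx = cx + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          const R_xlen_t j = yy + (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz);
          if (labels[j] == 0 && data[j] > B) {
            labels[j] = lab;
            pq.push(QItem{data[j], counter++, j});
          }
        }
  }
  labels.attr("dim") = dim;
  return labels;
}
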