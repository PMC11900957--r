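#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Circle Hough transform accumulator. For each edge pixel (x, y), each
// candidate radius r and each theta on a regular [0, 360) grid, a candidate
// center
//   a = x - r*cos(theta),  b = y - r*sin(theta)
// is computed and rounded half-up to the nearest accumulator cell.
// Coordinates are 0-based. Each edge pixel contributes AT MOST ONE vote per
// accumulator cell and radius (adjacent theta samples that round to the same
// cell are deduplicated with a stamp array), so a cell's support counts the
// distinct edge pixels consistent with that circle and is comparable across
// radii. The result has dim c(width, height, length(radii)):
// acc[a+1, b+1, ri].
// [[Rcpp::export]]
IntegerVector hough_accumulate_cpp(IntegerVector edge_x, IntegerVector edge_y,
                                   NumericVector radii, int n_theta,
                                   int width, int height) {
  const R_xlen_t ne = edge_x.size(), nr = radii.size();
  const R_xlen_t plane = (R_xlen_t)width * height;
  IntegerVector acc(plane * nr); // zero-initialised
  std::vector<double> ct(n_theta), st(n_theta);
  for (int k = 0; k < n_theta; ++k) {
    double th = 2.0 * M_PI * k / n_theta;
    ct[k] = std::cos(th);
    st[k] = std::sin(th);
  }
  std::vector<unsigned int> stamp(plane, 0u);
  unsigned int tick = 0u;
  int *p = INTEGER(acc);
  for (R_xlen_t ri = 0; ri < nr; ++ri) {
    const double r = radii[ri];
    int *slice = p + ri * plane;
    for (R_xlen_t e = 0; e < ne; ++e) {
      const double x = edge_x[e], y = edge_y[e];
      ++tick;
      if (tick == 0u) { // wrapped: reset stamps
        std::fill(stamp.begin(), stamp.end(), 0u);
        tick = 1u;
      }
      for (int k = 0; k < n_theta; ++k) {
        const int a = (int)std::floor(x - r * ct[k] + 0.5);
        const int b = (int)std::floor(y - r * st[k] + 0.5);
        if (a >= 0 && a < width && b >= 0 && b < height) {
          const R_xlen_t cell = (R_xlen_t)b * width + a;
          if (stamp[cell] != tick) {
            stamp[cell] = tick;
            slice[cell]++;
          }
        }
      }
    }
  }
  acc.attr("dim") = IntegerVector::create(width, height, (int)nr);
  return acc;
}

// 3x3x3 neighbourhood sum over the accumulator (center a, center b, radius
// cell). A circle whose true center or radius falls between accumulator
// cells splits its votes across neighbours; pooling restores the full
// support before peak selection. Out-of-range neighbours contribute zero.
// [[Rcpp::export]]
IntegerVector hough_pool_cpp(IntegerVector acc, int width, int height,
                             int nr) {
  const R_xlen_t plane = (R_xlen_t)width * height;
  IntegerVector out(plane * nr);
  const int *p = INTEGER(acc);
  int *q = INTEGER(out);
  for (int ri = 0; ri < nr; ++ri) {
    for (int b = 0; b < height; ++b) {
      for (int a = 0; a < width; ++a) {
        int s = 0;
        for (int dr = -1; dr <= 1; ++dr) {
          const int rj = ri + dr;
          if (rj < 0 || rj >= nr) continue;
          for (int db = -1; db <= 1; ++db) {
            const int bj = b + db;
            if (bj < 0 || bj >= height) continue;
            const R_xlen_t base = (R_xlen_t)rj * plane + (R_xlen_t)bj * width;
            for (int da = -1; da <= 1; ++da) {
              const int aj = a + da;
              if (aj < 0 || aj >= width) continue;
              s += p[base + aj];
            }
          }
        }
        q[(R_xlen_t)ri * plane + (R_xlen_t)b * width + a] = s;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(width, height, nr);
  return out;
}
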