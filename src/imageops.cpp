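// Image primitives used by preprocessing and fiber morphology:
// 3x3 median filter (NA-aware), 8-connected component labelling,
// exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// Zhang-Suen skeletonization, and disc stamping for fiber rasterization.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 3x3 median filter; NA pixels stay NA and are excluded from neighbours'
// medians. Border pixels use the available (truncated) neighbourhood.
// [[Rcpp::export(name = ".median3_cpp")]]
NumericMatrix median3_cpp(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(9);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (NumericMatrix::is_na(x(i, j))) { out(i, j) = NA_REAL; continue; }
      buf.clear();
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          double v = x(ii, jj);
          if (!NumericMatrix::is_na(v)) buf.push_back(v);
        }
      }
      size_t n = buf.size();
      std::sort(buf.begin(), buf.end());
      out(i, j) = (n % 2 == 1) ? buf[n / 2]
                               : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask; labels 1..k, 0 = bg.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

namespace {
// 1-D squared distance transform (Felzenszwalb & Huttenlocher 2012)
void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}
} // namespace

// Exact Euclidean distance (in px) from each foreground pixel to the nearest
// background pixel centre; 0 on background.
// [[Rcpp::export(name = ".distance_transform_cpp")]]
NumericMatrix distance_transform_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  std::vector<double> g(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      g[j * nr + i] = mask(i, j) ? INF : 0.0;

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = g[j * nr + i];
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) g[j * nr + i] = d[i];
  }
  // rows
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = g[j * nr + i];
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) out(i, j) = std::sqrt(d[j]);
  }
  return out;
}

// Zhang-Suen thinning to a ~1-px-wide 8-connected skeleton.
// [[Rcpp::export(name = ".skeletonize_cpp")]]
LogicalMatrix skeletonize_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<unsigned char> img(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[j * nr + i] = mask(i, j) ? 1 : 0;

  // neighbours P2..P9 clockwise from north
  const int di[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dj[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 1; j < nc - 1; ++j) {
        for (int i = 1; i < nr - 1; ++i) {
          if (!img[j * nr + i]) continue;
          unsigned char p[8];
          int b = 0;
          for (int k = 0; k < 8; ++k) {
            p[k] = img[(j + dj[k]) * nr + (i + di[k])];
            b += p[k];
          }
          if (b < 2 || b > 6) continue;
          int a = 0;
          for (int k = 0; k < 8; ++k)
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++a;
          if (a != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue; // P2*P4*P6
            if (p[2] * p[4] * p[6] != 0) continue; // P4*P6*P8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue; // P2*P4*P8
            if (p[0] * p[4] * p[6] != 0) continue; // P2*P6*P8
          }
          kill.push_back(j * nr + i);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) img[kill[k]] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[j * nr + i] != 0;
  return out;
}

// Stamp discs of given radius (px) at fractional centreline points into a
// label image (pixel centres within the radius of the continuous point, so
// rasterised fiber width matches the analytic band convention); earlier
// fibers keep their label (first-wins). Coordinates are 1-based.
// [[Rcpp::export(name = ".stamp_fiber_cpp")]]
void stamp_fiber_cpp(IntegerMatrix labels, NumericVector rows,
                     NumericVector cols, double radius, int id) {
  int nr = labels.nrow(), nc = labels.ncol();
  int npts = rows.size();
  double r2 = radius * radius;
  for (int k = 0; k < npts; ++k) {
    double rf = rows[k] - 1.0, cf = cols[k] - 1.0;
    int i0 = (int)std::floor(rf - radius), i1 = (int)std::ceil(rf + radius);
    int j0 = (int)std::floor(cf - radius), j1 = (int)std::ceil(cf + radius);
    for (int jj = j0; jj <= j1; ++jj) {
      for (int ii = i0; ii <= i1; ++ii) {
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double di = ii - rf, dj = jj - cf;
        if (di * di + dj * dj > r2) continue;
        if (labels(ii, jj) == 0) labels(ii, jj) = id;
      }
    }
  }
}
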