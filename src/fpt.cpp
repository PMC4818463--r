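#include <Rcpp.h>
using namespace Rcpp;

// First-passage times along a planar polyline.
//
// For fix i and radius r the FPT is the residence time of the path inside the
// circle of radius r centred on fix i: (forward exit time - t_i) plus
// (t_i - backward exit time).  Exit instants are located by exact
// segment-circle intersection with linear interpolation of time along the
// crossing segment.  Because squared distance to the centre is convex in the
// interpolation parameter, the path's maximum distance over a segment is
// attained at an endpoint, so radii can be resolved in ascending order with a
// single forward (or backward) walk per fix.

namespace {

// Exit times (same units as t) from the circle centred at (cx, cy), walking
// the polyline from index `from` in direction `dir` (+1 forward, -1 back).
// radii must be ascending.  Unresolved radii are left as NA.
void scan_exits(const NumericVector& x, const NumericVector& y,
                const NumericVector& t, int from, int dir,
                const NumericVector& radii, double cx, double cy,
                std::vector<double>& exit_t) {
  const int n = x.size(), nr = radii.size();
  int idx = 0;
  int j = from;
  double px = x[j] - cx, py = y[j] - cy;
  double d0 = std::sqrt(px * px + py * py);
  while (idx < nr) {
    int jn = j + dir;
    if (jn < 0 || jn >= n) break;
    double qx = x[jn] - cx, qy = y[jn] - cy;
    double d1 = std::sqrt(qx * qx + qy * qy);
    double dmax = std::max(d0, d1);
    double vx = qx - px, vy = qy - py;
    double a = vx * vx + vy * vy;
    while (idx < nr && radii[idx] < dmax) {
      double r = radii[idx];
      // solve |p + s v|^2 = r^2 for s in [0, 1]; outward crossing is the
      // larger root of the convex quadratic
      double b = 2.0 * (px * vx + py * vy);
      double c = px * px + py * py - r * r;
      double disc = b * b - 4.0 * a * c;
      double s;
      if (a <= 0.0 || disc < 0.0) {
        s = 1.0;  // numerically degenerate: exit at segment end
      } else {
        s = (-b + std::sqrt(disc)) / (2.0 * a);
        if (s < 0.0) s = 0.0;
        if (s > 1.0) s = 1.0;
      }
      exit_t[idx] = t[j] + s * (t[jn] - t[j]);
      ++idx;
    }
    j = jn;
    px = qx; py = qy; d0 = d1;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_fpt(NumericVector x, NumericVector y, NumericVector t,
                      NumericVector radii) {
  const int n = x.size(), nr = radii.size();
  NumericMatrix out(n, nr);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> fwd(nr), bwd(nr);
  for (int i = 0; i < n; ++i) {
    std::fill(fwd.begin(), fwd.end(), NA_REAL);
    std::fill(bwd.begin(), bwd.end(), NA_REAL);
    scan_exits(x, y, t, i, +1, radii, x[i], y[i], fwd);
    scan_exits(x, y, t, i, -1, radii, x[i], y[i], bwd);
    for (int k = 0; k < nr; ++k) {
      if (!ISNA(fwd[k]) && !ISNA(bwd[k]))
        out(i, k) = (fwd[k] - t[i]) + (t[i] - bwd[k]);
    }
  }
  return out;
}

// Penalized-contrast segmentation (Lavielle): Gaussian change-in-mean-and-
// variance cost n_ij * log(max(var_ij, eps)) with population variance, and a
// dynamic program over the number of segments K.

// [[Rcpp::export]]
List cpp_lavielle(NumericVector series, int Kmax, int Lmin, double eps) {
  const int n = series.size();
  if (Kmax < 1 || Lmin < 1 || n < Kmax * Lmin)
    stop("infeasible K_max/L_min for series length");
  // prefix sums for O(1) segment cost
  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + series[i];
    s2[i + 1] = s2[i] + series[i] * series[i];
  }
  const double INF = std::numeric_limits<double>::infinity();
  auto cost = [&](int i, int j) {  // 0-based inclusive [i, j]
    int m = j - i + 1;
    if (m < Lmin) return INF;
    double mu = (s1[j + 1] - s1[i]) / m;
    double v = (s2[j + 1] - s2[i]) / m - mu * mu;
    if (v < eps) v = eps;
    return m * std::log(v);
  };
  // I[k][j] = minimal cost of splitting [0, j] into k+1 segments
  NumericMatrix I(Kmax, n);
  IntegerMatrix back(Kmax, n);
  for (int j = 0; j < n; ++j) {
    I(0, j) = cost(0, j);
    back(0, j) = -1;
  }
  for (int k = 1; k < Kmax; ++k) {
    for (int j = 0; j < n; ++j) {
      double best = INF;
      int arg = -1;
      // last segment [m+1, j]
      for (int m = k * Lmin - 1; m <= j - Lmin; ++m) {
        if (!R_FINITE(I(k - 1, m))) continue;
        double cseg = cost(m + 1, j);
        if (!R_FINITE(cseg)) continue;
        double v = I(k - 1, m) + cseg;
        if (v < best) { best = v; arg = m; }
      }
      I(k, j) = best;
      back(k, j) = arg;
    }
  }
  NumericVector J(Kmax);
  List breaks(Kmax);
  for (int k = 0; k < Kmax; ++k) {
    J[k] = I(k, n - 1);
    IntegerVector ends(k + 1);  // 1-based inclusive end index of each segment
    int j = n - 1;
    for (int kk = k; kk >= 0; --kk) {
      ends[kk] = j + 1;
      j = back(kk, j);
    }
    breaks[k] = ends;
  }
  return List::create(_["J"] = J, _["breaks"] = breaks);
}
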