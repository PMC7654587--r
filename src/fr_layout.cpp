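#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3D Fruchterman-Reingold layout with a central gravity term.
//
// pos:   n x 3 initial coordinates (modified copy returned)
// ei/ej: 0-based edge endpoints
// w:     edge weights (attraction is scaled by w / mean(w))
// k:     ideal spring length, typically (volume / n)^(1/3)
// gravity: spring constant pulling every node toward the running centroid
// t0:    initial temperature (max per-iteration displacement), decays
//        linearly to 0 over niter iterations
// [[Rcpp::export]]
NumericMatrix fr_layout_cpp(NumericMatrix pos, IntegerVector ei,
                            IntegerVector ej, NumericVector w,
                            int niter, double k, double gravity,
                            double t0) {
  const int n = pos.nrow();
  const int ne = ei.size();
  NumericMatrix xy(clone(pos));
  std::vector<double> dx(n), dy(n), dz(n);
  double wmean = 1.0;
  if (ne > 0) {
    double s = 0.0;
    for (int e = 0; e < ne; ++e) s += w[e];
    wmean = s / ne;
    if (wmean <= 0) wmean = 1.0;
  }
  const double k2 = k * k;
  const double eps2 = 1e-12;

  double *X = &xy(0, 0), *Y = &xy(0, 1), *Z = &xy(0, 2);

  for (int it = 0; it < niter; ++it) {
    double t = t0 * (1.0 - (double)it / niter);
    std::fill(dx.begin(), dx.end(), 0.0);
    std::fill(dy.begin(), dy.end(), 0.0);
    std::fill(dz.begin(), dz.end(), 0.0);

    // pairwise repulsion: displacement magnitude k^2 / d (no sqrt needed)
    for (int i = 0; i < n; ++i) {
      const double xi = X[i], yi = Y[i], zi = Z[i];
      double ax = 0.0, ay = 0.0, az = 0.0;
      for (int j = i + 1; j < n; ++j) {
        double ddx = xi - X[j], ddy = yi - Y[j], ddz = zi - Z[j];
        double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (d2 < eps2) d2 = eps2;
        double f = k2 / d2;
        ax += ddx * f; ay += ddy * f; az += ddz * f;
        dx[j] -= ddx * f; dy[j] -= ddy * f; dz[j] -= ddz * f;
      }
      dx[i] += ax; dy[i] += ay; dz[i] += az;
    }

    // edge attraction: magnitude (w / wmean) * d^2 / k
    for (int e = 0; e < ne; ++e) {
      const int i = ei[e], j = ej[e];
      double ddx = X[i] - X[j], ddy = Y[i] - Y[j], ddz = Z[i] - Z[j];
      double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (d < 1e-9) continue;
      double f = (w[e] / wmean) * d / k;  // = (d^2/k) / d, applied to delta
      dx[i] -= ddx * f; dy[i] -= ddy * f; dz[i] -= ddz * f;
      dx[j] += ddx * f; dy[j] += ddy * f; dz[j] += ddz * f;
    }

    // central gravity toward the current centroid
    double cx = 0.0, cy = 0.0, cz = 0.0;
    for (int i = 0; i < n; ++i) { cx += X[i]; cy += Y[i]; cz += Z[i]; }
    cx /= n; cy /= n; cz /= n;
    for (int i = 0; i < n; ++i) {
      dx[i] -= gravity * (X[i] - cx);
      dy[i] -= gravity * (Y[i] - cy);
      dz[i] -= gravity * (Z[i] - cz);
    }

    // move, capped at temperature t
    for (int i = 0; i < n; ++i) {
      double dm = std::sqrt(dx[i] * dx[i] + dy[i] * dy[i] + dz[i] * dz[i]);
      if (dm < 1e-15) continue;
      double scale = (dm > t) ? t / dm : 1.0;
      X[i] += dx[i] * scale;
      Y[i] += dy[i] * scale;
      Z[i] += dz[i] * scale;
    }
  }
  return xy;
}
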