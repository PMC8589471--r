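#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brute-force nearest neighbour from each row of A to the rows of B.
// A and B must have the same number of columns (2 or 3 in practice).
// Returns 1-based indices and Euclidean distances.
// [[Rcpp::export(name = ".cross_nn")]]
List cross_nn(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  if (B.ncol() != d) stop("dimension mismatch between point sets");
  if (nb == 0) stop("empty reference point set");
  IntegerVector idx(na);
  NumericVector dist(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    int besti = 0;
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double dv = A(i, c) - B(j, c);
        s += dv * dv;
        if (s >= best) break;
      }
      if (s < best) { best = s; besti = j; }
    }
    idx[i] = besti + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Eigenvalues of a symmetric 3x3 matrix, descending, via the trigonometric
// closed form (Smith's method). a.. are the six unique entries.
static void eig3_sym(double a00, double a01, double a02,
                     double a11, double a12, double a22,
                     double ev[3]) {
  const double p1 = a01 * a01 + a02 * a02 + a12 * a12;
  const double q = (a00 + a11 + a22) / 3.0;
  if (p1 < 1e-300) {  // diagonal
    ev[0] = a00; ev[1] = a11; ev[2] = a22;
  } else {
    const double b00 = a00 - q, b11 = a11 - q, b22 = a22 - q;
    const double p2 = b00 * b00 + b11 * b11 + b22 * b22 + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    // det(B)/2 with B = (A - qI)/p
    const double det = b00 * (b11 * b22 - a12 * a12)
                     - a01 * (a01 * b22 - a12 * a02)
                     + a02 * (a01 * a12 - b11 * a02);
    double r = det / (2.0 * p * p * p);
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    const double phi = std::acos(r) / 3.0;
    ev[0] = q + 2.0 * p * std::cos(phi);
    ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    ev[1] = 3.0 * q - ev[0] - ev[2];
  }
  // enforce descending order
  if (ev[0] < ev[1]) std::swap(ev[0], ev[1]);
  if (ev[1] < ev[2]) std::swap(ev[1], ev[2]);
  if (ev[0] < ev[1]) std::swap(ev[0], ev[1]);
}

// Per-point surface variation lambda3/(lambda1+lambda2+lambda3) from the
// covariance of the k nearest neighbours (point itself included).
// Brute-force kNN; adequate for clouds up to a few tens of thousands of points.
// [[Rcpp::export(name = ".surface_variation")]]
NumericVector surface_variation(NumericMatrix P, int k) {
  const int n = P.nrow();
  if (k < 4) stop("k_neighbors must be at least 4");
  if (n <= k) stop("need more points than k_neighbors");
  NumericVector out(n);
  std::vector<double> bestd(k);
  std::vector<int> besti(k);
  for (int i = 0; i < n; ++i) {
    int m = 0;  // current heap size (simple insertion list, k is small)
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < 3; ++c) {
        const double dv = P(i, c) - P(j, c);
        s += dv * dv;
      }
      if (m < k) {
        int pos = m++;
        bestd[pos] = s; besti[pos] = j;
        while (pos > 0 && bestd[pos] < bestd[pos - 1]) {
          std::swap(bestd[pos], bestd[pos - 1]);
          std::swap(besti[pos], besti[pos - 1]);
          --pos;
        }
      } else if (s < bestd[k - 1]) {
        int pos = k - 1;
        bestd[pos] = s; besti[pos] = j;
        while (pos > 0 && bestd[pos] < bestd[pos - 1]) {
          std::swap(bestd[pos], bestd[pos - 1]);
          std::swap(besti[pos], besti[pos - 1]);
          --pos;
        }
      }
    }
    double mx = 0, my = 0, mz = 0;
    for (int t = 0; t < k; ++t) {
      mx += P(besti[t], 0); my += P(besti[t], 1); mz += P(besti[t], 2);
    }
    mx /= k; my /= k; mz /= k;
    double c00 = 0, c01 = 0, c02 = 0, c11 = 0, c12 = 0, c22 = 0;
    for (int t = 0; t < k; ++t) {
      const double dx = P(besti[t], 0) - mx;
      const double dy = P(besti[t], 1) - my;
      const double dz = P(besti[t], 2) - mz;
      c00 += dx * dx; c01 += dx * dy; c02 += dx * dz;
      c11 += dy * dy; c12 += dy * dz; c22 += dz * dz;
    }
    double ev[3];
    eig3_sym(c00 / k, c01 / k, c02 / k, c11 / k, c12 / k, c22 / k, ev);
    const double tot = ev[0] + ev[1] + ev[2];
    // degenerate neighbourhoods (collinear or coincident) score zero
    out[i] = (tot > 1e-300 && ev[2] > 0.0) ? ev[2] / tot : 0.0;
  }
  return out;
}
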