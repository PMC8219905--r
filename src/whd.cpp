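#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted Hausdorff distance between a nonnegative prediction map over mesh
// vertices (values in [0, 1]) and a target point set, averaged over its two
// directional terms:
//   A: prediction-mass-weighted mean distance to the nearest target point;
//   B: mean over target points of a generalized-mean (exponent alpha < 0,
//      a soft minimum) of z_xy = p_x * d(x, y) + (1 - p_x) * d_max over all
//      vertices x.
// eps guards empty predictions; d_max is an upper bound on mesh distances.
//
// predT:   p x n matrix, one prediction per column.
// targets: list of integer vectors; entries index COLUMNS of D (1-based).
// D:       p x m distance matrix (vertices x candidate target points). For
//          training this is the full p x p mesh distance matrix and targets
//          hold vertex indices.
//
// Vertices with a prediction of exactly zero contribute a closed-form
// constant to every soft-min sum, so per-entry work is restricted to the
// strictly positive entries. The returned gradient is likewise only filled
// for strictly positive entries: during training every zero entry comes out
// of the output ReLU, whose backward pass masks those gradients to zero, so
// the restriction is exact where it is consumed.

// [[Rcpp::export]]
List whd_batch_cpp(NumericMatrix predT, List targets, NumericMatrix D,
                   double dmax, double alpha, double eps, bool grad) {
  const int p = predT.nrow();
  const int n = predT.ncol();
  NumericVector loss(n);
  NumericMatrix g(grad ? p : 1, grad ? n : 1);
  const double zeps = 1e-6; // keeps z > 0 so z^alpha is finite
  const double zbulk = dmax + zeps;

  std::vector<int> act;
  std::vector<double> qa, dmin, zbuf;
  act.reserve(p); qa.reserve(p); dmin.reserve(p); zbuf.reserve(p);

  for (int i = 0; i < n; ++i) {
    IntegerVector y = targets[i];
    const int m = y.size();
    if (m == 0) stop("empty target point set");
    const double *q = &predT(0, i);

    act.clear(); qa.clear();
    double S = 0.0;
    for (int x = 0; x < p; ++x) {
      if (q[x] > 0.0) {
        act.push_back(x);
        qa.push_back(q[x]);
        S += q[x];
      }
    }
    const int na = (int)act.size();

    // nearest-target distance for every active vertex
    dmin.assign(na, R_PosInf);
    for (int j = 0; j < m; ++j) {
      const double *dcol = &D(0, y[j] - 1);
      for (int a = 0; a < na; ++a) {
        const double d = dcol[act[a]];
        if (d < dmin[a]) dmin[a] = d;
      }
    }
    double Anum = 0.0;
    for (int a = 0; a < na; ++a) Anum += qa[a] * dmin[a];
    const double A = Anum / (S + eps);

    double B = 0.0;
    zbuf.assign(na, 0.0);
    double *gi = grad ? &g(0, i) : nullptr;
    for (int j = 0; j < m; ++j) {
      const double *dcol = &D(0, y[j] - 1);
      double acc;
      if (alpha == -1.0) {
        acc = (p - na) / zbulk;
        for (int a = 0; a < na; ++a) {
          const double z = qa[a] * dcol[act[a]] + (1.0 - qa[a]) * dmax + zeps;
          zbuf[a] = z;
          acc += 1.0 / z;
        }
        const double M = p / acc; // generalized mean with alpha = -1
        B += M;
        if (grad) {
          const double coef = M * M / p / m;
          for (int a = 0; a < na; ++a) {
            const double z = zbuf[a];
            gi[act[a]] += coef * (dcol[act[a]] - dmax) / (z * z);
          }
        }
      } else {
        acc = (p - na) * std::pow(zbulk, alpha);
        for (int a = 0; a < na; ++a) {
          const double z = qa[a] * dcol[act[a]] + (1.0 - qa[a]) * dmax + zeps;
          zbuf[a] = z;
          acc += std::pow(z, alpha);
        }
        const double M = std::pow(acc / p, 1.0 / alpha);
        B += M;
        if (grad) {
          const double coef = std::pow(M, 1.0 - alpha) / p / m;
          for (int a = 0; a < na; ++a) {
            gi[act[a]] += coef * std::pow(zbuf[a], alpha - 1.0) *
                          (dcol[act[a]] - dmax);
          }
        }
      }
    }
    B /= m;
    loss[i] = 0.5 * (A + B);

    if (grad) {
      for (int a = 0; a < na; ++a) {
        gi[act[a]] = 0.5 * (gi[act[a]] + (dmin[a] - A) / (S + eps));
      }
    }
  }
  return List::create(_["loss"] = loss, _["grad"] = g);
}
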