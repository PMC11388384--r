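#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward pass for a set of independent tracks sharing one
// K-state chain. logB holds per-displacement log emission densities (rows:
// displacements of all tracks concatenated in track order; cols: states).
// Returns the posterior state marginals (gamma), the summed pairwise
// transition posteriors (xi, K x K), the summed first-observation posteriors
// and the total log-likelihood.

// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix logB, IntegerVector tlen,
                          NumericVector pi, NumericMatrix A) {
  int K = logB.ncol();
  int n_tracks = tlen.size();
  int N = logB.nrow();
  NumericMatrix gamma(N, K);
  NumericMatrix xi(K, K);
  NumericVector gamma0(K);
  double loglik = 0.0;

  std::vector<double> alpha(N * K), beta(N * K), B(N * K), cscale(N);

  // emission densities, row-rescaled for numerical stability
  std::vector<double> rowshift(N);
  for (int t = 0; t < N; ++t) {
    double mx = logB(t, 0);
    for (int k = 1; k < K; ++k) mx = std::max(mx, logB(t, k));
    rowshift[t] = mx;
    for (int k = 0; k < K; ++k) B[t * K + k] = std::exp(logB(t, k) - mx);
  }

  int off = 0;
  for (int tr = 0; tr < n_tracks; ++tr) {
    int T = tlen[tr];
    // forward
    for (int t = 0; t < T; ++t) {
      int r = off + t;
      double c = 0.0;
      if (t == 0) {
        for (int k = 0; k < K; ++k) {
          alpha[r * K + k] = pi[k] * B[r * K + k];
          c += alpha[r * K + k];
        }
      } else {
        int p = r - 1;
        for (int k = 0; k < K; ++k) {
          double s = 0.0;
          for (int j = 0; j < K; ++j) s += alpha[p * K + j] * A(j, k);
          alpha[r * K + k] = s * B[r * K + k];
          c += alpha[r * K + k];
        }
      }
      if (c <= 0.0) stop("zero forward probability (degenerate emissions)");
      cscale[r] = c;
      for (int k = 0; k < K; ++k) alpha[r * K + k] /= c;
      loglik += std::log(c) + rowshift[r];
    }
    // backward
    for (int k = 0; k < K; ++k) beta[(off + T - 1) * K + k] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      int r = off + t, nx = r + 1;
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j)
          s += A(k, j) * B[nx * K + j] * beta[nx * K + j];
        beta[r * K + k] = s / cscale[nx];
      }
    }
    // posteriors
    for (int t = 0; t < T; ++t) {
      int r = off + t;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        gamma(r, k) = alpha[r * K + k] * beta[r * K + k];
        tot += gamma(r, k);
      }
      for (int k = 0; k < K; ++k) gamma(r, k) /= tot;
    }
    for (int k = 0; k < K; ++k) gamma0[k] += gamma(off, k);
    for (int t = 0; t < T - 1; ++t) {
      int r = off + t, nx = r + 1;
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < K; ++j)
          xi(k, j) += alpha[r * K + k] * A(k, j) * B[nx * K + j] *
                      beta[nx * K + j] / cscale[nx];
    }
    off += T;
  }
  if (off != N) stop("track lengths do not sum to nrow(logB)");
  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["gamma0"] = gamma0, _["loglik"] = loglik);
}
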