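// Batched multi-head scaled dot-product attention, forward and backward.
// Activations are (B*T) x d matrices in token-major layout: token t of
// sample b sits in row t*B + b (0-based). Each matrix is transposed once on
// entry so that every token is a contiguous d-vector (column t*B + b of the
// d x (B*T) transpose); the per-head arithmetic then runs on contiguous
// memory with explicit loops (BLAS per-call overhead would dominate at
// these head sizes).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".mha_fwd_cpp")]]
List mha_fwd_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                 const int B, const int T, const int nh, const double scl) {
  const int d = Q.n_cols;
  const int dh = d / nh;
  arma::mat Qt = Q.t(), Kt = K.t(), Vt = V.t();   // d x (B*T)
  arma::mat Ot(d, Q.n_rows);
  arma::cube A(T, T, (arma::uword)nh * B);
  std::vector<double> S(T * T);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dh;
      for (int i = 0; i < T; ++i) {
        const double* qi = Qt.colptr((arma::uword)i * B + b) + c0;
        for (int j = 0; j < T; ++j) {
          const double* kj = Kt.colptr((arma::uword)j * B + b) + c0;
          double s = 0.0;
          for (int c = 0; c < dh; ++c) s += qi[c] * kj[c];
          S[i + T * j] = s * scl;
        }
      }
      for (int i = 0; i < T; ++i) {
        double mx = S[i];
        for (int j = 1; j < T; ++j) mx = std::max(mx, S[i + T * j]);
        double sum = 0.0;
        for (int j = 0; j < T; ++j) { S[i + T * j] = std::exp(S[i + T * j] - mx); sum += S[i + T * j]; }
        for (int j = 0; j < T; ++j) S[i + T * j] /= sum;
      }
      std::copy(S.begin(), S.end(), A.slice_memptr((arma::uword)h + (arma::uword)nh * b));
      for (int i = 0; i < T; ++i) {
        double* oi = Ot.colptr((arma::uword)i * B + b) + c0;
        for (int c = 0; c < dh; ++c) oi[c] = 0.0;
        for (int j = 0; j < T; ++j) {
          const double a = S[i + T * j];
          const double* vj = Vt.colptr((arma::uword)j * B + b) + c0;
          for (int c = 0; c < dh; ++c) oi[c] += a * vj[c];
        }
      }
    }
  }
  return List::create(Named("O") = arma::mat(Ot.t()), Named("A") = A);
}

// [[Rcpp::export(name = ".mha_bwd_cpp")]]
List mha_bwd_cpp(const arma::mat& dO, const arma::cube& A,
                 const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                 const int B, const int T, const int nh, const double scl) {
  const int d = Q.n_cols;
  const int dh = d / nh;
  arma::mat Qt = Q.t(), Kt = K.t(), Vt = V.t(), Gt = dO.t();
  arma::mat dQt(d, Q.n_rows, arma::fill::zeros),
            dKt(d, Q.n_rows, arma::fill::zeros),
            dVt(d, Q.n_rows, arma::fill::zeros);
  std::vector<double> dA(T * T), dS(T * T);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dh;
      const double* Ah = A.slice_memptr((arma::uword)h + (arma::uword)nh * b);
      for (int i = 0; i < T; ++i) {
        const double* gi = Gt.colptr((arma::uword)i * B + b) + c0;
        for (int j = 0; j < T; ++j) {
          const double* vj = Vt.colptr((arma::uword)j * B + b) + c0;
          double s = 0.0;
          for (int c = 0; c < dh; ++c) s += gi[c] * vj[c];
          dA[i + T * j] = s;
        }
      }
      for (int j = 0; j < T; ++j) {
        double* dvj = dVt.colptr((arma::uword)j * B + b) + c0;
        for (int i = 0; i < T; ++i) {
          const double a = Ah[i + T * j];
          const double* gi = Gt.colptr((arma::uword)i * B + b) + c0;
          for (int c = 0; c < dh; ++c) dvj[c] += a * gi[c];
        }
      }
      for (int i = 0; i < T; ++i) {
        double rs = 0.0;
        for (int j = 0; j < T; ++j) rs += Ah[i + T * j] * dA[i + T * j];
        for (int j = 0; j < T; ++j) dS[i + T * j] = Ah[i + T * j] * (dA[i + T * j] - rs);
      }
      for (int i = 0; i < T; ++i) {
        double* dqi = dQt.colptr((arma::uword)i * B + b) + c0;
        for (int j = 0; j < T; ++j) {
          const double s = dS[i + T * j] * scl;
          const double* kj = Kt.colptr((arma::uword)j * B + b) + c0;
          for (int c = 0; c < dh; ++c) dqi[c] += s * kj[c];
        }
      }
      for (int j = 0; j < T; ++j) {
        double* dkj = dKt.colptr((arma::uword)j * B + b) + c0;
        for (int i = 0; i < T; ++i) {
          const double s = dS[i + T * j] * scl;
          const double* qi = Qt.colptr((arma::uword)i * B + b) + c0;
          for (int c = 0; c < dh; ++c) dkj[c] += s * qi[c];
        }
      }
    }
  }
  return List::create(Named("dQ") = arma::mat(dQt.t()),
                      Named("dK") = arma::mat(dKt.t()),
                      Named("dV") = arma::mat(dVt.t()));
}
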