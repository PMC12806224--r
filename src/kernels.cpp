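// Compiled numerical kernels for the training path: causal FFT long
// convolution (forward + backward), depthwise causal short convolution,
// and GELU. Layouts mirror the R side: activations are (L*B) x C matrices,
// column-major over (L, B); the L x (B*C) channel view has batch index
// fastest over columns. Filters are shared across the batch (one column per
// channel), and their gradient is reduced over batch copies in the
// frequency domain.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// y[t] = sum_{j<=t} h[j] v[t-j] per channel; V: L x (B*C), H: L x C.
// [[Rcpp::export(name = ".cpp_fftconv_fwd")]]
Rcpp::List cpp_fftconv_fwd(const arma::mat& V, const arma::mat& H,
                           const int B, const int Lp) {
  const uword L = V.n_rows, M = V.n_cols, C = H.n_cols;
  cx_mat Vf = fft(V, Lp);
  cx_mat Hf = fft(H, Lp);
  cx_mat P(Lp, M);
  for (uword c = 0; c < C; ++c) {
    const cx_vec hc = Hf.col(c);
    for (uword b = 0; b < (uword)B; ++b) {
      const uword j = c * B + b;
      P.col(j) = Vf.col(j) % hc;
    }
  }
  mat y = real(ifft(P));
  return Rcpp::List::create(
      Rcpp::Named("y") = mat(y.rows(0, L - 1)),
      Rcpp::Named("Vf") = Vf, Rcpp::Named("Hf") = Hf);
}

// dV[s] = sum_j h[j] dz[s+j]; dH[j] = sum_{t,b} v[t] dz[t+j].
// [[Rcpp::export(name = ".cpp_fftconv_bwd")]]
Rcpp::List cpp_fftconv_bwd(const arma::mat& dZ, const arma::cx_mat& Vf,
                           const arma::cx_mat& Hf, const int B, const int L,
                           const bool need_dH) {
  const uword Lp = Vf.n_rows, M = Vf.n_cols, C = Hf.n_cols;
  cx_mat dZf = fft(dZ, Lp);
  cx_mat P(Lp, M);
  for (uword c = 0; c < C; ++c) {
    const cx_vec hc = conj(Hf.col(c));
    for (uword b = 0; b < (uword)B; ++b) {
      const uword j = c * B + b;
      P.col(j) = hc % dZf.col(j);
    }
  }
  mat dV = real(ifft(P));
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("dV") = mat(dV.rows(0, L - 1)),
      Rcpp::Named("dH") = R_NilValue);
  if (need_dH) {
    cx_mat S(Lp, C, fill::zeros);
    for (uword c = 0; c < C; ++c) {
      for (uword b = 0; b < (uword)B; ++b) {
        const uword j = c * B + b;
        S.col(c) += conj(Vf.col(j)) % dZf.col(j);
      }
    }
    mat dH = real(ifft(S));
    out["dH"] = mat(dH.rows(0, L - 1));
  }
  return out;
}

// X: L x (B*C) channel view; K: C x w (tap 1 = lag 0); causal.
// [[Rcpp::export(name = ".cpp_shortconv_fwd")]]
arma::mat cpp_shortconv_fwd(const arma::mat& X, const arma::mat& K,
                            const int B) {
  const uword L = X.n_rows, C = K.n_rows, w = K.n_cols;
  mat Y(L, X.n_cols);
  for (uword c = 0; c < C; ++c) {
    for (uword b = 0; b < (uword)B; ++b) {
      const uword j = c * B + b;
      const double* x = X.colptr(j);
      double* y = Y.colptr(j);
      for (uword t = 0; t < L; ++t) {
        double acc = 0.0;
        const uword jm = std::min<uword>(w - 1, t);
        for (uword k = 0; k <= jm; ++k) acc += K(c, k) * x[t - k];
        y[t] = acc;
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".cpp_shortconv_bwd")]]
Rcpp::List cpp_shortconv_bwd(const arma::mat& dZ, const arma::mat& X,
                             const arma::mat& K, const int B) {
  const uword L = X.n_rows, C = K.n_rows, w = K.n_cols;
  mat dX(L, X.n_cols);
  mat dK(C, w, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (uword b = 0; b < (uword)B; ++b) {
      const uword j = c * B + b;
      const double* x = X.colptr(j);
      const double* dz = dZ.colptr(j);
      double* dx = dX.colptr(j);
      for (uword t = 0; t < L; ++t) {
        double acc = 0.0;
        const uword jm = std::min<uword>(w - 1, L - 1 - t);
        for (uword k = 0; k <= jm; ++k) acc += K(c, k) * dz[t + k];
        dx[t] = acc;
      }
      for (uword k = 0; k < w && k < L; ++k) {
        double acc = 0.0;
        for (uword t = k; t < L; ++t) acc += dz[t] * x[t - k];
        dK(c, k) += acc;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dK") = dK);
}

// exact GELU x * Phi(x) and its derivative Phi(x) + x * phi(x)
// [[Rcpp::export(name = ".cpp_gelu_fwd")]]
Rcpp::List cpp_gelu_fwd(const arma::mat& X) {
  const double inv_sqrt2 = 0.7071067811865475244;
  mat P = 0.5 * (1.0 + erf(X * inv_sqrt2));
  return Rcpp::List::create(Rcpp::Named("y") = mat(X % P),
                            Rcpp::Named("P") = P);
}

// [[Rcpp::export(name = ".cpp_gelu_bwd")]]
arma::mat cpp_gelu_bwd(const arma::mat& dZ, const arma::mat& X,
                       const arma::mat& P) {
  const double inv_sqrt2pi = 0.3989422804014326779;
  return dZ % (P + X % (inv_sqrt2pi * exp(-0.5 * square(X))));
}

// Y + bias broadcast over rows, without materializing the broadcast in R
// [[Rcpp::export(name = ".cpp_add_bias")]]
arma::mat cpp_add_bias(const arma::mat& Y, const arma::vec& b) {
  mat out = Y;
  out.each_row() += b.t();
  return out;
}

// row-wise layer normalization over features (columns)
// [[Rcpp::export(name = ".cpp_layernorm_fwd")]]
Rcpp::List cpp_layernorm_fwd(const arma::mat& X, const arma::vec& g,
                             const arma::vec& b, const double eps) {
  vec mu = mean(X, 1);
  mat xc = X.each_col() - mu;
  vec inv = 1.0 / sqrt(mean(square(xc), 1) + eps);
  mat xhat = xc.each_col() % inv;
  mat y = xhat.each_row() % g.t();
  y.each_row() += b.t();
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export(name = ".cpp_layernorm_bwd")]]
Rcpp::List cpp_layernorm_bwd(const arma::mat& dZ, const arma::mat& xhat,
                             const arma::vec& inv, const arma::vec& g) {
  mat dxhat = dZ.each_row() % g.t();
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv;
  rowvec dg = sum(dZ % xhat, 0);
  rowvec db = sum(dZ, 0);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dg") = vec(dg.t()),
                            Rcpp::Named("db") = vec(db.t()));
}
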