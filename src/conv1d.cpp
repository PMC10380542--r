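// Stride-1 "same" 1-D convolution and kernel-3/stride-2/pad-1 max pooling
// on stacked spectra. Activation layout: channels x (n * L), sample i
// occupying the contiguous column block [i*L, (i+1)*L). A convolution is a
// sum over kernel taps t of W_t' * A with the result shifted by t columns
// within each sample block, which keeps every BLAS call on contiguous
// memory.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// [[Rcpp::export]]
arma::mat conv1d_fwd_cpp(const arma::mat& A, const Rcpp::List& taps,
                         const arma::ivec& offsets, const arma::vec& bias,
                         const int n, const int L) {
  const mat W0 = Rcpp::as<mat>(taps[0]);
  const uword Cout = W0.n_cols;
  mat out(Cout, A.n_cols, fill::zeros);
  for (int j = 0; j < taps.size(); ++j) {
    const mat W = Rcpp::as<mat>(taps[j]);
    const int t = offsets[j];
    const mat T = W.t() * A;  // Cout x nL
    const int p1 = std::max(0, -t);
    const int p2 = std::min(L - 1, L - 1 - t);
    if (p1 > p2) continue;
    for (int i = 0; i < n; ++i) {
      const int base = i * L;
      out.cols(base + p1, base + p2) += T.cols(base + p1 + t, base + p2 + t);
    }
  }
  out.each_col() += bias;
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::mat& dOut, const arma::mat& A,
                          const Rcpp::List& taps, const arma::ivec& offsets,
                          const int n, const int L, const bool need_param) {
  const uword Cin = A.n_rows;
  mat dA(Cin, A.n_cols, fill::zeros);
  Rcpp::List dW(taps.size());
  for (int j = 0; j < taps.size(); ++j) {
    const mat W = Rcpp::as<mat>(taps[j]);
    const int t = offsets[j];
    const int p1 = std::max(0, -t);
    const int p2 = std::min(L - 1, L - 1 - t);
    if (p1 > p2) { if (need_param) dW[j] = mat(Cin, dOut.n_rows, fill::zeros); continue; }
    // dA[:, dst + t] += W * dOut[:, dst]
    const mat U = W * dOut;  // Cin x nL
    for (int i = 0; i < n; ++i) {
      const int base = i * L;
      dA.cols(base + p1 + t, base + p2 + t) += U.cols(base + p1, base + p2);
    }
    if (need_param) {
      // dW_t = sum over valid dst columns of A[:, dst + t] * dOut[:, dst]'
      mat Ash(Cin, A.n_cols, fill::zeros);
      for (int i = 0; i < n; ++i) {
        const int base = i * L;
        Ash.cols(base + p1, base + p2) = A.cols(base + p1 + t, base + p2 + t);
      }
      dW[j] = Ash * dOut.t();
    }
  }
  if (need_param) {
    const vec db = sum(dOut, 1);
    return Rcpp::List::create(Rcpp::Named("dA") = dA,
                              Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db);
  }
  return Rcpp::List::create(Rcpp::Named("dA") = dA);
}

// [[Rcpp::export]]
Rcpp::List maxpool1d_fwd_cpp(const arma::mat& A, const int n, const int L) {
  const int L2 = (L - 1) / 2 + 1;
  const uword C = A.n_rows;
  mat out(C, (uword)(n * L2));
  imat which(C, (uword)(n * L2));
  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < L2; ++q) {
      const uword oc = (uword)(i * L2 + q);
      for (uword c = 0; c < C; ++c) {
        double best = -datum::inf;
        int wb = 0;
        for (int m = 0; m < 3; ++m) {
          const int p = 2 * q + m - 1;  // pad 1
          if (p < 0 || p >= L) continue;
          const double v = A.at(c, (uword)(i * L + p));
          if (v > best) { best = v; wb = m + 1; }
        }
        out.at(c, oc) = best;
        which.at(c, oc) = wb;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("which_tap") = which,
                            Rcpp::Named("L2") = L2);
}

// [[Rcpp::export]]
arma::mat maxpool1d_bwd_cpp(const arma::mat& dOut, const arma::imat& which,
                            const int n, const int L) {
  const int L2 = (L - 1) / 2 + 1;
  const uword C = dOut.n_rows;
  mat dA(C, (uword)(n * L), fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < L2; ++q) {
      const uword oc = (uword)(i * L2 + q);
      for (uword c = 0; c < C; ++c) {
        const int m = which.at(c, oc) - 1;
        const int p = 2 * q + m - 1;
        dA.at(c, (uword)(i * L + p)) += dOut.at(c, oc);
      }
    }
  }
  return dA;
}
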