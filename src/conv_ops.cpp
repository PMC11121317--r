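// Convolution and pooling primitives for the pair-image classifier.
//
// Activations are stored as (H*W) x C matrices in R's column-major spatial
// order (linear index p = (j-1)*H + i for row i, column j, both 1-based).
// Convolution kernels are passed as a ((2k+1)^2 * C_in) x C_out matrix whose
// row index enumerates channel fastest, then row offset t, then column
// offset s: row = ((s+k)*(2k+1) + (t+k))*C_in + c.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// gather zero-padded shifted copies: out(:, blk*C + c) holds x_{i+t, j+s}
static void im2col(const mat& X, int H, int W, int k, mat& out) {
  const int C = X.n_cols;
  const int K = 2 * k + 1;
  out.zeros(H * W, K * K * C);
  int blk = 0;
  for (int s = -k; s <= k; ++s) {
    for (int t = -k; t <= k; ++t) {
      const int i0 = std::max(0, -t), i1 = std::min(H, H - t);
      const int j0 = std::max(0, -s), j1 = std::min(W, W - s);
      if (i1 > i0) {
        for (int c = 0; c < C; ++c) {
          const double* src = X.colptr(c);
          double* dst = out.colptr(blk * C + c);
          for (int j = j0; j < j1; ++j) {
            std::memcpy(dst + (size_t)j * H + i0,
                        src + (size_t)(j + s) * H + (i0 + t),
                        sizeof(double) * (i1 - i0));
          }
        }
      }
      ++blk;
    }
  }
}

// scatter-add adjoint of im2col
static void col2im(const mat& dXc, int H, int W, int k, mat& dX) {
  const int C = dX.n_cols;
  const int K = 2 * k + 1;
  int blk = 0;
  for (int s = -k; s <= k; ++s) {
    for (int t = -k; t <= k; ++t) {
      const int i0 = std::max(0, -t), i1 = std::min(H, H - t);
      const int j0 = std::max(0, -s), j1 = std::min(W, W - s);
      if (i1 > i0) {
        for (int c = 0; c < C; ++c) {
          const double* src = dXc.colptr(blk * C + c);
          double* dst = dX.colptr(c);
          for (int j = j0; j < j1; ++j) {
            const double* sp = src + (size_t)j * H + i0;
            double* dp = dst + (size_t)(j + s) * H + (i0 + t);
            for (int i = 0; i < i1 - i0; ++i) dp[i] += sp[i];
          }
        }
      }
      ++blk;
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, int H, int W, int k,
                       const arma::mat& Wm, const arma::vec& bias) {
  mat Xc;
  im2col(X, H, W, k, Xc);
  mat Y = Xc * Wm;
  Y.each_row() += bias.t();
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::mat& X, const arma::mat& dY,
                        int H, int W, int k, const arma::mat& Wm,
                        bool need_dx) {
  mat Xc;
  im2col(X, H, W, k, Xc);
  mat dW = Xc.t() * dY;
  vec db = sum(dY, 0).t();
  mat dX;
  if (need_dx) {
    mat dXc = dY * Wm.t();
    dX.zeros(X.n_rows, X.n_cols);
    col2im(dXc, H, W, k, dX);
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}

// [[Rcpp::export]]
Rcpp::List cpp_pool_max(const arma::mat& X, int H, int W, int s) {
  const int C = X.n_cols;
  const int Hp = H / s, Wp = W / s;
  mat P(Hp * Wp, C);
  umat idx(Hp * Wp, C); // 1-based linear index into H*W
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    for (int bj = 0; bj < Wp; ++bj) {
      for (int bi = 0; bi < Hp; ++bi) {
        double best = -datum::inf;
        size_t besti = 0;
        for (int j = bj * s; j < (bj + 1) * s; ++j) {
          for (int i = bi * s; i < (bi + 1) * s; ++i) {
            const size_t p = (size_t)j * H + i;
            if (x[p] > best) { best = x[p]; besti = p; }
          }
        }
        const size_t q = (size_t)bj * Hp + bi;
        P(q, c) = best;
        idx(q, c) = besti + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("P") = P, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat cpp_pool_avg(const arma::mat& X, int H, int W, int s) {
  const int C = X.n_cols;
  const int Hp = H / s, Wp = W / s;
  const double inv = 1.0 / (s * s);
  mat P(Hp * Wp, C);
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    for (int bj = 0; bj < Wp; ++bj) {
      for (int bi = 0; bi < Hp; ++bi) {
        double acc = 0.0;
        for (int j = bj * s; j < (bj + 1) * s; ++j)
          for (int i = bi * s; i < (bi + 1) * s; ++i)
            acc += x[(size_t)j * H + i];
        P((size_t)bj * Hp + bi, c) = acc * inv;
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_unpool_max(const arma::mat& P, const arma::umat& idx,
                         int H, int W) {
  mat X(H * W, P.n_cols, fill::zeros);
  for (unsigned int c = 0; c < P.n_cols; ++c) {
    double* x = X.colptr(c);
    for (unsigned int q = 0; q < P.n_rows; ++q) {
      x[idx(q, c) - 1] += P(q, c);
    }
  }
  return X;
}

// [[Rcpp::export]]
arma::mat cpp_unpool_avg(const arma::mat& P, int H, int W, int s) {
  const int C = P.n_cols;
  const int Hp = H / s, Wp = W / s;
  const double inv = 1.0 / (s * s);
  mat X(H * W, C);
  for (int c = 0; c < C; ++c) {
    double* x = X.colptr(c);
    const double* p = P.colptr(c);
    for (int bj = 0; bj < Wp; ++bj) {
      for (int bi = 0; bi < Hp; ++bi) {
        const double v = p[(size_t)bj * Hp + bi] * inv;
        for (int j = bj * s; j < (bj + 1) * s; ++j)
          for (int i = bi * s; i < (bi + 1) * s; ++i)
            x[(size_t)j * H + i] = v;
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
arma::mat cpp_lrelu(const arma::mat& X) {
  mat Y(X.n_rows, X.n_cols);
  const double* x = X.memptr();
  double* y = Y.memptr();
  const size_t n = X.n_elem;
  for (size_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0.1 * x[i];
  return Y;
}

// d * LReLU'(z), fused
// [[Rcpp::export]]
arma::mat cpp_lrelu_bwd(const arma::mat& Z, const arma::mat& D) {
  mat Y(Z.n_rows, Z.n_cols);
  const double* z = Z.memptr();
  const double* d = D.memptr();
  double* y = Y.memptr();
  const size_t n = Z.n_elem;
  for (size_t i = 0; i < n; ++i) y[i] = z[i] > 0 ? d[i] : 0.1 * d[i];
  return Y;
}

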