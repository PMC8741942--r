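// Fused 1-D convolution + batch-norm + ReLU + max-pool kernels for the
// sample-level network. Activations are (channels x length*batch) matrices,
// columns time-major within each batch element, matching the R layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col with zero same-padding: A (C x L*B) -> Xc (k*C x L*B).
// Copies one contiguous (C x run) block per (batch element, tap).
static mat im2col(const mat& A, int k, int L, int B) {
  const int C = A.n_rows;
  const int pad = (k - 1) / 2;
  mat Xc(k * C, (size_t)L * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int o = 0; o < k; ++o) {
      const int t_lo = std::max(0, pad - o);
      const int t_hi = std::min(L - 1, L - 1 + pad - o);
      if (t_lo > t_hi) continue;
      Xc.submat(o * C, (uword)b * L + t_lo,
                (o + 1) * C - 1, (uword)b * L + t_hi) =
        A.cols((uword)b * L + t_lo + o - pad,
               (uword)b * L + t_hi + o - pad);
    }
  }
  return Xc;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_fwd(const arma::mat& A, const arma::mat& W,
                        const arma::vec& bias, const arma::vec& gamma,
                        const arma::vec& beta, const arma::vec& run_mean,
                        const arma::vec& run_var, bool train,
                        bool batchnorm, bool pool, int pool_size,
                        int k, int L, int B, double eps) {
  mat Xc = im2col(A, k, L, B);
  mat Z = W * Xc;
  Z.each_col() += bias;

  vec mu, v, invstd;
  mat xhat;
  if (batchnorm) {
    if (train) {
      mu = mean(Z, 1);
      v = mean(Z % Z, 1) - mu % mu;
      v.transform([](double x) { return x > 0 ? x : 0.0; });
      invstd = 1.0 / sqrt(v + eps);
      xhat = Z;
      xhat.each_col() -= mu;
      xhat.each_col() %= invstd;
      Z = xhat;
      Z.each_col() %= gamma;
      Z.each_col() += beta;
    } else {
      invstd = 1.0 / sqrt(run_var + eps);
      Z.each_col() -= run_mean;
      Z.each_col() %= invstd % gamma;
      Z.each_col() += beta;
    }
  }

  // ReLU in place; the backward pass recovers the mask from the cached
  // layer output (out > 0), so no mask is materialized here.
  Z.elem(find(Z < 0)).zeros();

  umat pidx;
  if (pool) {
    const int L_out = L / pool_size;
    mat P((size_t)Z.n_rows, (size_t)L_out * B);
    pidx.set_size(Z.n_rows, (size_t)L_out * B);
    for (int b = 0; b < B; ++b) {
      for (int t = 0; t < L_out; ++t) {
        const uword dst = (uword)b * L_out + t;
        const uword base = (uword)b * L + (uword)t * pool_size;
        for (uword c = 0; c < Z.n_rows; ++c) {
          double best = Z(c, base);
          uword arg = 0;
          for (int j = 1; j < pool_size; ++j) {
            const double val = Z(c, base + j);
            if (val > best) { best = val; arg = j; }
          }
          P(c, dst) = best;
          pidx(c, dst) = arg;
        }
      }
    }
    Z = std::move(P);
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("out") = Z,
    Rcpp::Named("pidx") = pidx);
  if (batchnorm && train) {
    out["xhat"] = xhat;
    out["invstd"] = invstd;
    out["mu"] = mu;
    out["var"] = v;
  }
  return out;
}

// `A_out` is the layer's cached output (post ReLU/pool); values > 0 mark
// positions that passed the ReLU, so the mask is applied on the (smaller)
// output grid before unpooling.
// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::mat& dOut, const arma::mat& A_in,
                        const arma::mat& A_out, const arma::mat& W,
                        const arma::vec& gamma,
                        const arma::mat& xhat, const arma::vec& invstd,
                        const arma::umat& pidx,
                        bool batchnorm, bool pool, int pool_size,
                        int k, int L, int B) {
  const int C_out = W.n_rows;
  const int C_in = A_in.n_rows;
  const int pad = (k - 1) / 2;

  mat dMasked = dOut;
  dMasked.elem(find(A_out <= 0)).zeros();

  mat dH;
  if (pool) {
    const int L_out = L / pool_size;
    dH.zeros(C_out, (size_t)L * B);
    for (int b = 0; b < B; ++b) {
      for (int t = 0; t < L_out; ++t) {
        const uword src = (uword)b * L_out + t;
        const uword base = (uword)b * L + (uword)t * pool_size;
        for (int c = 0; c < C_out; ++c)
          dH(c, base + pidx(c, src)) = dMasked(c, src);
      }
    }
  } else {
    dH = std::move(dMasked);
  }

  vec dgamma, dbeta;
  mat dZ;
  if (batchnorm) {
    const double M = (double)dH.n_cols;
    dgamma = sum(dH % xhat, 1);
    dbeta = sum(dH, 1);
    mat dxhat = dH;
    dxhat.each_col() %= gamma;
    const vec s1 = sum(dxhat, 1);
    const vec s2 = sum(dxhat % xhat, 1);
    dZ = M * dxhat;
    dZ.each_col() -= s1;
    dZ -= xhat.each_col() % s2;
    dZ.each_col() %= invstd / M;
  } else {
    dZ = dH;
  }

  mat Xc = im2col(A_in, k, L, B);
  mat dW = dZ * Xc.t();
  vec db = sum(dZ, 1);
  mat dXc = W.t() * dZ;

  // col2im: accumulate tap rows back onto the input grid, one contiguous
  // block per (batch element, tap)
  mat dA(C_in, (size_t)L * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int o = 0; o < k; ++o) {
      const int t_lo = std::max(0, pad - o);
      const int t_hi = std::min(L - 1, L - 1 + pad - o);
      if (t_lo > t_hi) continue;
      dA.cols((uword)b * L + t_lo + o - pad,
              (uword)b * L + t_hi + o - pad) +=
        dXc.submat(o * C_in, (uword)b * L + t_lo,
                   (o + 1) * C_in - 1, (uword)b * L + t_hi);
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("dA") = dA, Rcpp::Named("dW") = dW,
    Rcpp::Named("db") = db);
  if (batchnorm) {
    out["dgamma"] = dgamma;
    out["dbeta"] = dbeta;
  }
  return out;
}
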