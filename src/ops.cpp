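// Batched linear-algebra kernels for the attention model.
// Layout convention: a batch of matrices is an arma::cube with
// dims (rows = sequence positions, cols = features, slices = batch).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Flatten (m x h x S) cube to (m*S x h) matrix; row index r + s*m.
static mat flatten_cube(const cube& X) {
  const uword m = X.n_rows, h = X.n_cols, S = X.n_slices;
  mat M(m * S, h);
  for (uword s = 0; s < S; ++s)
    M.rows(s * m, s * m + m - 1) = X.slice(s);
  return M;
}

static cube unflatten_mat(const mat& M, uword m, uword S) {
  cube X(m, M.n_cols, S);
  for (uword s = 0; s < S; ++s)
    X.slice(s) = M.rows(s * m, s * m + m - 1);
  return X;
}

// Position-wise linear with shared weights: Y_s = X_s * W + b (one dgemm).
// [[Rcpp::export]]
arma::cube gx_cube_linear(const arma::cube& X, const arma::mat& W,
                          const arma::rowvec& b) {
  mat M = flatten_cube(X) * W;
  M.each_row() += b;
  return unflatten_mat(M, X.n_rows, X.n_slices);
}

// Gradient wrt shared weights: dW = sum_s X_s^T dY_s.
// [[Rcpp::export]]
arma::mat gx_cube_linear_dW(const arma::cube& X, const arma::cube& dY) {
  return flatten_cube(X).t() * flatten_cube(dY);
}

// Gradient wrt shared bias: colsums over all positions and slices.
// [[Rcpp::export]]
arma::rowvec gx_cube_colsums(const arma::cube& dY) {
  return sum(flatten_cube(dY), 0);
}

// Slice-wise matrix product C_s = op(A_s) * op(B_s).
// [[Rcpp::export]]
arma::cube gx_bmm(const arma::cube& A, const arma::cube& B,
                  bool transA = false, bool transB = false) {
  const uword S = A.n_slices;
  if (B.n_slices != S) Rcpp::stop("gx_bmm: slice count mismatch");
  const uword m = transA ? A.n_cols : A.n_rows;
  const uword n = transB ? B.n_rows : B.n_cols;
  cube C(m, n, S);
  for (uword s = 0; s < S; ++s) {
    if (!transA && !transB)      C.slice(s) = A.slice(s) * B.slice(s);
    else if (!transA && transB)  C.slice(s) = A.slice(s) * B.slice(s).t();
    else if (transA && !transB)  C.slice(s) = A.slice(s).t() * B.slice(s);
    else                         C.slice(s) = A.slice(s).t() * B.slice(s).t();
  }
  return C;
}

// Split (m x H x S) into per-head cube (m x H/heads x S*heads);
// slice index of instance s, head j is s*heads + j.
// [[Rcpp::export]]
arma::cube gx_split_heads(const arma::cube& X, int heads) {
  const uword m = X.n_rows, H = X.n_cols, S = X.n_slices;
  const uword dh = H / heads;
  cube Y(m, dh, S * heads);
  for (uword s = 0; s < S; ++s)
    for (uword j = 0; j < (uword)heads; ++j)
      Y.slice(s * heads + j) = X.slice(s).cols(j * dh, (j + 1) * dh - 1);
  return Y;
}

// [[Rcpp::export]]
arma::cube gx_merge_heads(const arma::cube& Y, int heads) {
  const uword m = Y.n_rows, dh = Y.n_cols, Sh = Y.n_slices;
  const uword S = Sh / heads;
  cube X(m, dh * heads, S);
  for (uword s = 0; s < S; ++s)
    for (uword j = 0; j < (uword)heads; ++j)
      X.slice(s).cols(j * dh, (j + 1) * dh - 1) = Y.slice(s * heads + j);
  return X;
}

// Row-wise softmax under an additive mask (0 = allowed, -Inf = forbidden).
// scores: (m x n x S*heads); amask: (m x n x S), shared across heads.
// Forbidden keys get weight exactly 0; fully forbidden rows become all-0.
// [[Rcpp::export]]
arma::cube gx_masked_softmax(const arma::cube& scores, const arma::cube& amask,
                             int heads) {
  const uword m = scores.n_rows, n = scores.n_cols, Sh = scores.n_slices;
  cube A(m, n, Sh, fill::zeros);
  for (uword sh = 0; sh < Sh; ++sh) {
    const double* msk = amask.slice_memptr(sh / heads);
    const double* z = scores.slice_memptr(sh);
    double* a = A.slice_memptr(sh);
    for (uword r = 0; r < m; ++r) {
      double mx = -datum::inf;
      for (uword c = 0; c < n; ++c) {
        const uword k = r + c * m;
        if (msk[k] == 0.0 && z[k] > mx) mx = z[k];
      }
      if (!std::isfinite(mx)) continue;  // fully masked row stays all-zero
      double tot = 0.0;
      for (uword c = 0; c < n; ++c) {
        const uword k = r + c * m;
        if (msk[k] == 0.0) { a[k] = std::exp(z[k] - mx); tot += a[k]; }
      }
      for (uword c = 0; c < n; ++c) {
        const uword k = r + c * m;
        if (a[k] != 0.0) a[k] /= tot;
      }
    }
  }
  return A;
}

// Backward of row-softmax: dS = A % (dA - rowsum(dA % A)).
// Rows zeroed in the forward pass yield zero gradient.
// [[Rcpp::export]]
arma::cube gx_softmax_bwd(const arma::cube& A, const arma::cube& dA) {
  const uword m = A.n_rows, n = A.n_cols;
  cube dS(size(A), fill::zeros);
  std::vector<double> rs(m);
  for (uword s = 0; s < A.n_slices; ++s) {
    const double* a = A.slice_memptr(s);
    const double* da = dA.slice_memptr(s);
    double* ds = dS.slice_memptr(s);
    std::fill(rs.begin(), rs.end(), 0.0);
    for (uword c = 0; c < n; ++c)
      for (uword r = 0; r < m; ++r) {
        const uword k = r + c * m;
        if (a[k] != 0.0) rs[r] += a[k] * da[k];
      }
    for (uword c = 0; c < n; ++c)
      for (uword r = 0; r < m; ++r) {
        const uword k = r + c * m;
        if (a[k] != 0.0) ds[k] = a[k] * (da[k] - rs[r]);
      }
  }
  return dS;
}

// Layer normalisation over the feature axis, per position per slice.
// [[Rcpp::export]]
Rcpp::List gx_layernorm_fwd(const arma::cube& X, const arma::rowvec& gamma,
                            const arma::rowvec& beta, double eps) {
  const uword m = X.n_rows, h = X.n_cols, S = X.n_slices;
  cube Y(m, h, S), Xhat(m, h, S);
  mat rstd(m, S);
  std::vector<double> mu(m), var(m);
  for (uword s = 0; s < S; ++s) {
    const double* x = X.slice_memptr(s);
    double* xh = Xhat.slice_memptr(s);
    double* y = Y.slice_memptr(s);
    std::fill(mu.begin(), mu.end(), 0.0);
    std::fill(var.begin(), var.end(), 0.0);
    for (uword c = 0; c < h; ++c)
      for (uword r = 0; r < m; ++r) mu[r] += x[r + c * m];
    for (uword r = 0; r < m; ++r) mu[r] /= h;
    for (uword c = 0; c < h; ++c)
      for (uword r = 0; r < m; ++r) {
        const double d = x[r + c * m] - mu[r];
        var[r] += d * d;
      }
    for (uword r = 0; r < m; ++r)
      rstd(r, s) = 1.0 / std::sqrt(var[r] / h + eps);
    for (uword c = 0; c < h; ++c) {
      const double g = gamma(c), b = beta(c);
      for (uword r = 0; r < m; ++r) {
        const uword k = r + c * m;
        xh[k] = (x[k] - mu[r]) * rstd(r, s);
        y[k] = xh[k] * g + b;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("xhat") = Xhat,
                            Rcpp::Named("rstd") = rstd);
}

// [[Rcpp::export]]
Rcpp::List gx_layernorm_bwd(const arma::cube& dY, const arma::cube& Xhat,
                            const arma::mat& rstd, const arma::rowvec& gamma) {
  const uword m = dY.n_rows, h = dY.n_cols, S = dY.n_slices;
  cube dX(m, h, S);
  rowvec dgamma(h, fill::zeros), dbeta(h, fill::zeros);
  std::vector<double> m1(m), m2(m);
  for (uword s = 0; s < S; ++s) {
    const double* dy = dY.slice_memptr(s);
    const double* xh = Xhat.slice_memptr(s);
    double* dx = dX.slice_memptr(s);
    std::fill(m1.begin(), m1.end(), 0.0);
    std::fill(m2.begin(), m2.end(), 0.0);
    for (uword c = 0; c < h; ++c) {
      const double g = gamma(c);
      double dg = 0.0, db = 0.0;
      for (uword r = 0; r < m; ++r) {
        const uword k = r + c * m;
        dg += dy[k] * xh[k];
        db += dy[k];
        const double dxh = dy[k] * g;
        m1[r] += dxh;
        m2[r] += dxh * xh[k];
      }
      dgamma(c) += dg;
      dbeta(c) += db;
    }
    for (uword r = 0; r < m; ++r) { m1[r] /= h; m2[r] /= h; }
    for (uword c = 0; c < h; ++c) {
      const double g = gamma(c);
      for (uword r = 0; r < m; ++r) {
        const uword k = r + c * m;
        dx[k] = rstd(r, s) * (dy[k] * g - m1[r] - xh[k] * m2[r]);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
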