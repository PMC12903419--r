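// Hot inner kernels of the convolutional-recurrent classifier: patch
// extraction (im2col) and its adjoint, max pooling, and layer normalisation.
// Matrix products stay in R where they reach BLAS directly.
#include <Rcpp.h>
using namespace Rcpp;

// X: (C, L, B) array; returns (K*C, L*B) patch matrix for a dilated,
// zero-padded ('same') kernel of size K.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector X, int C, int L, int B, int K, int dilation) {
  int pad = (K - 1) / 2 * dilation;
  NumericMatrix M(K * C, L * B);
  const double* x = X.begin();
  double* m = M.begin();
  int nrow = K * C;
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (size_t)b * C * L;
    for (int t = 0; t < L; ++t) {
      double* col = m + (size_t)(b * L + t) * nrow;
      for (int k = 0; k < K; ++k) {
        int src = t - pad + k * dilation;
        if (src >= 0 && src < L) {
          const double* xc = xb + (size_t)src * C;
          std::copy(xc, xc + C, col + k * C);
        }
      }
    }
  }
  return M;
}

// Adjoint of im2col: accumulates dM (K*C, L*B) back into dX (C, L, B).
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dM, int C, int L, int B, int K, int dilation) {
  int pad = (K - 1) / 2 * dilation;
  NumericVector dX((size_t)C * L * B);
  const double* m = dM.begin();
  double* x = dX.begin();
  int nrow = K * C;
  for (int b = 0; b < B; ++b) {
    double* xb = x + (size_t)b * C * L;
    for (int t = 0; t < L; ++t) {
      const double* col = m + (size_t)(b * L + t) * nrow;
      for (int k = 0; k < K; ++k) {
        int src = t - pad + k * dilation;
        if (src >= 0 && src < L) {
          double* xc = xb + (size_t)src * C;
          const double* mc = col + k * C;
          for (int c = 0; c < C; ++c) xc[c] += mc[c];
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(C, L, B);
  return dX;
}

// Non-overlapping max pooling over positions. Y: (f, L*B) with position
// fastest; returns out (f, Tn*B) and the within-window argmax (1-based).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericMatrix Y, int L, int B, int size) {
  int f = Y.nrow();
  int Tn = L / size;
  NumericMatrix out(f, Tn * B);
  IntegerMatrix amax(f, Tn * B);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < Tn; ++w) {
      double* o = &out(0, b * Tn + w);
      int* a = &amax(0, b * Tn + w);
      const double* y0 = &Y(0, b * L + w * size);
      for (int r = 0; r < f; ++r) { o[r] = y0[r]; a[r] = 1; }
      for (int k = 1; k < size; ++k) {
        const double* yk = &Y(0, b * L + w * size + k);
        for (int r = 0; r < f; ++r) {
          if (yk[r] > o[r]) { o[r] = yk[r]; a[r] = k + 1; }
        }
      }
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(NumericMatrix dOut, IntegerMatrix amax,
                              int L, int B, int size) {
  int f = dOut.nrow();
  int Tn = L / size;
  NumericMatrix dY(f, L * B);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < Tn; ++w) {
      const double* d = &dOut(0, b * Tn + w);
      const int* a = &amax(0, b * Tn + w);
      for (int r = 0; r < f; ++r) {
        dY(r, b * L + w * size + (a[r] - 1)) += d[r];
      }
    }
  }
  return dY;
}

// Layer normalisation across rows (channels) of each column.
// [[Rcpp::export]]
List cpp_layernorm_fwd(NumericMatrix Y, NumericVector g, NumericVector be,
                       double eps) {
  int f = Y.nrow(), n = Y.ncol();
  NumericMatrix out(f, n), xhat(f, n);
  NumericVector inv(n);
  for (int j = 0; j < n; ++j) {
    const double* y = &Y(0, j);
    double mu = 0, ss = 0;
    for (int r = 0; r < f; ++r) mu += y[r];
    mu /= f;
    for (int r = 0; r < f; ++r) { double d = y[r] - mu; ss += d * d; }
    double iv = 1.0 / std::sqrt(ss / f + eps);
    inv[j] = iv;
    double* xh = &xhat(0, j);
    double* o = &out(0, j);
    for (int r = 0; r < f; ++r) {
      xh[r] = (y[r] - mu) * iv;
      o[r] = xh[r] * g[r] + be[r];
    }
  }
  return List::create(_["out"] = out, _["Xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_layernorm_bwd(NumericMatrix dOut, NumericMatrix Xhat, NumericVector inv,
                       NumericVector g, bool need_param_grads) {
  int f = dOut.nrow(), n = dOut.ncol();
  NumericMatrix dX(f, n);
  NumericVector dg(f), dbe(f);
  for (int j = 0; j < n; ++j) {
    const double* d = &dOut(0, j);
    const double* xh = &Xhat(0, j);
    double m1 = 0, m2 = 0;
    for (int r = 0; r < f; ++r) {
      double dxh = d[r] * g[r];
      m1 += dxh;
      m2 += dxh * xh[r];
      if (need_param_grads) { dg[r] += d[r] * xh[r]; dbe[r] += d[r]; }
    }
    m1 /= f; m2 /= f;
    double iv = inv[j];
    double* o = &dX(0, j);
    for (int r = 0; r < f; ++r) {
      o[r] = (d[r] * g[r] - m1 - xh[r] * m2) * iv;
    }
  }
  if (need_param_grads) {
    return List::create(_["dX"] = dX, _["dg"] = dg, _["dbe"] = dbe);
  }
  return List::create(_["dX"] = dX, _["dg"] = R_NilValue, _["dbe"] = R_NilValue);
}

// Fused ReLU + optional dropout mask application; returns the activation
// and keeps the mask logic in the caller via the returned relu mask.
// [[Rcpp::export]]
List cpp_relu(NumericMatrix Y) {
  int f = Y.nrow(), n = Y.ncol();
  NumericMatrix out(f, n);
  LogicalMatrix mask(f, n);
  size_t total = (size_t)f * n;
  const double* y = Y.begin();
  double* o = out.begin();
  int* mk = mask.begin();
  for (size_t i = 0; i < total; ++i) {
    bool pos = y[i] > 0;
    mk[i] = pos;
    o[i] = pos ? y[i] : 0.0;
  }
  return List::create(_["out"] = out, _["mask"] = mask);
}
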