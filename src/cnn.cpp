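// Minimal 1D convolution / pooling kernels for the built-in CNN trainer.
// Layout: signals as arma::cube (length x channels x batch), kernels as
// arma::cube (kernel x in_channels x filters). Valid convolution, stride 1
// (cross-correlation orientation, as in every deep-learning framework).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export(name = ".conv1d_forward_cpp")]]
arma::cube conv1d_forward_cpp(const arma::cube& X, const arma::cube& W,
                              const arma::vec& b) {
  const uword Lin = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const uword k = W.n_rows, F = W.n_slices;
  if (W.n_cols != Cin) Rcpp::stop("channel mismatch");
  if (k > Lin) Rcpp::stop("kernel longer than input");
  const uword Lout = Lin - k + 1;
  cube Y(Lout, F, B);
  for (uword n = 0; n < B; ++n) {
    const mat& Xs = X.slice(n);
    mat& Ys = Y.slice(n);
    for (uword f = 0; f < F; ++f) {
      const mat& Wf = W.slice(f);
      double* y = Ys.colptr(f);
      for (uword t = 0; t < Lout; ++t) y[t] = b[f];
      for (uword c = 0; c < Cin; ++c) {
        const double* xc = Xs.colptr(c);
        const double* wc = Wf.colptr(c);
        for (uword kk = 0; kk < k; ++kk) {
          const double w = wc[kk];
          const double* xs = xc + kk;
          for (uword t = 0; t < Lout; ++t) y[t] += w * xs[t];
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".conv1d_backward_cpp")]]
Rcpp::List conv1d_backward_cpp(const arma::cube& X, const arma::cube& W,
                               const arma::cube& dY) {
  const uword Lin = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const uword k = W.n_rows, F = W.n_slices;
  const uword Lout = Lin - k + 1;
  cube dX(Lin, Cin, B, fill::zeros);
  cube dW(k, Cin, F, fill::zeros);
  vec db(F, fill::zeros);
  for (uword n = 0; n < B; ++n) {
    const mat& Xs = X.slice(n);
    const mat& dYs = dY.slice(n);
    mat& dXs = dX.slice(n);
    for (uword f = 0; f < F; ++f) {
      const double* g = dYs.colptr(f);
      const mat& Wf = W.slice(f);
      mat& dWf = dW.slice(f);
      double acc = 0.0;
      for (uword t = 0; t < Lout; ++t) acc += g[t];
      db[f] += acc;
      for (uword c = 0; c < Cin; ++c) {
        const double* xc = Xs.colptr(c);
        const double* wc = Wf.colptr(c);
        double* dxc = dXs.colptr(c);
        double* dwc = dWf.colptr(c);
        for (uword kk = 0; kk < k; ++kk) {
          const double w = wc[kk];
          double dw = 0.0;
          const double* xs = xc + kk;
          double* dxs = dxc + kk;
          for (uword t = 0; t < Lout; ++t) {
            dw += xs[t] * g[t];
            dxs[t] += w * g[t];
          }
          dwc[kk] += dw;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Non-overlapping pooling with factor p; trailing remainder positions are
// dropped. type 0 = max (argmax returned as 1-based input row), 1 = mean.
// [[Rcpp::export(name = ".pool1d_forward_cpp")]]
Rcpp::List pool1d_forward_cpp(const arma::cube& X, int p, int type) {
  const uword Lin = X.n_rows, C = X.n_cols, B = X.n_slices;
  const uword Lout = Lin / (uword)p;
  if (Lout < 1) Rcpp::stop("pool factor larger than input length");
  cube Y(Lout, C, B);
  ucube amax(Lout, C, B, fill::zeros);
  for (uword n = 0; n < B; ++n)
    for (uword c = 0; c < C; ++c) {
      const double* x = X.slice(n).colptr(c);
      double* y = Y.slice(n).colptr(c);
      for (uword t = 0; t < Lout; ++t) {
        const uword s = t * (uword)p;
        if (type == 0) {
          uword bi = s;
          double bv = x[s];
          for (uword j = 1; j < (uword)p; ++j)
            if (x[s + j] > bv) { bv = x[s + j]; bi = s + j; }
          y[t] = bv;
          amax(t, c, n) = bi + 1;
        } else {
          double acc = 0.0;
          for (uword j = 0; j < (uword)p; ++j) acc += x[s + j];
          y[t] = acc / p;
        }
      }
    }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export(name = ".pool1d_backward_cpp")]]
arma::cube pool1d_backward_cpp(const arma::cube& dY, const arma::ucube& amax,
                               int Lin, int p, int type) {
  const uword Lout = dY.n_rows, C = dY.n_cols, B = dY.n_slices;
  cube dX((uword)Lin, C, B, fill::zeros);
  for (uword n = 0; n < B; ++n)
    for (uword c = 0; c < C; ++c) {
      const double* g = dY.slice(n).colptr(c);
      double* dx = dX.slice(n).colptr(c);
      for (uword t = 0; t < Lout; ++t) {
        if (type == 0) {
          dx[amax(t, c, n) - 1] += g[t];
        } else {
          const double share = g[t] / p;
          const uword s = t * (uword)p;
          for (uword j = 0; j < (uword)p; ++j) dx[s + j] += share;
        }
      }
    }
  return dX;
}

// Exact lagged inner products with zero extension, ascending accumulation so
// results match a naive double-loop written in interpreted code bit for bit.
// lag k runs from -(len(a)-1) .. len(b)-1; z(k) = sum_t a[t] * b[t+k].
// [[Rcpp::export(name = ".xcorr_cpp")]]
arma::vec xcorr_cpp(const arma::vec& a, const arma::vec& b) {
  const int la = a.n_elem, lb = b.n_elem;
  vec z(la + lb - 1, fill::zeros);
  for (int k = -(la - 1); k <= lb - 1; ++k) {
    const int t0 = std::max(0, -k);
    const int t1 = std::min(la - 1, lb - 1 - k);
    long double acc = 0.0;   // match R's extended-precision sum()
    for (int t = t0; t <= t1; ++t) acc += a[t] * b[t + k];
    z[k + la - 1] = (double)acc;
  }
  return z;
}
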