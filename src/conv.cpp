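// Strided valid/padded convolution kernels for the two branches.
// Layout conventions match the R side: arrays are column-major with the
// batch index fastest, i.e. a 1-D batch is [N, C, L] and a 2-D batch is
// [N, C, H, W]; weights are ((C*k) x Cout) with column index
// (c-1)*k + kk for 1-D and (c-1)*k*k + (ki-1)*k + kj for 2-D, exactly the
// im2col ordering the pure-R reference used.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::cube as_cube(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  return arma::cube(const_cast<double *>(x.begin()), d[0], d[1], d[2], false);
}

// ---- 1-D -------------------------------------------------------------------

static arma::mat im2col1(const arma::cube &X, int k, int stride, int Lout) {
  const int N = X.n_rows, C = X.n_cols;
  arma::mat M(N * Lout, C * k);
  for (int c = 0; c < C; ++c) {
    for (int kk = 0; kk < k; ++kk) {
      for (int l = 0; l < Lout; ++l) {
        const arma::vec col = X.slice(l * stride + kk).col(c);
        M.col(c * k + kk).subvec(l * N, l * N + N - 1) = col;
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".conv1d_fwd")]]
NumericVector conv1d_fwd(NumericVector Xr, const arma::mat &W,
                         const arma::vec &b, int k, int stride) {
  arma::cube X = as_cube(Xr);
  const int N = X.n_rows, L = X.n_slices, Cout = W.n_cols;
  const int Lout = (L - k) / stride + 1;
  arma::mat M = im2col1(X, k, stride, Lout);
  arma::mat Y = M * W;
  Y.each_row() += b.t();
  // Y rows are (n + N*l); output cube is [N, Cout, Lout]
  NumericVector out(N * Cout * Lout);
  arma::cube O(out.begin(), N, Cout, Lout, false);
  for (int l = 0; l < Lout; ++l) {
    O.slice(l) = Y.rows(l * N, l * N + N - 1);
  }
  out.attr("dim") = IntegerVector::create(N, Cout, Lout);
  return out;
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
List conv1d_bwd(NumericVector Xr, const arma::mat &W, NumericVector dOutr,
                int k, int stride) {
  arma::cube X = as_cube(Xr), dO = as_cube(dOutr);
  const int N = X.n_rows, C = X.n_cols, L = X.n_slices;
  const int Cout = dO.n_cols, Lout = dO.n_slices;
  arma::mat dY(N * Lout, Cout);
  for (int l = 0; l < Lout; ++l) {
    dY.rows(l * N, l * N + N - 1) = dO.slice(l);
  }
  arma::mat M = im2col1(X, k, stride, Lout);
  arma::mat dW = M.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dM = dY * W.t();
  NumericVector dXr(N * C * L);
  arma::cube dX(dXr.begin(), N, C, L, false);
  for (int c = 0; c < C; ++c) {
    for (int kk = 0; kk < k; ++kk) {
      for (int l = 0; l < Lout; ++l) {
        dX.slice(l * stride + kk).col(c) +=
          dM.col(c * k + kk).subvec(l * N, l * N + N - 1);
      }
    }
  }
  dXr.attr("dim") = IntegerVector::create(N, C, L);
  return List::create(_["dX"] = dXr, _["dW"] = dW, _["db"] = db);
}

// ---- 2-D -------------------------------------------------------------------
// X is [N, C, H, W] flattened column-major; treat as N*C rows? Simpler:
// address manually: index(n, c, h, w) = n + N*(c + C*(h + H*w)).

struct Dim4 {
  int N, C, H, W;
};

static inline double get4(const double *x, const Dim4 &d, int n, int c,
                          int h, int w) {
  return x[n + (size_t)d.N * (c + (size_t)d.C * (h + (size_t)d.H * w))];
}

static inline double *ptr4(double *x, const Dim4 &d, int n, int c, int h,
                           int w) {
  return x + n + (size_t)d.N * (c + (size_t)d.C * (h + (size_t)d.H * w));
}

static arma::mat im2col2(const double *x, const Dim4 &d, int k, int stride,
                         int pad, int Hout, int Wout) {
  arma::mat M(d.N * Hout * Wout, d.C * k * k, arma::fill::zeros);
  for (int c = 0; c < d.C; ++c) {
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int col = c * k * k + ki * k + kj;
        for (int w = 0; w < Wout; ++w) {
          const int wi = w * stride + kj - pad;
          if (wi < 0 || wi >= d.W) continue;
          for (int h = 0; h < Hout; ++h) {
            const int hi = h * stride + ki - pad;
            if (hi < 0 || hi >= d.H) continue;
            const size_t row0 = (size_t)d.N * (h + (size_t)Hout * w);
            for (int n = 0; n < d.N; ++n) {
              M(row0 + n, col) = get4(x, d, n, c, hi, wi);
            }
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector Xr, const arma::mat &W,
                         const arma::vec &b, int k, int stride, int pad) {
  IntegerVector dd = Xr.attr("dim");
  Dim4 d{dd[0], dd[1], dd[2], dd[3]};
  const int Hout = (d.H + 2 * pad - k) / stride + 1;
  const int Wout = (d.W + 2 * pad - k) / stride + 1;
  const int Cout = W.n_cols;
  arma::mat M = im2col2(Xr.begin(), d, k, stride, pad, Hout, Wout);
  arma::mat Y = M * W;  // rows: n + N*(h + Hout*w)
  Y.each_row() += b.t();
  NumericVector out((size_t)d.N * Cout * Hout * Wout);
  Dim4 od{d.N, Cout, Hout, Wout};
  for (int co = 0; co < Cout; ++co) {
    const arma::vec ycol = Y.col(co);
    for (int w = 0; w < Wout; ++w) {
      for (int h = 0; h < Hout; ++h) {
        const size_t row0 = (size_t)d.N * (h + (size_t)Hout * w);
        std::copy(ycol.memptr() + row0, ycol.memptr() + row0 + d.N,
                  ptr4(out.begin(), od, 0, co, h, w));
      }
    }
  }
  out.attr("dim") = IntegerVector::create(d.N, Cout, Hout, Wout);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector Xr, const arma::mat &W, NumericVector dOutr,
                int k, int stride, int pad) {
  IntegerVector dd = Xr.attr("dim");
  Dim4 d{dd[0], dd[1], dd[2], dd[3]};
  IntegerVector od4 = dOutr.attr("dim");
  Dim4 od{od4[0], od4[1], od4[2], od4[3]};
  const int Cout = od.C, Hout = od.H, Wout = od.W;
  arma::mat dY((size_t)d.N * Hout * Wout, Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int w = 0; w < Wout; ++w) {
      for (int h = 0; h < Hout; ++h) {
        const size_t row0 = (size_t)d.N * (h + (size_t)Hout * w);
        const double *src = ptr4(const_cast<double *>(dOutr.begin()), od, 0,
                                 co, h, w);
        std::copy(src, src + d.N, dY.colptr(co) + row0);
      }
    }
  }
  arma::mat M = im2col2(Xr.begin(), d, k, stride, pad, Hout, Wout);
  arma::mat dW = M.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dM = dY * W.t();
  NumericVector dXr((size_t)d.N * d.C * d.H * d.W);
  for (int c = 0; c < d.C; ++c) {
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int col = c * k * k + ki * k + kj;
        for (int w = 0; w < Wout; ++w) {
          const int wi = w * stride + kj - pad;
          if (wi < 0 || wi >= d.W) continue;
          for (int h = 0; h < Hout; ++h) {
            const int hi = h * stride + ki - pad;
            if (hi < 0 || hi >= d.H) continue;
            const size_t row0 = (size_t)d.N * (h + (size_t)Hout * w);
            double *dst = ptr4(dXr.begin(), d, 0, c, hi, wi);
            const double *src = dM.colptr(col) + row0;
            for (int n = 0; n < d.N; ++n) dst[n] += src[n];
          }
        }
      }
    }
  }
  dXr.attr("dim") = IntegerVector::create(d.N, d.C, d.H, d.W);
  return List::create(_["dX"] = dXr, _["dW"] = dW, _["db"] = db);
}
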