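// Minimal CNN kernels for the VGG-family classifiers: 3x3 same-padding
// convolution via im2col + GEMM, and max-pooling with argmax bookkeeping.
// Layout convention throughout: activations are (H, W, C, N) column-major
// R arrays; convolution weights are a (C_out x 9*C_in) matrix whose columns
// are ordered (ky, kx, c_in) fastest-to-slowest matching im2col below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat im2col3x3(const double* x, int H, int W, int C) {
  // returns (9*C) x (H*W) patch matrix for one sample, zero padding of 1
  arma::mat cols(9 * C, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        int row = (ky + 1) + 3 * (kx + 1) + 9 * c;
        for (int j = 0; j < W; ++j) {
          int sj = j + kx;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + ky;
            if (si < 0 || si >= H) continue;
            cols(row, i + (size_t)H * j) = xc[si + (size_t)H * sj];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv3x3_forward")]]
NumericVector conv3x3_forward(NumericVector x, NumericMatrix w,
                              NumericVector b) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = w.nrow();
  if (w.ncol() != 9 * C) stop("conv weight shape mismatch");
  arma::mat wm(w.begin(), Cout, 9 * C, false);
  arma::vec bv(b.begin(), Cout, false);
  NumericVector out((R_xlen_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat cols = im2col3x3(x.begin() + (size_t)n * H * W * C, H, W, C);
    arma::mat o = wm * cols;              // Cout x (H*W)
    o.each_col() += bv;
    // transpose into (H*W) x Cout contiguous per-channel layout
    arma::mat ot = o.t();
    std::copy(ot.begin(), ot.end(), out.begin() + (size_t)n * H * W * Cout);
  }
  return out;
}

// [[Rcpp::export(name = ".conv3x3_backward")]]
List conv3x3_backward(NumericVector x, NumericVector gy, NumericMatrix w) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = w.nrow();
  arma::mat wm(w.begin(), Cout, 9 * C, false);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat gw(Cout, 9 * C, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat cols = im2col3x3(x.begin() + (size_t)n * H * W * C, H, W, C);
    // gy sample as (H*W) x Cout, transpose to Cout x (H*W)
    arma::mat gyt(const_cast<double*>(gy.begin()) + (size_t)n * H * W * Cout,
                  H * W, Cout, false);
    arma::mat g = gyt.t();
    gw += g * cols.t();
    gb += arma::sum(g, 1);
    arma::mat gcols = wm.t() * g;         // (9*C) x (H*W)
    // col2im: scatter-add patches back into gx
    double* gxn = gx.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      double* gxc = gxn + (size_t)c * H * W;
      for (int kx = -1; kx <= 1; ++kx) {
        for (int ky = -1; ky <= 1; ++ky) {
          int row = (ky + 1) + 3 * (kx + 1) + 9 * c;
          for (int j = 0; j < W; ++j) {
            int sj = j + kx;
            if (sj < 0 || sj >= W) continue;
            for (int i = 0; i < H; ++i) {
              int si = i + ky;
              if (si < 0 || si >= H) continue;
              gxc[si + (size_t)H * sj] += gcols(row, i + (size_t)H * j);
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx,
                      _["gw"] = NumericMatrix(Cout, 9 * C, gw.begin()),
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward(NumericVector x, int s) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % s || W % s) stop("maxpool: spatial dims not divisible by stride");
  int Ho = H / s, Wo = W / s;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * N);
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * H * W;
      double* oc = out.begin() + (size_t)(n * C + c) * Ho * Wo;
      int* ac = arg.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          double best = -1e300; int bidx = -1;
          for (int dj = 0; dj < s; ++dj)
            for (int di = 0; di < s; ++di) {
              int idx = (io * s + di) + H * (jo * s + dj);
              if (xc[idx] > best) { best = xc[idx]; bidx = idx; }
            }
          oc[io + (size_t)Ho * jo] = best;
          ac[io + (size_t)Ho * jo] = bidx;
        }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
NumericVector maxpool_backward(NumericVector gy, IntegerVector arg,
                               IntegerVector in_dim) {
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  int H = in_dim[0], W = in_dim[1];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = gy.begin() + (size_t)(n * C + c) * Ho * Wo;
      const int* ac = arg.begin() + (size_t)(n * C + c) * Ho * Wo;
      double* gxc = gx.begin() + (size_t)(n * C + c) * H * W;
      for (int k = 0; k < Ho * Wo; ++k) gxc[ac[k]] += gc[k];
    }
  return gx;
}

// [[Rcpp::export(name = ".conv1x1_forward")]]
NumericVector conv1x1_forward(NumericVector x, NumericMatrix w,
                              NumericVector b) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = w.nrow();
  if (w.ncol() != C) stop("conv1x1 weight shape mismatch");
  arma::mat wm(w.begin(), Cout, C, false);
  arma::vec bv(b.begin(), Cout, false);
  NumericVector out((R_xlen_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat xs(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                 H * W, C, false);
    arma::mat o = xs * wm.t();            // (H*W) x Cout
    o.each_row() += bv.t();
    std::copy(o.begin(), o.end(), out.begin() + (size_t)n * H * W * Cout);
  }
  return out;
}

// [[Rcpp::export(name = ".conv1x1_backward")]]
List conv1x1_backward(NumericVector x, NumericVector gy, NumericMatrix w) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = w.nrow();
  arma::mat wm(w.begin(), Cout, C, false);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat gw(Cout, C, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat xs(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                 H * W, C, false);
    arma::mat gys(const_cast<double*>(gy.begin()) + (size_t)n * H * W * Cout,
                  H * W, Cout, false);
    gw += gys.t() * xs;
    gb += arma::sum(gys, 0).t();
    arma::mat g = gys * wm;               // (H*W) x C
    std::copy(g.begin(), g.end(), gx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["gx"] = gx,
                      _["gw"] = NumericMatrix(Cout, C, gw.begin()),
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}
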