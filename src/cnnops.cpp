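// Batched 2D convolution (valid padding, stride 1) and max-pooling
// primitives for the curvature-image CNN. Convolutions are evaluated as
// im2col + BLAS matrix products via Armadillo.
//
// Array layouts (R column-major):
//   activations: dim (H, W, C, N)
//   conv weights: matrix (k*k*C_in) x C_out, patch entry order
//                 c_in * k^2 + ky * k + kx
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_one(const double *x, int H, int W, int C, int k,
                       arma::mat &cols) {
  const int Ho = H - k + 1, Wo = W - k + 1;
  // cols: (k*k*C) x (Ho*Wo); output position index = wo * Ho + ho
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * H * W;
    for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        int row = c * k * k + ky * k + kx;
        for (int wo = 0; wo < Wo; ++wo) {
          const double *src = xc + (size_t)(wo + kx) * H + ky;
          double *dst = cols.memptr() + (size_t)(wo * Ho) * cols.n_rows + row;
          for (int ho = 0; ho < Ho; ++ho)
            dst[(size_t)ho * cols.n_rows] = src[ho];
        }
      }
  }
}

// [[Rcpp::export(name = ".conv_forward")]]
NumericVector conv_forward(NumericVector x, IntegerVector xdim,
                           NumericMatrix w, NumericVector bias) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = (int)std::lround(std::sqrt((double)w.nrow() / C));
  const int Co = w.ncol();
  const int Ho = H - k + 1, Wo = W - k + 1;
  if (Ho < 1 || Wo < 1) stop("input smaller than convolution kernel");
  NumericVector out((R_xlen_t)Ho * Wo * Co * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat cols(k * k * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    arma::mat o = wm.t() * cols;  // Co x (Ho*Wo)
    double *op = out.begin() + (size_t)n * Ho * Wo * Co;
    for (int c = 0; c < Co; ++c) {
      double bc = bias[c];
      for (int pos = 0; pos < Ho * Wo; ++pos)
        op[(size_t)c * Ho * Wo + pos] = o(c, pos) + bc;
    }
  }
  return out;
}

// Gradients of a conv layer. Returns list(dx, dw, db); dx omitted when
// need_dx is false (first layer).
// [[Rcpp::export(name = ".conv_backward")]]
List conv_backward(NumericVector x, IntegerVector xdim, NumericMatrix w,
                   NumericVector dout, bool need_dx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = (int)std::lround(std::sqrt((double)w.nrow() / C));
  const int Co = w.ncol();
  const int Ho = H - k + 1, Wo = W - k + 1;
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dW(w.nrow(), Co, arma::fill::zeros);
  arma::vec db(Co, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((R_xlen_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  arma::mat cols(k * k * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double *dop = dout.begin() + (size_t)n * Ho * Wo * Co;
    arma::mat dY(Co, Ho * Wo);
    for (int c = 0; c < Co; ++c)
      for (int pos = 0; pos < Ho * Wo; ++pos)
        dY(c, pos) = dop[(size_t)c * Ho * Wo + pos];
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    dW += cols * dY.t();
    db += arma::sum(dY, 1);
    if (need_dx) {
      arma::mat dcols = wm * dY;  // (k*k*C) x (Ho*Wo)
      double *dxp = dx.begin() + (size_t)n * H * W * C;
      for (int c = 0; c < C; ++c) {
        double *dxc = dxp + (size_t)c * H * W;
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx) {
            int row = c * k * k + ky * k + kx;
            for (int wo = 0; wo < Wo; ++wo) {
              double *dst = dxc + (size_t)(wo + kx) * H + ky;
              const double *src = dcols.memptr() + (size_t)(wo * Ho) * dcols.n_rows + row;
              for (int ho = 0; ho < Ho; ++ho)
                dst[ho] += src[(size_t)ho * dcols.n_rows];
            }
          }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW), _["db"] = wrap(db));
}

// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward(NumericVector x, IntegerVector xdim, int p) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / p, Wo = W / p;
  if (Ho < 1 || Wo < 1) stop("input smaller than pooling window");
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector amax((R_xlen_t)Ho * Wo * C * N);  // linear index into (H,W) plane
  amax.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + (size_t)(n * C + c) * H * W;
      double *op = out.begin() + (size_t)(n * C + c) * Ho * Wo;
      int *ap = amax.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300;
          int besti = 0;
          for (int dx = 0; dx < p; ++dx)
            for (int dy = 0; dy < p; ++dy) {
              int hh = ho * p + dy, ww = wo * p + dx;
              double v = xp[(size_t)ww * H + hh];
              if (v > best) { best = v; besti = ww * H + hh; }
            }
          op[(size_t)wo * Ho + ho] = best;
          ap[(size_t)wo * Ho + ho] = besti;
        }
    }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
NumericVector maxpool_backward(NumericVector dout, IntegerVector amax,
                               IntegerVector outdim, IntegerVector xdim) {
  const int Ho = outdim[0], Wo = outdim[1], C = outdim[2], N = outdim[3];
  const int H = xdim[0], W = xdim[1];
  NumericVector dx((R_xlen_t)H * W * xdim[2] * xdim[3]);
  dx.attr("dim") = IntegerVector::create(H, W, xdim[2], xdim[3]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *dop = dout.begin() + (size_t)(n * C + c) * Ho * Wo;
      const int *ap = amax.begin() + (size_t)(n * C + c) * Ho * Wo;
      double *dxp = dx.begin() + (size_t)(n * C + c) * H * W;
      for (int i = 0; i < Ho * Wo; ++i) dxp[ap[i]] += dop[i];
    }
  return dx;
}
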