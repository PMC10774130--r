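// Minimal 2-D convolution / pooling primitives for the tracker network.
// Tensors are R arrays with dim (H, W, C, N) in column-major order.
// Convolutions are 'same' (zero padded), stride 1, square kernels of odd size.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat im2col(const double* x, int H, int W, int C, int k) {
  const int pad = k / 2, HW = H * W, R = C * k * k;
  arma::mat col(R, HW, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int r = c * k * k + dy * k + dx;
        for (int w = 0; w < W; ++w) {
          const int ww = w + dx - pad;
          if (ww < 0 || ww >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hh = h + dy - pad;
            if (hh < 0 || hh >= H) continue;
            col(r, h + H * w) = xc[hh + H * ww];
          }
        }
      }
    }
  }
  return col;
}

static inline void col2im_add(double* x, const arma::mat& col, int H, int W,
                              int C, int k) {
  const int pad = k / 2, HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * HW;
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int r = c * k * k + dy * k + dx;
        for (int w = 0; w < W; ++w) {
          const int ww = w + dx - pad;
          if (ww < 0 || ww >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hh = h + dy - pad;
            if (hh < 0 || hh >= H) continue;
            xc[hh + H * ww] += col(r, h + H * w);
          }
        }
      }
    }
  }
}

// x: (H,W,Cin,N); wmat: Cout x (Cin*k*k); b: Cout. Returns (H,W,Cout,N).
// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(const NumericVector& x, const arma::mat& wmat,
                             const arma::vec& b, int k) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int Cout = wmat.n_rows, HW = H * W;
  NumericVector y((size_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(&x[0] + (size_t)n * HW * C, H, W, C, k);
    arma::mat out = wmat * col;          // Cout x HW
    out.each_col() += b;
    double* yn = &y[0] + (size_t)n * HW * Cout;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < HW; ++p) yn[p + (size_t)co * HW] = out(co, p);
  }
  return y;
}

// Backward pass: returns list(dx, dw, db).
// [[Rcpp::export]]
List conv2d_bwd_cpp(const NumericVector& x, const arma::mat& wmat,
                    const NumericVector& dy, int k) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int Cout = wmat.n_rows, HW = H * W;
  NumericVector dx((size_t)HW * C * N);
  dx.attr("dim") = dm;
  arma::mat dw(wmat.n_rows, wmat.n_cols, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(Cout, HW);
    const double* dyp = &dy[0] + (size_t)n * HW * Cout;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < HW; ++p) dyn(co, p) = dyp[p + (size_t)co * HW];
    arma::mat col = im2col(&x[0] + (size_t)n * HW * C, H, W, C, k);
    dw += dyn * col.t();
    db += arma::sum(dyn, 1);
    arma::mat dcol = wmat.t() * dyn;     // R x HW
    col2im_add(&dx[0] + (size_t)n * HW * C, dcol, H, W, C, k);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling (H, W even). Returns pooled tensor and 0-based argmax
// offsets into the input for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(const NumericVector& x) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector amax((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = &x[0] + (size_t)(n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          int base = 2 * h + H * (2 * w);
          int cand[4] = {base, base + 1, base + H, base + H + 1};
          int am = cand[0];
          double best = xc[cand[0]];
          for (int t = 1; t < 4; ++t)
            if (xc[cand[t]] > best) { best = xc[cand[t]]; am = cand[t]; }
          size_t oi = (size_t)(n * C + c) * Ho * Wo + h + Ho * w;
          y[oi] = best;
          amax[oi] = am;
        }
    }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(const NumericVector& dy,
                               const IntegerVector& amax, int H, int W) {
  IntegerVector dm = dy.attr("dim");
  const int Ho = dm[0], Wo = dm[1], C = dm[2], N = dm[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dxc = &dx[0] + (size_t)(n * C + c) * H * W;
      const size_t off = (size_t)(n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t oi = off + h + Ho * w;
          dxc[amax[oi]] += dy[oi];
        }
    }
  return dx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(const NumericVector& x) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = &x[0] + (size_t)(n * C + c) * H * W;
      double* yc = &y[0] + (size_t)(n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          yc[h + Ho * w] = xc[(h / 2) + H * (w / 2)];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(const NumericVector& dy) {
  IntegerVector dm = dy.attr("dim");
  const int Ho = dm[0], Wo = dm[1], C = dm[2], N = dm[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dyc = &dy[0] + (size_t)(n * C + c) * Ho * Wo;
      double* dxc = &dx[0] + (size_t)(n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          dxc[(h / 2) + H * (w / 2)] += dyc[h + Ho * w];
    }
  return dx;
}
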