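// Low-level tensor primitives for the bottleneck-residual networks.
// Activations are R arrays of dim (H, W, C, B), column-major.
// Convolutions use im2col + BLAS gemm; weights are stored as a
// (k*k*Cin_per_group) x Cout matrix whose row order is
// (c_local * k * k) + dw * k + dh, matching im2col below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, bool same) {
  if (same) return (in + stride - 1) / stride;
  return (in - k) / stride + 1;
}

static inline int pad_begin(int in, int out, int k, int stride, bool same) {
  if (!same) return 0;
  int tot = (out - 1) * stride + k - in;
  if (tot < 0) tot = 0;
  return tot / 2;
}

// Gather one image's patches for one channel group into M (P x k*k*cg).
static void im2col(const double* x, int H, int W, int c0, int cg, int C,
                   int k, int stride, int ph, int pw, int Ho, int Wo,
                   arma::mat& M) {
  const long HW = (long)H * W;
  for (int cl = 0; cl < cg; ++cl) {
    const double* xc = x + HW * (c0 + cl);
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = cl * k * k + dw * k + dh;
        double* Mc = M.colptr(col);
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pw + dw;
          bool wok = (iw >= 0 && iw < W);
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - ph + dh;
            double v = 0.0;
            if (wok && ih >= 0 && ih < H) v = xc[(long)iw * H + ih];
            Mc[(long)ow * Ho + oh] = v;
          }
        }
      }
    }
  }
}

// Scatter-add the columns of M back onto the input gradient.
static void col2im_add(const arma::mat& M, double* dx, int H, int W, int c0,
                       int cg, int C, int k, int stride, int ph, int pw,
                       int Ho, int Wo) {
  const long HW = (long)H * W;
  for (int cl = 0; cl < cg; ++cl) {
    double* xc = dx + HW * (c0 + cl);
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = cl * k * k + dw * k + dh;
        const double* Mc = M.colptr(col);
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pw + dw;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - ph + dh;
            if (ih < 0 || ih >= H) continue;
            xc[(long)iw * H + ih] += Mc[(long)ow * Ho + oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2d_forward(NumericVector x, NumericMatrix wmat,
                             NumericVector bias, int k, int stride,
                             bool same, int groups) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Cout = wmat.ncol();
  int cg = C / groups, og = Cout / groups;
  int Ho = out_size(H, k, stride, same);
  int Wo = out_size(W, k, stride, same);
  int ph = pad_begin(H, Ho, k, stride, same);
  int pw = pad_begin(W, Wo, k, stride, same);
  long P = (long)Ho * Wo;

  NumericVector y(P * Cout * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  arma::mat Wm(wmat.begin(), wmat.nrow(), Cout, false);
  arma::mat M(P, (long)k * k * cg);

  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (long)H * W * C * b;
    double* yb = y.begin() + P * Cout * b;
    for (int g = 0; g < groups; ++g) {
      im2col(xb, H, W, g * cg, cg, C, k, stride, ph, pw, Ho, Wo, M);
      arma::mat Yg(yb + P * (long)g * og, P, og, false, true);
      Yg = M * Wm.cols(g * og, (g + 1) * og - 1);
      for (int oc = 0; oc < og; ++oc) Yg.col(oc) += bias[g * og + oc];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2d_backward(NumericVector x, NumericMatrix wmat, NumericVector dy,
                     int k, int stride, bool same, int groups) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Cout = wmat.ncol();
  int cg = C / groups, og = Cout / groups;
  int Ho = out_size(H, k, stride, same);
  int Wo = out_size(W, k, stride, same);
  int ph = pad_begin(H, Ho, k, stride, same);
  int pw = pad_begin(W, Wo, k, stride, same);
  long P = (long)Ho * Wo;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericMatrix dwmat(wmat.nrow(), Cout);
  NumericVector db(Cout);
  arma::mat Wm(wmat.begin(), wmat.nrow(), Cout, false);
  arma::mat dWm(dwmat.begin(), wmat.nrow(), Cout, false, true);
  arma::mat M(P, (long)k * k * cg);

  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (long)H * W * C * b;
    const double* dyb = dy.begin() + P * Cout * b;
    for (int g = 0; g < groups; ++g) {
      im2col(xb, H, W, g * cg, cg, C, k, stride, ph, pw, Ho, Wo, M);
      arma::mat dYg(const_cast<double*>(dyb) + P * (long)g * og, P, og,
                    false, true);
      dWm.cols(g * og, (g + 1) * og - 1) += M.t() * dYg;
      for (int oc = 0; oc < og; ++oc)
        db[g * og + oc] += arma::accu(dYg.col(oc));
      arma::mat dM = dYg * Wm.cols(g * og, (g + 1) * og - 1).t();
      col2im_add(dM, dx.begin() + (long)H * W * C * b, H, W, g * cg, cg, C,
                 k, stride, ph, pw, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwmat, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpoolForward")]]
List maxpool_forward(NumericVector x, int k, int stride, bool same) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Ho = out_size(H, k, stride, same);
  int Wo = out_size(W, k, stride, same);
  int ph = pad_begin(H, Ho, k, stride, same);
  int pw = pad_begin(W, Wo, k, stride, same);

  NumericVector y((long)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  NumericVector amax(y.size());  // 1-based linear index into x

  long oi = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (long)H * W * (c + (long)C * b);
      long base = (long)H * W * (c + (long)C * b);
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          long besti = -1;
          for (int dw = 0; dw < k; ++dw) {
            int iw = ow * stride - pw + dw;
            if (iw < 0 || iw >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              int ih = oh * stride - ph + dh;
              if (ih < 0 || ih >= H) continue;
              double v = xc[(long)iw * H + ih];
              if (v > best) { best = v; besti = base + (long)iw * H + ih; }
            }
          }
          // window fully in padding cannot occur with k > pad
          long idx = (long)b * Ho * Wo * C + (long)c * Ho * Wo +
                     (long)ow * Ho + oh;
          y[idx] = best;
          amax[idx] = (double)(besti + 1);
          ++oi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpoolBackward")]]
NumericVector maxpool_backward(NumericVector dy, NumericVector amax,
                               IntegerVector xdim) {
  long n = (long)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (long i = 0; i < dy.size(); ++i)
    dx[(long)amax[i] - 1] += dy[i];
  return dx;
}
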