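// Low-level numerical kernels for the multitask segmentation/counting network
// and for connected-component labelling of binary masks.
//
// Feature maps cross the R/C++ boundary as 4-d arrays dim(H, W, C, B)
// (column-major, as R stores them). Convolution weights are matrices of
// shape (C_out, C_in * k * k) with patch rows ordered channel-major,
// then kernel column, then kernel row (dh fastest).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Convolutions run in single precision: the GEMM dominates the cost and
// float halves memory traffic; parameters and activations cross the R
// boundary as doubles.

// Gather one sample's im2col matrix: (H*W) x (Cin*k*k).
// 'same' padding with zeros; pad must equal (k-1)/2 for odd k.
static void im2col_sample(const double* x, int H, int W, int Cin, int k,
                          int pad, arma::fmat& Xc) {
  Xc.zeros();
  const int HW = H * W;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int col = c * k * k + dw * k + dh;
        float* out = Xc.colptr(col);
        const int oh = dh - pad, ow = dw - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + ow;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -oh);
          const int i1 = std::min(H, H - oh);  // exclusive
          for (int i = i0; i < i1; ++i)
            out[(size_t)j * H + i] = (float)xc[(size_t)sj * H + i + oh];
        }
      }
    }
  }
}

// Scatter-add the transpose operation of im2col (col2im).
static void col2im_sample(const arma::fmat& Gc, int H, int W, int Cin, int k,
                          int pad, double* gx) {
  const int HW = H * W;
  for (int c = 0; c < Cin; ++c) {
    double* gxc = gx + (size_t)c * HW;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int col = c * k * k + dw * k + dh;
        const float* in = Gc.colptr(col);
        const int oh = dh - pad, ow = dw - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + ow;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -oh);
          const int i1 = std::min(H, H - oh);
          for (int i = i0; i < i1; ++i)
            gxc[(size_t)sj * H + i + oh] += in[(size_t)j * H + i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, IntegerVector dims,
                             const arma::mat& w, const arma::vec& bias,
                             int k, int pad) {
  const int H = dims[0], W = dims[1], Cin = dims[2], B = dims[3];
  const int Cout = w.n_rows;
  const int HW = H * W;
  NumericVector y((size_t)HW * Cout * B);
  const arma::fmat wf = arma::conv_to<arma::fmat>::from(w);
  const arma::frowvec bf =
      arma::conv_to<arma::frowvec>::from(bias.t());
  arma::fmat Xc(HW, Cin * k * k);
  arma::fmat Y(HW, Cout);
  for (int b = 0; b < B; ++b) {
    im2col_sample(x.begin() + (size_t)b * HW * Cin, H, W, Cin, k, pad, Xc);
    Y = Xc * wf.t();
    Y.each_row() += bf;
    double* yp = y.begin() + (size_t)b * HW * Cout;
    const float* yf = Y.memptr();
    for (size_t q = 0; q < (size_t)HW * Cout; ++q) yp[q] = yf[q];
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, IntegerVector dims, const arma::mat& w,
                     NumericVector gy, int k, int pad) {
  const int H = dims[0], W = dims[1], Cin = dims[2], B = dims[3];
  const int Cout = w.n_rows;
  const int HW = H * W;
  NumericVector gx((size_t)HW * Cin * B);
  const arma::fmat wf = arma::conv_to<arma::fmat>::from(w);
  arma::fmat gwf(w.n_rows, w.n_cols, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::fmat Xc(HW, Cin * k * k);
  arma::fmat Gyf(HW, Cout);
  for (int b = 0; b < B; ++b) {
    im2col_sample(x.begin() + (size_t)b * HW * Cin, H, W, Cin, k, pad, Xc);
    const double* gp = gy.begin() + (size_t)b * HW * Cout;
    float* gf = Gyf.memptr();
    for (size_t q = 0; q < (size_t)HW * Cout; ++q) gf[q] = (float)gp[q];
    gwf += Gyf.t() * Xc;
    gb += arma::conv_to<arma::vec>::from(arma::sum(Gyf, 0).t());
    arma::fmat Gc = Gyf * wf;  // (HW) x (Cin*k*k)
    col2im_sample(Gc, H, W, Cin, k, pad, gx.begin() + (size_t)b * HW * Cin);
  }
  gx.attr("dim") = IntegerVector::create(H, W, Cin, B);
  arma::mat gw = arma::conv_to<arma::mat>::from(gwf);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. H and W must be even.
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  const size_t nslice = (size_t)C * B;
  NumericVector y((size_t)Ho * Wo * nslice);
  IntegerVector arg((size_t)Ho * Wo * nslice);  // linear index into input slice
  for (size_t s = 0; s < nslice; ++s) {
    const double* xs = x.begin() + s * H * W;
    double* ys = y.begin() + s * Ho * Wo;
    int* as = arg.begin() + s * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i2 = 2 * i, j2 = 2 * j;
        int best = j2 * H + i2;
        double bv = xs[best];
        const int cand[3] = {j2 * H + i2 + 1, (j2 + 1) * H + i2,
                             (j2 + 1) * H + i2 + 1};
        for (int q = 0; q < 3; ++q)
          if (xs[cand[q]] > bv) { bv = xs[cand[q]]; best = cand[q]; }
        ys[j * Ho + i] = bv;
        as[j * Ho + i] = best;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector gy, IntegerVector arg,
                                IntegerVector dims_in) {
  const int H = dims_in[0], W = dims_in[1], C = dims_in[2], B = dims_in[3];
  const int Ho = H / 2, Wo = W / 2;
  const size_t nslice = (size_t)C * B;
  NumericVector gx((size_t)H * W * nslice);
  for (size_t s = 0; s < nslice; ++s) {
    const double* gys = gy.begin() + s * Ho * Wo;
    const int* as = arg.begin() + s * Ho * Wo;
    double* gxs = gx.begin() + s * H * W;
    for (int t = 0; t < Ho * Wo; ++t) gxs[as[t]] += gys[t];
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export(name = ".upsample2_forward")]]
NumericVector upsample2_forward(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Ho = 2 * H, Wo = 2 * W;
  const size_t nslice = (size_t)C * B;
  NumericVector y((size_t)Ho * Wo * nslice);
  for (size_t s = 0; s < nslice; ++s) {
    const double* xs = x.begin() + s * H * W;
    double* ys = y.begin() + s * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double* xcol = xs + (size_t)(j / 2) * H;
      double* ycol = ys + (size_t)j * Ho;
      for (int i = 0; i < Ho; ++i) ycol[i] = xcol[i / 2];
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
NumericVector upsample2_backward(NumericVector gy, IntegerVector dims_in) {
  const int H = dims_in[0], W = dims_in[1], C = dims_in[2], B = dims_in[3];
  const int Ho = 2 * H, Wo = 2 * W;
  const size_t nslice = (size_t)C * B;
  NumericVector gx((size_t)H * W * nslice);
  for (size_t s = 0; s < nslice; ++s) {
    const double* gys = gy.begin() + s * Ho * Wo;
    double* gxs = gx.begin() + s * H * W;
    for (int j = 0; j < Wo; ++j) {
      const double* gcol = gys + (size_t)j * Ho;
      double* xcol = gxs + (size_t)(j / 2) * H;
      for (int i = 0; i < Ho; ++i) xcol[i / 2] += gcol[i];
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  return gx;
}

// Connected components of a binary matrix by breadth-first search.
// connectivity: 4 or 8. Returns integer label matrix (0 = background).
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  stack.reserve(256);
  const int dh4[4] = {-1, 1, 0, 0}, dw4[4] = {0, 0, -1, 1};
  const int dh8[8] = {-1, 1, 0, 0, -1, -1, 1, 1},
            dw8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dh = connectivity == 8 ? dh8 : dh4;
  const int* dw = connectivity == 8 ? dw8 : dw4;
  const int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      stack.push_back(j * H + i);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int q = 0; q < nn; ++q) {
          const int ni = pi + dh[q], nj = pj + dw[q];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(nj * H + ni);
          }
        }
      }
    }
  }
  return lab;
}
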