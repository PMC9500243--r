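#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as dense matrices with one row per spatial location:
// row index = (n-1)*H*W + (y-1)*W + (x-1) + 1, one column per channel.
// Patch matrices use column index = ((ky-1)*K + (kx-1))*C + c, so conv forward
// is a single GEMM: patches %*% W[(K*K*C) x Cout].
//
// Loops are ordered so that both matrices are walked down columns
// (column-major storage): for each (ky, kx, channel) patch column, output
// rows advance contiguously while input rows advance with the conv stride.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& x, int n, int h, int w,
                         int k, int stride, int pad) {
  const int c = x.ncol();
  const int oh = (h + 2 * pad - k) / stride + 1;
  const int ow = (w + 2 * pad - k) / stride + 1;
  NumericMatrix out(n * oh * ow, k * k * c);
  const double* xp = x.begin();
  double* op = out.begin();
  const size_t xrows = x.nrow();
  const size_t orows = out.nrow();
  for (int ky = 0; ky < k; ++ky) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ch = 0; ch < c; ++ch) {
        double* ocol = op + (size_t)((ky * k + kx) * c + ch) * orows;
        const double* xcol = xp + (size_t)ch * xrows;
        for (int img = 0; img < n; ++img) {
          const size_t xoff = (size_t)img * h * w;
          const size_t ooff = (size_t)img * oh * ow;
          for (int oy = 0; oy < oh; ++oy) {
            const int iy = oy * stride - pad + ky;
            double* orow = ocol + ooff + (size_t)oy * ow;
            if (iy < 0 || iy >= h) continue; // zero padding (matrix init 0)
            const double* xrow = xcol + xoff + (size_t)iy * w;
            int ox = 0;
            int ix = -pad + kx;
            // skip left out-of-range columns
            while (ix < 0 && ox < ow) { ix += stride; ++ox; }
            for (; ox < ow && ix < w; ++ox, ix += stride)
              orow[ox] = xrow[ix];
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add transpose of im2col: accumulates patch gradients back onto the
// input grid. `g` has the shape im2col_cpp would produce for these arguments.
// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& g, int n, int h, int w, int c,
                         int k, int stride, int pad) {
  const int oh = (h + 2 * pad - k) / stride + 1;
  const int ow = (w + 2 * pad - k) / stride + 1;
  NumericMatrix out(n * h * w, c);
  const double* gp = g.begin();
  double* op = out.begin();
  const size_t grows = g.nrow();
  const size_t orows = out.nrow();
  for (int ky = 0; ky < k; ++ky) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ch = 0; ch < c; ++ch) {
        const double* gcol = gp + (size_t)((ky * k + kx) * c + ch) * grows;
        double* ocol = op + (size_t)ch * orows;
        for (int img = 0; img < n; ++img) {
          const size_t goff = (size_t)img * oh * ow;
          const size_t ooff = (size_t)img * h * w;
          for (int oy = 0; oy < oh; ++oy) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= h) continue;
            const double* grow = gcol + goff + (size_t)oy * ow;
            double* orow = ocol + ooff + (size_t)iy * w;
            int ox = 0;
            int ix = -pad + kx;
            while (ix < 0 && ox < ow) { ix += stride; ++ox; }
            for (; ox < ow && ix < w; ++ox, ix += stride)
              orow[ix] += grow[ox];
          }
        }
      }
    }
  }
  return out;
}

// Nearest-neighbour 2x upsample on the row-per-pixel layout.
// [[Rcpp::export]]
NumericMatrix upsample2_cpp(const NumericMatrix& x, int n, int h, int w) {
  const int c = x.ncol();
  const int oh = 2 * h, ow = 2 * w;
  NumericMatrix out(n * oh * ow, c);
  const double* xp = x.begin();
  double* op = out.begin();
  const size_t xrows = x.nrow(), orows = out.nrow();
  for (int ch = 0; ch < c; ++ch) {
    const double* xcol = xp + (size_t)ch * xrows;
    double* ocol = op + (size_t)ch * orows;
    for (int img = 0; img < n; ++img)
      for (int oy = 0; oy < oh; ++oy) {
        const double* xrow = xcol + (size_t)img * h * w + (size_t)(oy / 2) * w;
        double* orow = ocol + (size_t)img * oh * ow + (size_t)oy * ow;
        for (int ox = 0; ox < ow; ++ox) orow[ox] = xrow[ox / 2];
      }
  }
  return out;
}

// Backward of 2x nearest upsample: sum each 2x2 block of output gradients.
// h, w are the *input* (coarse) dims; g lives on the 2h x 2w grid.
// [[Rcpp::export]]
NumericMatrix downsum2_cpp(const NumericMatrix& g, int n, int h, int w) {
  const int c = g.ncol();
  const int oh = 2 * h, ow = 2 * w;
  NumericMatrix out(n * h * w, c);
  const double* gp = g.begin();
  double* op = out.begin();
  const size_t grows = g.nrow(), orows = out.nrow();
  for (int ch = 0; ch < c; ++ch) {
    const double* gcol = gp + (size_t)ch * grows;
    double* ocol = op + (size_t)ch * orows;
    for (int img = 0; img < n; ++img)
      for (int gy = 0; gy < oh; ++gy) {
        const double* grow = gcol + (size_t)img * oh * ow + (size_t)gy * ow;
        double* orow = ocol + (size_t)img * h * w + (size_t)(gy / 2) * w;
        for (int gx = 0; gx < ow; ++gx) orow[gx / 2] += grow[gx];
      }
  }
  return out;
}

// y[i, j] = x[i, j] * s[j] + b[j] : the batchnorm/bias affine applied down
// columns (channels) without R-level sweep() copies.
// [[Rcpp::export]]
NumericMatrix col_scale_add_cpp(const NumericMatrix& x,
                                const NumericVector& s,
                                const NumericVector& b) {
  NumericMatrix out(x.nrow(), x.ncol());
  const double* xp = x.begin();
  double* op = out.begin();
  const size_t nr = x.nrow();
  for (int j = 0; j < x.ncol(); ++j) {
    const double sj = s[j], bj = b[j];
    const double* xc = xp + (size_t)j * nr;
    double* oc = op + (size_t)j * nr;
    for (size_t i = 0; i < nr; ++i) oc[i] = xc[i] * sj + bj;
  }
  return out;
}

// Batchnorm backward core in normalized coordinates:
// out[i, j] = (d[i, j] - v[j] - zhat[i, j] * w[j]) * istd[j]
// [[Rcpp::export]]
NumericMatrix bn_center_scale_cpp(const NumericMatrix& d,
                                  const NumericMatrix& zhat,
                                  const NumericVector& v,
                                  const NumericVector& w,
                                  const NumericVector& istd) {
  NumericMatrix out(d.nrow(), d.ncol());
  const double* dp = d.begin();
  const double* zp = zhat.begin();
  double* op = out.begin();
  const size_t nr = d.nrow();
  for (int j = 0; j < d.ncol(); ++j) {
    const double vj = v[j], wj = w[j], sj = istd[j];
    const double* dc = dp + (size_t)j * nr;
    const double* zc = zp + (size_t)j * nr;
    double* oc = op + (size_t)j * nr;
    for (size_t i = 0; i < nr; ++i) oc[i] = (dc[i] - vj - zc[i] * wj) * sj;
  }
  return out;
}
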