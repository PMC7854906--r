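#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One direct-form-II-transposed filter step applied to a whole row of
// series at once (series index varies fastest, so the inner loops are
// straight-line vectorizable instead of a per-series serial chain).
static void lfilter_rows(const std::vector<double>& b,
                         const std::vector<double>& a,
                         double* w, int nc, int ne, int step,
                         std::vector<double>& z) {
  const int m = (int)a.size() - 1;
  double* zp = z.data();
  std::vector<double> y((size_t)nc);
  double* yp = y.data();
  const double b0 = b[0];
  for (int i = 0; i < ne; ++i) {
    double* xi = w + (size_t)(step > 0 ? i : ne - 1 - i) * nc;
    for (int j = 0; j < nc; ++j) yp[j] = b0 * xi[j] + zp[j];
    for (int k = 0; k < m - 1; ++k) {
      double* zk = zp + (size_t)k * nc;
      const double* zk1 = zk + nc;
      const double bk = b[k + 1], ak = a[k + 1];
      for (int j = 0; j < nc; ++j) zk[j] = zk1[j] + bk * xi[j] - ak * yp[j];
    }
    double* zl = zp + (size_t)(m - 1) * nc;
    const double bm = b[m], am = a[m];
    for (int j = 0; j < nc; ++j) zl[j] = bm * xi[j] - am * yp[j];
    for (int j = 0; j < nc; ++j) xi[j] = yp[j];
  }
}

// Zero-phase (forward-backward) IIR filtering of each column of x.
// zi is the steady-state filter state for a unit-step input; it is scaled
// by the first sample of each pass so start-up transients are suppressed.
// Columns are extended at both ends by odd reflection over `padlen`
// samples before filtering; padlen must be < nrow(x).
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt(NumericVector b, NumericVector a,
                           NumericMatrix x, NumericVector zi, int padlen) {
  const int n = x.nrow(), nc = x.ncol();
  if (padlen >= n) stop("padlen must be smaller than the series length");
  const int m = (int)a.size() - 1;
  if ((int)b.size() != m + 1) stop("b and a must have equal length");
  if ((int)zi.size() != m) stop("zi must have length length(a)-1");
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  const int ne = n + 2 * padlen;
  // transposed working buffer: row i holds sample i of every series
  std::vector<double> w((size_t)ne * nc), z((size_t)m * nc);
  for (int j = 0; j < nc; ++j) {
    const double x0 = x(0, j), xl = x(n - 1, j);
    for (int i = 0; i < padlen; ++i)
      w[(size_t)i * nc + j] = 2.0 * x0 - x(padlen - i, j);
    for (int i = 0; i < n; ++i) w[(size_t)(padlen + i) * nc + j] = x(i, j);
    for (int i = 0; i < padlen; ++i)
      w[(size_t)(padlen + n + i) * nc + j] = 2.0 * xl - x(n - 2 - i, j);
  }
  for (int k = 0; k < m; ++k)
    for (int j = 0; j < nc; ++j) z[(size_t)k * nc + j] = zi[k] * w[j];
  lfilter_rows(bb, aa, w.data(), nc, ne, +1, z);
  const double* last = w.data() + (size_t)(ne - 1) * nc;
  for (int k = 0; k < m; ++k)
    for (int j = 0; j < nc; ++j) z[(size_t)k * nc + j] = zi[k] * last[j];
  lfilter_rows(bb, aa, w.data(), nc, ne, -1, z);
  NumericMatrix out(n, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < n; ++i) out(i, j) = w[(size_t)(padlen + i) * nc + j];
  return out;
}

// Batch-normalization forward over a (m x K) column block: column j is
// one (channel, sample) cell with m spatial positions; mu / inv_std /
// gamma / beta are per-column vectors of length K. Returns y and xhat.
// [[Rcpp::export]]
List cpp_bn_forward(NumericVector x, int m, NumericVector mu,
                    NumericVector inv_std, NumericVector gamma,
                    NumericVector beta) {
  const int K = mu.size();
  NumericVector y((size_t)m * K), xhat((size_t)m * K);
  const double* px = x.begin();
  double* py = y.begin(); double* ph = xhat.begin();
  for (int j = 0; j < K; ++j) {
    const double mj = mu[j], sj = inv_std[j], gj = gamma[j], bj = beta[j];
    const double* xc = px + (size_t)j * m;
    double* yc = py + (size_t)j * m;
    double* hc = ph + (size_t)j * m;
    for (int i = 0; i < m; ++i) {
      double h = (xc[i] - mj) * sj;
      hc[i] = h;
      yc[i] = gj * h + bj;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// Matching backward: dx = (dy - md[j] - xhat * mdx[j]) * ge[j] with
// per-column constants.
// [[Rcpp::export]]
NumericVector cpp_bn_backward(NumericVector dy, NumericVector xhat, int m,
                              NumericVector md, NumericVector mdx,
                              NumericVector ge) {
  const int K = md.size();
  NumericVector dx((size_t)m * K);
  const double* pd = dy.begin(); const double* ph = xhat.begin();
  double* po = dx.begin();
  for (int j = 0; j < K; ++j) {
    const double a = md[j], b = mdx[j], g = ge[j];
    const double* dc = pd + (size_t)j * m;
    const double* hc = ph + (size_t)j * m;
    double* oc = po + (size_t)j * m;
    for (int i = 0; i < m; ++i) oc[i] = (dc[i] - a - hc[i] * b) * g;
  }
  return dx;
}

// Unrolls valid-convolution patches of a [h, w, c, batch] array into a
// matrix of (oh*ow*batch) rows by (kh*kw*c) columns; row index runs over
// output rows fastest, then output columns, then batch; column index over
// kernel rows fastest, then kernel columns, then input channel. This
// matches matrix-multiplying by weights reshaped from [kh, kw, c, cout].
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims, int kh, int kw) {
  const int h = dims[0], w = dims[1], c = dims[2], nb = dims[3];
  const int oh = h - kh + 1, ow = w - kw + 1;
  if (oh < 1 || ow < 1) stop("kernel larger than input");
  NumericMatrix col(oh * ow * nb, kh * kw * c);
  const double* px = x.begin();
  for (int ci = 0; ci < c; ++ci)
    for (int kx = 0; kx < kw; ++kx)
      for (int ky = 0; ky < kh; ++ky) {
        const int jcol = ci * kh * kw + kx * kh + ky;
        double* pc = &col(0, jcol);
        for (int b = 0; b < nb; ++b) {
          const double* base = px + (size_t)b * h * w * c + (size_t)ci * h * w;
          for (int ox = 0; ox < ow; ++ox) {
            const double* src = base + (size_t)(ox + kx) * h + ky;
            double* dst = pc + (size_t)b * oh * ow + (size_t)ox * oh;
            for (int oy = 0; oy < oh; ++oy) dst[oy] = src[oy];
          }
        }
      }
  return col;
}

// Adjoint of cpp_im2col: scatter-adds patch gradients back onto the
// [h, w, c, batch] input gradient.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix col, IntegerVector dims, int kh, int kw) {
  const int h = dims[0], w = dims[1], c = dims[2], nb = dims[3];
  const int oh = h - kh + 1, ow = w - kw + 1;
  NumericVector dx((size_t)h * w * c * nb);
  double* px = dx.begin();
  for (int ci = 0; ci < c; ++ci)
    for (int kx = 0; kx < kw; ++kx)
      for (int ky = 0; ky < kh; ++ky) {
        const int jcol = ci * kh * kw + kx * kh + ky;
        const double* pc = &col(0, jcol);
        for (int b = 0; b < nb; ++b) {
          double* base = px + (size_t)b * h * w * c + (size_t)ci * h * w;
          for (int ox = 0; ox < ow; ++ox) {
            double* dst = base + (size_t)(ox + kx) * h + ky;
            const double* src = pc + (size_t)b * oh * ow + (size_t)ox * oh;
            for (int oy = 0; oy < oh; ++oy) dst[oy] += src[oy];
          }
        }
      }
  dx.attr("dim") = dims;
  return dx;
}

// 2x2 max pooling with stride 2 in ceil mode (a trailing odd row/column
// forms its own pool). Returns the pooled array and 1-based argmax
// indices into the input for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x, IntegerVector dims) {
  const int h = dims[0], w = dims[1], c = dims[2], nb = dims[3];
  const int oh = (h + 1) / 2, ow = (w + 1) / 2;
  NumericVector out((size_t)oh * ow * c * nb);
  IntegerVector arg((size_t)oh * ow * c * nb);
  const double* px = x.begin();
  size_t o = 0;
  for (int b = 0; b < nb; ++b)
    for (int ci = 0; ci < c; ++ci) {
      const size_t plane = (size_t)b * h * w * c + (size_t)ci * h * w;
      for (int ox = 0; ox < ow; ++ox)
        for (int oy = 0; oy < oh; ++oy) {
          double best = R_NegInf;
          size_t bi = 0;
          for (int dx2 = 0; dx2 < 2; ++dx2) {
            int xx = 2 * ox + dx2;
            if (xx >= w) continue;
            for (int dy = 0; dy < 2; ++dy) {
              int yy = 2 * oy + dy;
              if (yy >= h) continue;
              size_t idx = plane + (size_t)xx * h + yy;
              if (px[idx] > best) { best = px[idx]; bi = idx; }
            }
          }
          // output layout [oh, ow, c, batch]
          size_t oidx = (size_t)b * oh * ow * c + (size_t)ci * oh * ow +
                        (size_t)ox * oh + oy;
          out[oidx] = best;
          arg[oidx] = (int)bi + 1;
          ++o;
        }
    }
  out.attr("dim") = IntegerVector::create(oh, ow, c, nb);
  arg.attr("dim") = IntegerVector::create(oh, ow, c, nb);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dout, IntegerVector argmax,
                                    IntegerVector in_dims) {
  size_t n = (size_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[argmax[i] - 1] += dout[i];
  dx.attr("dim") = in_dims;
  return dx;
}

// Full valid 3x3 convolution forward: x [h,w,c,B] -> out [oh,ow,cout,B],
// via an internal im2col patch matrix (returned for the backward pass).
// [[Rcpp::export]]
List cpp_conv_forward(NumericVector x, IntegerVector dims, NumericMatrix W,
                      NumericVector bias) {
  const int h = dims[0], w = dims[1], c = dims[2], nb = dims[3];
  const int kh = 3, kw = 3;
  const int oh = h - 2, ow = w - 2, cout = W.ncol();
  arma::mat col((size_t)oh * ow * nb, (size_t)kh * kw * c);
  const double* px = x.begin();
  for (int ci = 0; ci < c; ++ci)
    for (int kx = 0; kx < kw; ++kx)
      for (int ky = 0; ky < kh; ++ky) {
        double* pc = col.colptr(ci * kh * kw + kx * kh + ky);
        for (int b = 0; b < nb; ++b) {
          const double* base = px + (size_t)b * h * w * c + (size_t)ci * h * w;
          for (int ox = 0; ox < ow; ++ox) {
            const double* src = base + (size_t)(ox + kx) * h + ky;
            double* dst = pc + (size_t)b * oh * ow + (size_t)ox * oh;
            for (int oy = 0; oy < oh; ++oy) dst[oy] = src[oy];
          }
        }
      }
  const arma::mat Wm(const_cast<double*>(W.begin()), W.nrow(), W.ncol(),
                     false, true);
  arma::mat om = col * Wm; // rows ordered (oy, ox, b)
  NumericVector out((size_t)oh * ow * cout * nb);
  double* po = out.begin();
  for (int co = 0; co < cout; ++co) {
    const double* src = om.colptr(co);
    const double bv = bias[co];
    for (int b = 0; b < nb; ++b) {
      double* dst = po + (size_t)b * oh * ow * cout + (size_t)co * oh * ow;
      const double* s = src + (size_t)b * oh * ow;
      for (int i = 0; i < oh * ow; ++i) dst[i] = s[i] + bv;
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, cout, nb);
  return List::create(_["out"] = out, _["col"] = col);
}

// Backward of cpp_conv_forward. dout [oh,ow,cout,B]; returns dW, db and
// (unless skipped for the first layer) dx [h,w,c,B].
// [[Rcpp::export]]
List cpp_conv_backward(NumericMatrix col, IntegerVector dims,
                       NumericMatrix W, NumericVector dout, bool need_dx) {
  const int h = dims[0], w = dims[1], c = dims[2], nb = dims[3];
  const int kh = 3, kw = 3;
  const int oh = h - 2, ow = w - 2, cout = W.ncol();
  // reorder dout [oh,ow,cout,B] -> matrix rows (oy,ox,b) x cout
  arma::mat dom((size_t)oh * ow * nb, cout);
  const double* pd = dout.begin();
  for (int co = 0; co < cout; ++co) {
    double* dst = dom.colptr(co);
    for (int b = 0; b < nb; ++b) {
      const double* src = pd + (size_t)b * oh * ow * cout + (size_t)co * oh * ow;
      double* d2 = dst + (size_t)b * oh * ow;
      for (int i = 0; i < oh * ow; ++i) d2[i] = src[i];
    }
  }
  const arma::mat colm(const_cast<double*>(col.begin()), col.nrow(),
                       col.ncol(), false, true);
  const arma::mat Wm(const_cast<double*>(W.begin()), W.nrow(), W.ncol(),
                     false, true);
  arma::mat dW = colm.t() * dom;
  arma::rowvec db = arma::sum(dom, 0);
  List out = List::create(_["dW"] = wrap(dW),
                          _["db"] = NumericVector(db.begin(), db.end()));
  if (need_dx) {
    arma::mat dcol = dom * Wm.t();
    NumericVector dx((size_t)h * w * c * nb);
    double* px = dx.begin();
    for (int ci = 0; ci < c; ++ci)
      for (int kx = 0; kx < kw; ++kx)
        for (int ky = 0; ky < kh; ++ky) {
          const double* pc = dcol.colptr(ci * kh * kw + kx * kh + ky);
          for (int b = 0; b < nb; ++b) {
            double* base = px + (size_t)b * h * w * c + (size_t)ci * h * w;
            for (int ox = 0; ox < ow; ++ox) {
              double* dst = base + (size_t)(ox + kx) * h + ky;
              const double* src = pc + (size_t)b * oh * ow + (size_t)ox * oh;
              for (int oy = 0; oy < oh; ++oy) dst[oy] += src[oy];
            }
          }
        }
    dx.attr("dim") = dims;
    out["dx"] = dx;
  }
  return out;
}
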