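// Convolution / resampling kernels backing the autodiff ops.
//
// Tensor layout everywhere: numeric array with dim c(H, W, C, B),
// column-major, so each (c, b) spatial plane is contiguous.
// Dense convolutions go through im2col + BLAS gemm; the column buffer is
// chunked over output pixels so wide layers never materialise multi-GB
// intermediates. Depthwise convolutions are direct loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword idx4(arma::uword h, arma::uword w, arma::uword c,
                               arma::uword b, arma::uword H, arma::uword W,
                               arma::uword C) {
  return h + H * (w + W * (c + C * b));
}

// im2col buffer layout: rows = output pixels of one sample (p = ho + Ho*wo),
// cols = K = c*kh*kw + ki*kw + kj. Filling iterates k outer / p inner so both
// the read from x and the write to the buffer stream contiguously for
// stride-1 convolutions.
static void fill_colN(const double* x, arma::mat& col, arma::uword p0,
                      arma::uword p1, arma::uword H, arma::uword W,
                      arma::uword C, arma::uword b, int kh, int kw, int stride,
                      int pad, arma::uword Ho, arma::uword Wo) {
  arma::uword ho0 = p0 % Ho, wo0 = p0 / Ho;
  for (arma::uword c = 0; c < C; ++c) {
    const double* xc = x + idx4(0, 0, c, b, H, W, C);
    for (int ki = 0; ki < kh; ++ki)
      for (int kj = 0; kj < kw; ++kj) {
        double* dst = col.colptr(c * kh * kw + ki * kw + kj);
        arma::uword ho = ho0, wo = wo0;
        for (arma::uword p = p0; p < p1; ++p) {
          int hi = (int)ho * stride - pad + ki;
          int wi = (int)wo * stride - pad + kj;
          dst[p - p0] = (hi >= 0 && hi < (int)H && wi >= 0 && wi < (int)W)
                            ? xc[hi + H * wi]
                            : 0.0;
          if (++ho == Ho) { ho = 0; ++wo; }
        }
      }
  }
}

static void scatter_colN(double* dx, const arma::mat& col, arma::uword p0,
                         arma::uword p1, arma::uword H, arma::uword W,
                         arma::uword C, arma::uword b, int kh, int kw,
                         int stride, int pad, arma::uword Ho, arma::uword Wo) {
  arma::uword ho0 = p0 % Ho, wo0 = p0 / Ho;
  for (arma::uword c = 0; c < C; ++c) {
    double* xc = dx + idx4(0, 0, c, b, H, W, C);
    for (int ki = 0; ki < kh; ++ki)
      for (int kj = 0; kj < kw; ++kj) {
        const double* src = col.colptr(c * kh * kw + ki * kw + kj);
        arma::uword ho = ho0, wo = wo0;
        for (arma::uword p = p0; p < p1; ++p) {
          int hi = (int)ho * stride - pad + ki;
          int wi = (int)wo * stride - pad + kj;
          if (hi >= 0 && hi < (int)H && wi >= 0 && wi < (int)W)
            xc[hi + H * wi] += src[p - p0];
          if (++ho == Ho) { ho = 0; ++wo; }
        }
      }
  }
}

static arma::uword chunk_rows(arma::uword K) {
  // cap the column buffer around 128 MB
  arma::uword n = (arma::uword)(16e6 / (double)K);
  return std::max<arma::uword>(n, 64);
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericMatrix wmat,
                             NumericVector bias, int kh, int kw, int stride,
                             int pad) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], B = d[3];
  arma::uword Ho = (H + 2 * pad - kh) / stride + 1;
  arma::uword Wo = (W + 2 * pad - kw) / stride + 1;
  arma::uword Cout = wmat.nrow(), K = wmat.ncol(), N = Ho * Wo;
  if (K != C * (arma::uword)(kh * kw)) stop("conv2d: weight/input mismatch");
  arma::mat wm(wmat.begin(), Cout, K, false);
  NumericVector out(Ho * Wo * Cout * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  bool has_b = bias.size() > 0;
  arma::vec bv = has_b ? arma::vec(bias.begin(), Cout) : arma::vec();
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    // 1x1: each sample's (HW x C) slab multiplies the weights directly
    for (arma::uword b = 0; b < B; ++b) {
      arma::mat xs(const_cast<double*>(x.begin()) + idx4(0, 0, 0, b, H, W, C),
                   N, C, false);
      arma::mat os(out.begin() + (arma::uword)N * Cout * b, N, Cout, false,
                   true);
      os = xs * wm.t();
      if (has_b) os.each_row() += bv.t();
    }
    return out;
  }
  if (stride == 1) {
    // tap-wise gemms: for every kernel offset, a contiguous copy of the
    // shifted input block multiplies the (C x Cout) weight slice; padding
    // falls out of the clipped ranges (outside contributions are zero).
    arma::mat wtap(C, Cout);
    for (arma::uword b = 0; b < B; ++b) {
      arma::cube xc(const_cast<double*>(x.begin()) + idx4(0, 0, 0, b, H, W, C),
                    H, W, C, false);
      arma::cube oc(out.begin() + (arma::uword)N * Cout * b, Ho, Wo, Cout,
                    false, true);
      for (int ki = 0; ki < kh; ++ki)
        for (int kj = 0; kj < kw; ++kj) {
          int dh = ki - pad, dw2 = kj - pad;
          int ho_lo = std::max(0, -dh), ho_hi = std::min((int)Ho, (int)H - dh);
          int wo_lo = std::max(0, -dw2), wo_hi = std::min((int)Wo, (int)W - dw2);
          if (ho_lo >= ho_hi || wo_lo >= wo_hi) continue;
          arma::uword nh = ho_hi - ho_lo, nw = wo_hi - wo_lo;
          for (arma::uword c = 0; c < C; ++c)
            for (arma::uword co = 0; co < Cout; ++co)
              wtap(c, co) = wm(co, c * kh * kw + ki * kw + kj);
          arma::cube xs = xc.subcube(ho_lo + dh, wo_lo + dw2, 0,
                                     ho_hi - 1 + dh, wo_hi - 1 + dw2, C - 1);
          arma::mat xm(xs.memptr(), nh * nw, C, false);
          arma::mat om = xm * wtap;  // (nh*nw x Cout)
          arma::cube omc(om.memptr(), nh, nw, Cout, false);
          oc.subcube(ho_lo, wo_lo, 0, ho_hi - 1, wo_hi - 1, Cout - 1) += omc;
        }
      if (has_b)
        for (arma::uword co = 0; co < Cout; ++co) oc.slice(co) += bv[co];
    }
    return out;
  }
  arma::uword CH = std::min(chunk_rows(K), N);
  arma::mat col(CH, K);
  for (arma::uword b = 0; b < B; ++b) {
    for (arma::uword p0 = 0; p0 < N; p0 += CH) {
      arma::uword p1 = std::min(p0 + CH, N);
      if (p1 - p0 != col.n_rows) col.set_size(p1 - p0, K);
      fill_colN(x.begin(), col, p0, p1, H, W, C, b, kh, kw, stride, pad, Ho, Wo);
      arma::mat o = col * wm.t();  // (n x Cout)
      for (arma::uword c = 0; c < Cout; ++c) {
        double* dst = out.begin() + idx4(0, 0, c, b, Ho, Wo, Cout);
        const double* src = o.colptr(c);
        double bb = has_b ? bv[c] : 0.0;
        for (arma::uword p = p0; p < p1; ++p) dst[p] = src[p - p0] + bb;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericMatrix wmat, NumericVector dy,
                    int kh, int kw, int stride, int pad, bool need_dx) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], B = d[3];
  IntegerVector dd = dy.attr("dim");
  arma::uword Ho = dd[0], Wo = dd[1], Cout = dd[2];
  arma::uword K = wmat.ncol(), N = Ho * Wo;
  arma::mat wm(wmat.begin(), Cout, K, false);
  arma::mat dwt(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = x.attr("dim");
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    for (arma::uword b = 0; b < B; ++b) {
      arma::mat xs(const_cast<double*>(x.begin()) + idx4(0, 0, 0, b, H, W, C),
                   N, C, false);
      arma::mat gs(const_cast<double*>(dy.begin()) + (arma::uword)N * Cout * b,
                   N, Cout, false);
      dwt += xs.t() * gs;
      db += arma::sum(gs, 0).t();
      if (need_dx) {
        arma::mat dxs(dx.begin() + idx4(0, 0, 0, b, H, W, C), N, C, false,
                      true);
        dxs = gs * wm;
      }
    }
    return List::create(_["dw"] = wrap(arma::mat(dwt.t())),
                        _["db"] = wrap(db), _["dx"] = dx);
  }
  if (stride == 1) {
    arma::mat wtap(C, Cout);
    for (arma::uword b = 0; b < B; ++b) {
      arma::cube xc(const_cast<double*>(x.begin()) + idx4(0, 0, 0, b, H, W, C),
                    H, W, C, false);
      arma::cube gc(const_cast<double*>(dy.begin()) + (arma::uword)N * Cout * b,
                    Ho, Wo, Cout, false);
      for (arma::uword co = 0; co < Cout; ++co)
        db[co] += arma::accu(gc.slice(co));
      for (int ki = 0; ki < kh; ++ki)
        for (int kj = 0; kj < kw; ++kj) {
          int dh = ki - pad, dw2 = kj - pad;
          int ho_lo = std::max(0, -dh), ho_hi = std::min((int)Ho, (int)H - dh);
          int wo_lo = std::max(0, -dw2), wo_hi = std::min((int)Wo, (int)W - dw2);
          if (ho_lo >= ho_hi || wo_lo >= wo_hi) continue;
          arma::uword nh = ho_hi - ho_lo, nw = wo_hi - wo_lo;
          arma::cube xs = xc.subcube(ho_lo + dh, wo_lo + dw2, 0,
                                     ho_hi - 1 + dh, wo_hi - 1 + dw2, C - 1);
          arma::mat xm(xs.memptr(), nh * nw, C, false);
          arma::cube gs = gc.subcube(ho_lo, wo_lo, 0, ho_hi - 1, wo_hi - 1,
                                     Cout - 1);
          arma::mat gm(gs.memptr(), nh * nw, Cout, false);
          arma::mat T = xm.t() * gm;  // C x Cout
          for (arma::uword c = 0; c < C; ++c)
            for (arma::uword co = 0; co < Cout; ++co)
              dwt(c * kh * kw + ki * kw + kj, co) += T(c, co);
          if (need_dx) {
            for (arma::uword c = 0; c < C; ++c)
              for (arma::uword co = 0; co < Cout; ++co)
                wtap(c, co) = wm(co, c * kh * kw + ki * kw + kj);
            arma::mat dxm = gm * wtap.t();  // (nh*nw x C)
            arma::cube dxmc(dxm.memptr(), nh, nw, C, false);
            arma::cube dxc(dx.begin() + idx4(0, 0, 0, b, H, W, C), H, W, C,
                           false, true);
            dxc.subcube(ho_lo + dh, wo_lo + dw2, 0, ho_hi - 1 + dh,
                        wo_hi - 1 + dw2, C - 1) += dxmc;
          }
        }
    }
    return List::create(_["dw"] = wrap(arma::mat(dwt.t())), _["db"] = wrap(db),
                        _["dx"] = dx);
  }
  arma::uword CH = std::min(chunk_rows(K), N);
  arma::mat col(CH, K);
  for (arma::uword b = 0; b < B; ++b) {
    for (arma::uword p0 = 0; p0 < N; p0 += CH) {
      arma::uword p1 = std::min(p0 + CH, N);
      arma::uword n = p1 - p0;
      if (n != col.n_rows) col.set_size(n, K);
      fill_colN(x.begin(), col, p0, p1, H, W, C, b, kh, kw, stride, pad, Ho, Wo);
      arma::mat dO(n, Cout);
      for (arma::uword c = 0; c < Cout; ++c) {
        const double* src = dy.begin() + idx4(0, 0, c, b, Ho, Wo, Cout);
        double* dst = dO.colptr(c);
        double acc = 0.0;
        for (arma::uword p = p0; p < p1; ++p) {
          dst[p - p0] = src[p];
          acc += src[p];
        }
        db[c] += acc;
      }
      dwt += col.t() * dO;
      if (need_dx) {
        arma::mat dcol = dO * wm;  // n x K
        scatter_colN(dx.begin(), dcol, p0, p1, H, W, C, b, kh, kw, stride, pad,
                     Ho, Wo);
      }
    }
  }
  return List::create(_["dw"] = wrap(arma::mat(dwt.t())), _["db"] = wrap(db),
                      _["dx"] = dx);
}

// Depthwise convolution, depth multiplier 1. w: array (kh, kw, C).
// [[Rcpp::export]]
NumericVector dwconv2d_fwd_cpp(NumericVector x, NumericVector w, int kh,
                               int kw, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], B = d[3];
  arma::uword Ho = (H + 2 * pad - kh) / stride + 1;
  arma::uword Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector out(Ho * Wo * C * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  if (stride == 1) {
    // tap-wise shifted-plane accumulation: contiguous reads and writes
    for (arma::uword b = 0; b < B; ++b)
      for (arma::uword c = 0; c < C; ++c) {
        const double* xc = x.begin() + idx4(0, 0, c, b, H, W, C);
        const double* wc = w.begin() + (arma::uword)(kh * kw) * c;
        double* oc = out.begin() + idx4(0, 0, c, b, Ho, Wo, C);
        for (int ki = 0; ki < kh; ++ki)
          for (int kj = 0; kj < kw; ++kj) {
            double wgt = wc[ki + kh * kj];
            int dh = ki - pad, dw2 = kj - pad;
            arma::uword ho_lo = std::max(0, -dh), ho_hi = std::min((int)Ho, (int)H - dh);
            arma::uword wo_lo = std::max(0, -dw2), wo_hi = std::min((int)Wo, (int)W - dw2);
            for (arma::uword wo = wo_lo; wo < wo_hi; ++wo) {
              const double* xs = xc + (ho_lo + dh) + H * (wo + dw2);
              double* os = oc + ho_lo + Ho * wo;
              for (arma::uword hh = ho_lo; hh < ho_hi; ++hh)
                *os++ += wgt * *xs++;
            }
          }
      }
    return out;
  }
  for (arma::uword b = 0; b < B; ++b)
    for (arma::uword c = 0; c < C; ++c) {
      const double* xc = x.begin() + idx4(0, 0, c, b, H, W, C);
      const double* wc = w.begin() + (arma::uword)(kh * kw) * c;
      double* oc = out.begin() + idx4(0, 0, c, b, Ho, Wo, C);
      for (arma::uword wo = 0; wo < Wo; ++wo)
        for (arma::uword ho = 0; ho < Ho; ++ho) {
          int hi0 = (int)ho * stride - pad, wi0 = (int)wo * stride - pad;
          double acc = 0.0;
          for (int kj = 0; kj < kw; ++kj) {
            int wi = wi0 + kj;
            if (wi < 0 || wi >= (int)W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int hi = hi0 + ki;
              if (hi < 0 || hi >= (int)H) continue;
              acc += xc[hi + H * wi] * wc[ki + kh * kj];
            }
          }
          oc[ho + Ho * wo] = acc;
        }
    }
  return out;
}

// [[Rcpp::export]]
List dwconv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                      int kh, int kw, int stride, int pad, bool need_dx) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], B = d[3];
  IntegerVector dd = dy.attr("dim");
  arma::uword Ho = dd[0], Wo = dd[1];
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = x.attr("dim");
  if (stride == 1) {
    for (arma::uword b = 0; b < B; ++b)
      for (arma::uword c = 0; c < C; ++c) {
        const double* xc = x.begin() + idx4(0, 0, c, b, H, W, C);
        const double* wc = w.begin() + (arma::uword)(kh * kw) * c;
        const double* gc = dy.begin() + idx4(0, 0, c, b, Ho, Wo, C);
        double* dwc = dw.begin() + (arma::uword)(kh * kw) * c;
        double* dxc = need_dx ? dx.begin() + idx4(0, 0, c, b, H, W, C) : nullptr;
        for (int ki = 0; ki < kh; ++ki)
          for (int kj = 0; kj < kw; ++kj) {
            double wgt = wc[ki + kh * kj];
            int dh = ki - pad, dw2 = kj - pad;
            arma::uword ho_lo = std::max(0, -dh), ho_hi = std::min((int)Ho, (int)H - dh);
            arma::uword wo_lo = std::max(0, -dw2), wo_hi = std::min((int)Wo, (int)W - dw2);
            double acc = 0.0;
            for (arma::uword wo = wo_lo; wo < wo_hi; ++wo) {
              const double* xs = xc + (ho_lo + dh) + H * (wo + dw2);
              const double* gs = gc + ho_lo + Ho * wo;
              double* dxs = need_dx ? dxc + (ho_lo + dh) + H * (wo + dw2) : nullptr;
              for (arma::uword hh = ho_lo; hh < ho_hi; ++hh) {
                double g = *gs++;
                acc += g * *xs++;
                if (need_dx) *dxs++ += wgt * g;
              }
            }
            dwc[ki + kh * kj] += acc;
          }
      }
    return List::create(_["dw"] = dw, _["dx"] = dx);
  }
  for (arma::uword b = 0; b < B; ++b)
    for (arma::uword c = 0; c < C; ++c) {
      const double* xc = x.begin() + idx4(0, 0, c, b, H, W, C);
      const double* wc = w.begin() + (arma::uword)(kh * kw) * c;
      const double* gc = dy.begin() + idx4(0, 0, c, b, Ho, Wo, C);
      double* dwc = dw.begin() + (arma::uword)(kh * kw) * c;
      double* dxc = need_dx ? dx.begin() + idx4(0, 0, c, b, H, W, C) : nullptr;
      for (arma::uword wo = 0; wo < Wo; ++wo)
        for (arma::uword ho = 0; ho < Ho; ++ho) {
          double g = gc[ho + Ho * wo];
          if (g == 0.0) continue;
          int hi0 = (int)ho * stride - pad, wi0 = (int)wo * stride - pad;
          for (int kj = 0; kj < kw; ++kj) {
            int wi = wi0 + kj;
            if (wi < 0 || wi >= (int)W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int hi = hi0 + ki;
              if (hi < 0 || hi >= (int)H) continue;
              dwc[ki + kh * kj] += g * xc[hi + H * wi];
              if (need_dx) dxc[hi + H * wi] += g * wc[ki + kh * kj];
            }
          }
        }
    }
  return List::create(_["dw"] = dw, _["dx"] = dx);
}

// Bilinear resize (half-pixel centers, zoom-out clamped at borders).
// Weights are a pure function of the geometry, so backward is the exact
// transpose scatter of forward.
static inline void src_coord(arma::uword o, arma::uword Ho, arma::uword Hi,
                             arma::uword& i0, arma::uword& i1, double& t) {
  double s = ((double)o + 0.5) * (double)Hi / (double)Ho - 0.5;
  if (s < 0) s = 0;
  if (s > (double)(Hi - 1)) s = (double)(Hi - 1);
  i0 = (arma::uword)std::floor(s);
  i1 = std::min(i0 + 1, Hi - 1);
  t = s - (double)i0;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_cpp(NumericVector x, int Ho_, int Wo_) {
  IntegerVector d = x.attr("dim");
  arma::uword H = d[0], W = d[1], C = d[2], B = d[3];
  arma::uword Ho = Ho_, Wo = Wo_;
  NumericVector out(Ho * Wo * C * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  std::vector<arma::uword> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> th(Ho), tw(Wo);
  for (arma::uword i = 0; i < Ho; ++i) src_coord(i, Ho, H, h0[i], h1[i], th[i]);
  for (arma::uword j = 0; j < Wo; ++j) src_coord(j, Wo, W, w0[j], w1[j], tw[j]);
  for (arma::uword b = 0; b < B; ++b)
    for (arma::uword c = 0; c < C; ++c) {
      const double* xc = x.begin() + idx4(0, 0, c, b, H, W, C);
      double* oc = out.begin() + idx4(0, 0, c, b, Ho, Wo, C);
      for (arma::uword j = 0; j < Wo; ++j)
        for (arma::uword i = 0; i < Ho; ++i) {
          double a = xc[h0[i] + H * w0[j]], bb = xc[h1[i] + H * w0[j]];
          double cc = xc[h0[i] + H * w1[j]], dd2 = xc[h1[i] + H * w1[j]];
          double top = a + th[i] * (bb - a), bot = cc + th[i] * (dd2 - cc);
          oc[i + Ho * j] = top + tw[j] * (bot - top);
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_bwd_cpp(NumericVector dy, int Hi_, int Wi_) {
  IntegerVector d = dy.attr("dim");
  arma::uword Ho = d[0], Wo = d[1], C = d[2], B = d[3];
  arma::uword H = Hi_, W = Wi_;
  NumericVector dx(H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  std::vector<arma::uword> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> th(Ho), tw(Wo);
  for (arma::uword i = 0; i < Ho; ++i) src_coord(i, Ho, H, h0[i], h1[i], th[i]);
  for (arma::uword j = 0; j < Wo; ++j) src_coord(j, Wo, W, w0[j], w1[j], tw[j]);
  for (arma::uword b = 0; b < B; ++b)
    for (arma::uword c = 0; c < C; ++c) {
      double* xc = dx.begin() + idx4(0, 0, c, b, H, W, C);
      const double* gc = dy.begin() + idx4(0, 0, c, b, Ho, Wo, C);
      for (arma::uword j = 0; j < Wo; ++j)
        for (arma::uword i = 0; i < Ho; ++i) {
          double g = gc[i + Ho * j];
          double wt = tw[j], ht = th[i];
          xc[h0[i] + H * w0[j]] += g * (1 - ht) * (1 - wt);
          xc[h1[i] + H * w0[j]] += g * ht * (1 - wt);
          xc[h0[i] + H * w1[j]] += g * (1 - ht) * wt;
          xc[h1[i] + H * w1[j]] += g * ht * wt;
        }
    }
  return dx;
}

// ---- fused batch-norm helpers ---------------------------------------------

// y[.,.,c,b] = x * scale[c] + shift[c]
// [[Rcpp::export]]
NumericVector chan_affine_cpp(NumericVector x, NumericVector scale,
                              NumericVector shift) {
  IntegerVector d = x.attr("dim");
  arma::uword HW = (arma::uword)d[0] * d[1], C = d[2], B = d[3];
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* op = out.begin();
  for (arma::uword b = 0; b < B; ++b)
    for (arma::uword c = 0; c < C; ++c) {
      double s = scale[c], t = shift[c];
      for (arma::uword i = 0; i < HW; ++i, ++xp, ++op) *op = *xp * s + t;
    }
  return out;
}

// Per-channel sums of g and of g * xhat, and (optionally) the fused
// training-mode input gradient; xhat = (x - mu[c]) / sd[c].
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector x, NumericVector g, NumericVector mu,
                NumericVector sd, NumericVector scale, bool training,
                bool need_dx) {
  IntegerVector d = x.attr("dim");
  arma::uword HW = (arma::uword)d[0] * d[1], C = d[2], B = d[3];
  arma::vec s_g(C, arma::fill::zeros), s_gx(C, arma::fill::zeros);
  const double* xp = x.begin();
  const double* gp = g.begin();
  for (arma::uword b = 0; b < B; ++b)
    for (arma::uword c = 0; c < C; ++c) {
      double m = mu[c], is = 1.0 / sd[c], a1 = 0, a2 = 0;
      for (arma::uword i = 0; i < HW; ++i, ++xp, ++gp) {
        a1 += *gp;
        a2 += *gp * (*xp - m) * is;
      }
      s_g[c] += a1;
      s_gx[c] += a2;
    }
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) {
    dx.attr("dim") = x.attr("dim");
    double N = (double)(HW * B);
    xp = x.begin(); gp = g.begin();
    double* dp = dx.begin();
    for (arma::uword b = 0; b < B; ++b)
      for (arma::uword c = 0; c < C; ++c) {
        double m = mu[c], is = 1.0 / sd[c], sc = scale[c];
        double mg = s_g[c] / N, mgx = s_gx[c] / N;
        for (arma::uword i = 0; i < HW; ++i, ++xp, ++gp, ++dp)
          *dp = training ? (*gp - mg - (*xp - m) * is * mgx) * sc
                         : *gp * sc;
      }
  }
  return List::create(_["s_g"] = wrap(s_g), _["s_gx"] = wrap(s_gx),
                      _["dx"] = dx);
}
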