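// Low-level numerical kernels for the encoder-decoder backbone and the
// surface-distance metric. Activations are dense column-major arrays with
// dim (H, W, C, B); convolution weights have dim (K, K, Cin, Cout) so that
// the flattened filter matrix is (K*K*Cin) x Cout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& B) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, B)");
  H = d[0]; W = d[1]; C = d[2]; B = d[3];
}

// colT(i + H*j, r) with r = k1 + K*(k2 + K*c) holds x[i + k1 - pad, j + k2 - pad, c];
// the transposed layout keeps both reads and writes contiguous.
static void im2colT(const double* x, int H, int W, int C, int K, int pad, arma::mat& colT) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int k2 = 0; k2 < K; ++k2) {
      for (int k1 = 0; k1 < K; ++k1) {
        const int r = k1 + K * (k2 + K * c);
        double* dst = colT.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int jj = j + k2 - pad;
          double* dcol = dst + (size_t)H * j;
          if (jj < 0 || jj >= W) {
            std::fill(dcol, dcol + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * jj;
          const int lo = std::max(0, pad - k1);           // i with ii >= 0
          const int hi = std::min(H, H + pad - k1);       // i with ii < H
          for (int i = 0; i < lo; ++i) dcol[i] = 0.0;
          for (int i = lo; i < hi; ++i) dcol[i] = src[i + k1 - pad];
          for (int i = hi; i < H; ++i) dcol[i] = 0.0;
        }
      }
    }
  }
}

static void col2imT_acc(const arma::mat& colT, int H, int W, int C, int K, int pad, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int k2 = 0; k2 < K; ++k2) {
      for (int k1 = 0; k1 < K; ++k1) {
        const int r = k1 + K * (k2 + K * c);
        const double* src0 = colT.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int jj = j + k2 - pad;
          if (jj < 0 || jj >= W) continue;
          const double* scol = src0 + (size_t)H * j;
          double* dcol = xc + (size_t)H * jj;
          const int lo = std::max(0, pad - k1);
          const int hi = std::min(H, H + pad - k1);
          for (int i = lo; i < hi; ++i) dcol[i + k1 - pad] += scol[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, Cin, B;
  get_dims4(x, H, W, Cin, B);
  IntegerVector wd = w.attr("dim");
  const int K = wd[0], Cout = wd[3];
  if (wd[1] != K || wd[2] != Cin) stop("weight dims do not match input channels");
  const int pad = (K - 1) / 2;
  arma::mat Wm(w.begin(), (size_t)K * K * Cin, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  NumericVector y((R_xlen_t)H * W * Cout * B);
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  arma::mat colT((size_t)H * W, (size_t)K * K * Cin);
  for (int bi = 0; bi < B; ++bi) {
    im2colT(x.begin() + (size_t)bi * H * W * Cin, H, W, Cin, K, pad, colT);
    arma::mat ym(y.begin() + (size_t)bi * H * W * Cout, (size_t)H * W, Cout, false, true);
    ym = colT * Wm;
    ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, Cin, B;
  get_dims4(x, H, W, Cin, B);
  IntegerVector wd = w.attr("dim");
  const int K = wd[0], Cout = wd[3];
  const int pad = (K - 1) / 2;
  arma::mat Wm(w.begin(), (size_t)K * K * Cin, Cout, false, true);
  NumericVector dx((R_xlen_t)H * W * Cin * B);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, B);
  NumericVector dw((R_xlen_t)K * K * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(K, K, Cin, Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), (size_t)K * K * Cin, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat colT((size_t)H * W, (size_t)K * K * Cin);
  for (int bi = 0; bi < B; ++bi) {
    im2colT(x.begin() + (size_t)bi * H * W * Cin, H, W, Cin, K, pad, colT);
    arma::mat dyb(dy.begin() + (size_t)bi * H * W * Cout, (size_t)H * W, Cout, false, true);
    dWm += colT.t() * dyb;
    dbv += arma::sum(dyb, 0);
    arma::mat dcolT = dyb * Wm.t();
    col2imT_acc(dcolT, H, W, Cin, K, pad, dx.begin() + (size_t)bi * H * W * Cin);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and the linear offset
// (0..3 = di + 2*dj) of each argmax for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  if (H % 2 || W % 2) stop("maxpool requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * B);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int cb = 0; cb < C * B; ++cb) {
    const double* xs = xp + (size_t)H * W * cb;
    double* ys = yp + (size_t)Ho * Wo * cb;
    int* as = ap + (size_t)Ho * Wo * cb;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double best = xs[2 * io + H * (2 * jo)];
        int bidx = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = xs[2 * io + di + (size_t)H * (2 * jo + dj)];
            if (v > best) { best = v; bidx = di + 2 * dj; }
          }
        }
        ys[io + (size_t)Ho * jo] = best;
        as[io + (size_t)Ho * jo] = bidx;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector arg, int H, int W) {
  int Ho, Wo, C, B;
  get_dims4(dy, Ho, Wo, C, B);
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  const double* dyp = dy.begin();
  const int* ap = arg.begin();
  double* dxp = dx.begin();
  for (int cb = 0; cb < C * B; ++cb) {
    const double* dys = dyp + (size_t)Ho * Wo * cb;
    const int* as = ap + (size_t)Ho * Wo * cb;
    double* dxs = dxp + (size_t)H * W * cb;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int a = as[io + (size_t)Ho * jo];
        const int di = a % 2, dj = a / 2;
        dxs[2 * io + di + (size_t)H * (2 * jo + dj)] += dys[io + (size_t)Ho * jo];
      }
    }
  }
  return dx;
}

struct BilinW { int i0, i1; double f; };

static std::vector<BilinW> bilin_weights(int Hin, int Hout) {
  std::vector<BilinW> w(Hout);
  const double scale = (double)Hin / Hout;
  for (int o = 0; o < Hout; ++o) {
    double p = (o + 0.5) * scale - 0.5;
    if (p < 0) p = 0;
    if (p > Hin - 1) p = Hin - 1;
    const int i0 = (int)std::floor(p);
    w[o].i0 = i0;
    w[o].i1 = std::min(i0 + 1, Hin - 1);
    w[o].f = p - i0;
  }
  return w;
}

// Bilinear resampling to an arbitrary output shape (half-pixel-center
// convention); shared by the decoder upsampling and slice resampling.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Ho, int Wo) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  std::vector<BilinW> wi = bilin_weights(H, Ho), wj = bilin_weights(W, Wo);
  NumericVector y((R_xlen_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  for (int cb = 0; cb < C * B; ++cb) {
    const double* xs = x.begin() + (size_t)H * W * cb;
    double* ys = y.begin() + (size_t)Ho * Wo * cb;
    for (int jo = 0; jo < Wo; ++jo) {
      const BilinW& bj = wj[jo];
      for (int io = 0; io < Ho; ++io) {
        const BilinW& bi = wi[io];
        const double v00 = xs[bi.i0 + (size_t)H * bj.i0];
        const double v10 = xs[bi.i1 + (size_t)H * bj.i0];
        const double v01 = xs[bi.i0 + (size_t)H * bj.i1];
        const double v11 = xs[bi.i1 + (size_t)H * bj.i1];
        ys[io + (size_t)Ho * jo] =
          (1 - bi.f) * (1 - bj.f) * v00 + bi.f * (1 - bj.f) * v10 +
          (1 - bi.f) * bj.f * v01 + bi.f * bj.f * v11;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_backward(NumericVector dy, int H, int W) {
  int Ho, Wo, C, B;
  get_dims4(dy, Ho, Wo, C, B);
  std::vector<BilinW> wi = bilin_weights(H, Ho), wj = bilin_weights(W, Wo);
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  for (int cb = 0; cb < C * B; ++cb) {
    const double* dys = dy.begin() + (size_t)Ho * Wo * cb;
    double* dxs = dx.begin() + (size_t)H * W * cb;
    for (int jo = 0; jo < Wo; ++jo) {
      const BilinW& bj = wj[jo];
      for (int io = 0; io < Ho; ++io) {
        const BilinW& bi = wi[io];
        const double g = dys[io + (size_t)Ho * jo];
        dxs[bi.i0 + (size_t)H * bj.i0] += (1 - bi.f) * (1 - bj.f) * g;
        dxs[bi.i1 + (size_t)H * bj.i0] += bi.f * (1 - bj.f) * g;
        dxs[bi.i0 + (size_t)H * bj.i1] += (1 - bi.f) * bj.f * g;
        dxs[bi.i1 + (size_t)H * bj.i1] += bi.f * bj.f * g;
      }
    }
  }
  return dx;
}

// In-plane rotation about the image center, out-of-bounds filled with 0.
// x has dim (H, W, C); bilinear = false gives nearest-neighbour sampling
// (used for label masks so they stay binary).
// [[Rcpp::export]]
NumericVector cpp_rotate2d(NumericVector x, double angle_deg, bool bilinear) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array (H, W, C)");
  const int H = d[0], W = d[1], C = d[2];
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double ci = (H - 1) / 2.0, cj = (W - 1) / 2.0;
  NumericVector y((R_xlen_t)H * W * C);
  y.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double* xs = x.begin() + (size_t)H * W * c;
    double* ys = y.begin() + (size_t)H * W * c;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        // inverse map: source = R(-theta) * (dest - center) + center
        const double di = i - ci, dj = j - cj;
        const double si = ct * di + st * dj + ci;
        const double sj = -st * di + ct * dj + cj;
        double v = 0.0;
        if (bilinear) {
          if (si >= 0 && si <= H - 1 && sj >= 0 && sj <= W - 1) {
            const int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
            const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
            const double fi = si - i0, fj = sj - j0;
            v = (1 - fi) * (1 - fj) * xs[i0 + (size_t)H * j0] +
                fi * (1 - fj) * xs[i1 + (size_t)H * j0] +
                (1 - fi) * fj * xs[i0 + (size_t)H * j1] +
                fi * fj * xs[i1 + (size_t)H * j1];
          }
        } else {
          const int ri = (int)std::lround(si), rj = (int)std::lround(sj);
          if (ri >= 0 && ri < H && rj >= 0 && rj < W) v = xs[ri + (size_t)H * rj];
        }
        ys[i + (size_t)H * j] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_row_median(NumericMatrix m) {
  const int n = m.nrow(), k = m.ncol();
  NumericVector out(n);
  std::vector<double> buf(k);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) buf[j] = m(i, j);
    const int mid = k / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double v = buf[mid];
    if (k % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
      v = 0.5 * (v + buf[mid - 1]);
    }
    out[i] = v;
  }
  return out;
}

// For each row of A (points, any fixed dimension), the minimum Euclidean
// distance to the rows of B. Coordinates are already in physical units.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  if (B.ncol() != d) stop("dimension mismatch");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = A(i, c) - B(j, c);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Per-channel mean and (population) variance over spatial and batch dims.
// [[Rcpp::export]]
List cpp_channel_mean_var(NumericVector x) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  const size_t hw = (size_t)H * W;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int bi = 0; bi < B; ++bi) {
      const double* xs = x.begin() + hw * (c + (size_t)C * bi);
      for (size_t i = 0; i < hw; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
    }
    const double n = (double)hw * B;
    mu[c] = s / n;
    double v = s2 / n - mu[c] * mu[c];
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// Fused batchnorm + ReLU forward: y = max(0, g*xhat + be),
// xhat = (x - mu) * istd. Returns y and xhat (cached for backward).
// [[Rcpp::export]]
List cpp_bnrelu_forward(NumericVector x, NumericVector mu, NumericVector istd,
                        NumericVector g, NumericVector be, bool want_cache) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  const size_t hw = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  NumericVector xhat;
  if (want_cache) {
    xhat = NumericVector(x.size());
    xhat.attr("dim") = x.attr("dim");
  }
  for (int bi = 0; bi < B; ++bi) {
    for (int c = 0; c < C; ++c) {
      const double m = mu[c], is = istd[c], gc = g[c], bc = be[c];
      const double* xs = x.begin() + hw * (c + (size_t)C * bi);
      double* ys = y.begin() + hw * (c + (size_t)C * bi);
      if (want_cache) {
        double* hs = xhat.begin() + hw * (c + (size_t)C * bi);
        for (size_t i = 0; i < hw; ++i) {
          const double xh = (xs[i] - m) * is;
          hs[i] = xh;
          const double v = gc * xh + bc;
          ys[i] = v > 0 ? v : 0;
        }
      } else {
        for (size_t i = 0; i < hw; ++i) {
          const double v = gc * ((xs[i] - m) * is) + bc;
          ys[i] = v > 0 ? v : 0;
        }
      }
    }
  }
  if (want_cache) return List::create(_["y"] = y, _["xhat"] = xhat);
  return List::create(_["y"] = y);
}

// Fused ReLU + batchnorm backward. dy is the gradient at the ReLU output,
// y the ReLU output (mask), xhat/istd the forward cache. Returns dx and
// per-channel dgamma/dbeta.
// [[Rcpp::export]]
List cpp_bnrelu_backward(NumericVector dy, NumericVector y, NumericVector xhat,
                         NumericVector g, NumericVector istd) {
  int H, W, C, B;
  get_dims4(dy, H, W, C, B);
  const size_t hw = (size_t)H * W;
  const double n = (double)hw * B;
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  // first pass: mask dy through the ReLU and accumulate channel sums
  for (int bi = 0; bi < B; ++bi) {
    for (int c = 0; c < C; ++c) {
      const size_t off = hw * (c + (size_t)C * bi);
      const double* dys = dy.begin() + off;
      const double* ys = y.begin() + off;
      const double* hs = xhat.begin() + off;
      double a_dg = 0, a_db = 0, a_s1 = 0, a_s2 = 0;
      const double gc = g[c];
      double* dxs = dx.begin() + off;  // temporarily stores dxhat
      for (size_t i = 0; i < hw; ++i) {
        const double d = ys[i] > 0 ? dys[i] : 0.0;
        a_dg += d * hs[i];
        a_db += d;
        const double dxh = d * gc;
        dxs[i] = dxh;
        a_s1 += dxh;
        a_s2 += dxh * hs[i];
      }
      dgamma[c] += a_dg;
      dbeta[c] += a_db;
      s1[c] += a_s1;
      s2[c] += a_s2;
    }
  }
  // second pass: dx = istd/n * (n*dxhat - s1 - xhat*s2)
  for (int bi = 0; bi < B; ++bi) {
    for (int c = 0; c < C; ++c) {
      const size_t off = hw * (c + (size_t)C * bi);
      const double* hs = xhat.begin() + off;
      double* dxs = dx.begin() + off;
      const double isn = istd[c] / n;
      const double cs1 = s1[c], cs2 = s2[c];
      for (size_t i = 0; i < hw; ++i) {
        dxs[i] = isn * (n * dxs[i] - cs1 - hs[i] * cs2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dg"] = dgamma, _["dbe"] = dbeta);
}
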