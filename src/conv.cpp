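// Convolution kernels for the training engine.
// Tensor layout everywhere: R arrays dim (H, W, C, N), column-major, so one
// (H, W, C) sample is contiguous and maps onto an arma::cube (rows = H,
// cols = W, slices = C) without copying.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect without edge repetition: -1 -> 1, n -> n-2 (valid for pad <= n-1)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static void pad_sample(const double* x, arma::cube& xp,
                       int H, int W, int C, int p, bool reflect) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  if (!reflect) xp.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < Wp; ++j) {
      int sj = j - p;
      if (reflect) sj = reflect_idx(sj, W);
      else if (sj < 0 || sj >= W) continue;
      for (int i = 0; i < Hp; ++i) {
        int si = i - p;
        if (reflect) si = reflect_idx(si, H);
        else if (si < 0 || si >= H) continue;
        xp(i, j, c) = xc[si + (size_t)sj * H];
      }
    }
  }
}

static void im2col(const arma::cube& xp, arma::mat& M,
                   int kh, int kw, int stride, int Ho, int Wo) {
  const int C = xp.n_slices;
  // column l = ho + Ho*wo; row r = ki + kh*(kj + kw*c)
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int l = ho + Ho * wo;
      double* Mcol = M.colptr(l);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const double* src = &xp(ho * stride, wo * stride + kj, c);
          double* dst = Mcol + kh * (kj + kw * c);
          for (int ki = 0; ki < kh; ++ki) dst[ki] = src[ki];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, bool reflect) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = (Hp - kh) / stride + 1, Wo = (Wp - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: input smaller than kernel");
  const int K = kh * kw * Cin, L = Ho * Wo;
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::cube xp(Hp, Wp, C);
  arma::mat M(K, L);
  for (int n = 0; n < N; ++n) {
    pad_sample(x.begin() + (size_t)n * H * W * C, xp, H, W, C, pad, reflect);
    im2col(xp, M, kh, kw, stride, Ho, Wo);
    arma::mat Yl(y.begin() + (size_t)n * L * Cout, L, Cout, false, true);
    Yl = M.t() * Wm;                      // (L x Cout), contiguous (Ho,Wo,Cout)
    for (int o = 0; o < Cout; ++o) Yl.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad, bool reflect) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int K = kh * kw * C, L = Ho * Wo;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)kh * kw * C * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::cube xp(Hp, Wp, C);
  arma::mat M(K, L), dM(K, L);
  arma::cube dxp(Hp, Wp, C);
  for (int n = 0; n < N; ++n) {
    pad_sample(x.begin() + (size_t)n * H * W * C, xp, H, W, C, pad, reflect);
    im2col(xp, M, kh, kw, stride, Ho, Wo);
    arma::mat dYl(dy.begin() + (size_t)n * L * Cout, L, Cout, false, true);
    dWm += M * dYl;
    for (int o = 0; o < Cout; ++o) db[o] += arma::accu(dYl.col(o));
    dM = Wm * dYl.t();                    // (K x L)
    dxp.zeros();
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int l = ho + Ho * wo;
        const double* Mcol = dM.colptr(l);
        for (int c = 0; c < C; ++c) {
          for (int kj = 0; kj < kw; ++kj) {
            double* dst = &dxp(ho * stride, wo * stride + kj, c);
            const double* src = Mcol + kh * (kj + kw * c);
            for (int ki = 0; ki < kh; ++ki) dst[ki] += src[ki];
          }
        }
      }
    }
    // fold padded gradient back onto source pixels
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxn + (size_t)c * H * W;
      for (int j = 0; j < Wp; ++j) {
        int sj = j - pad;
        if (reflect) sj = reflect_idx(sj, W);
        else if (sj < 0 || sj >= W) continue;
        for (int i = 0; i < Hp; ++i) {
          int si = i - pad;
          if (reflect) si = reflect_idx(si, H);
          else if (si < 0 || si >= H) continue;
          dxc[si + (size_t)sj * H] += dxp(i, j, c);
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 6-connected component labelling of a 3-D logical array (dim z,y,x or any).
// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  const int n1 = d[0], n2 = d[1], n3 = d.size() > 2 ? d[2] : 1;
  IntegerVector lab(mask.size());
  lab.attr("dim") = d;
  std::vector<size_t> stack;
  int next = 0;
  const size_t s1 = 1, s2 = (size_t)n1, s3 = (size_t)n1 * n2;
  for (size_t v = 0; v < (size_t)mask.size(); ++v) {
    if (!mask[v] || lab[v]) continue;
    ++next;
    lab[v] = next;
    stack.push_back(v);
    while (!stack.empty()) {
      size_t u = stack.back(); stack.pop_back();
      int i = u % n1, j = (u / n1) % n2, k = u / ((size_t)n1 * n2);
      size_t nb[6]; int nn = 0;
      if (i > 0)      nb[nn++] = u - s1;
      if (i < n1 - 1) nb[nn++] = u + s1;
      if (j > 0)      nb[nn++] = u - s2;
      if (j < n2 - 1) nb[nn++] = u + s2;
      if (k > 0)      nb[nn++] = u - s3;
      if (k < n3 - 1) nb[nn++] = u + s3;
      for (int t = 0; t < nn; ++t) {
        size_t q = nb[t];
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}
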