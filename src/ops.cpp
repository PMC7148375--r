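// Native kernels for the 3D network primitives and volume utilities.
// Tensor layout everywhere: channel-last R arrays dim = (D, H, W, C),
// column-major, so linear index = d + D*(h + H*(w + W*c)), 0-based.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int dim4(const NumericVector& x, int i, int fallback) {
  if (!x.hasAttribute("dim")) return fallback;
  IntegerVector d = x.attr("dim");
  return (i < d.size()) ? d[i] : fallback;
}

// im2col for same-padded k x k x k convolution: rows = voxels, cols =
// (kd, kh, kw, cin) in R column-major flattening order of dim (k,k,k,Cin).
static arma::mat im2col3(const double* x, int D, int H, int W, int Cin, int k) {
  const int p = (k - 1) / 2;
  const long V = (long)D * H * W;
  arma::mat col(V, (long)k * k * k * Cin, arma::fill::zeros);
  long q = 0;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (long)c * V;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          // column index follows R flatten of (kd,kh,kw,c)
          q = (long)kd + k * ((long)kh + k * ((long)kw + k * (long)c));
          double* dst = col.colptr(q);
          for (int w = 0; w < W; ++w) {
            int sw = w + kw - p;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              int sh = h + kh - p;
              if (sh < 0 || sh >= H) continue;
              for (int d = 0; d < D; ++d) {
                int sd = d + kd - p;
                if (sd < 0 || sd >= D) continue;
                dst[d + (long)D * (h + (long)H * w)] =
                  xc[sd + (long)D * (sh + (long)H * sw)];
              }
            }
          }
        }
  }
  return col;
}

// scatter-add transpose of im2col3
static void col2im3(const arma::mat& col, double* gx,
                    int D, int H, int W, int Cin, int k) {
  const int p = (k - 1) / 2;
  const long V = (long)D * H * W;
  for (int c = 0; c < Cin; ++c) {
    double* gc = gx + (long)c * V;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          long q = (long)kd + k * ((long)kh + k * ((long)kw + k * (long)c));
          const double* src = col.colptr(q);
          for (int w = 0; w < W; ++w) {
            int sw = w + kw - p;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              int sh = h + kh - p;
              if (sh < 0 || sh >= H) continue;
              for (int d = 0; d < D; ++d) {
                int sd = d + kd - p;
                if (sd < 0 || sd >= D) continue;
                gc[sd + (long)D * (sh + (long)H * sw)] +=
                  src[d + (long)D * (h + (long)H * w)];
              }
            }
          }
        }
  }
}

// [[Rcpp::export(name = "cpp_conv3d")]]
NumericVector cpp_conv3d(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  int k = wd[0], Cout = wd[4];
  if (wd[3] != Cin) stop("conv3d: input channels (%d) != kernel channels (%d)", Cin, wd[3]);
  const long V = (long)D * H * W;
  arma::mat Wm(w.begin(), (long)k * k * k * Cin, Cout, false, true);
  NumericVector y(V * Cout);
  arma::mat ym(y.begin(), V, Cout, false, true);
  if (k == 1) {             // pointwise convolution: plain GEMM, no im2col
    arma::mat Xm(x.begin(), V, Cin, false, true);
    ym = Xm * Wm;
  } else {
    arma::mat col = im2col3(x.begin(), D, H, W, Cin, k);
    ym = col * Wm;
  }
  for (int c = 0; c < Cout; ++c) ym.col(c) += b[c];
  y.attr("dim") = IntegerVector::create(D, H, W, Cout);
  return y;
}

// forward that also returns the im2col matrix for reuse in backward
// (pointwise convolutions need no cache: backward reuses the input itself)
// [[Rcpp::export(name = "cpp_conv3d_cached")]]
List cpp_conv3d_cached(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  int k = wd[0], Cout = wd[4];
  if (wd[3] != Cin) stop("conv3d: input channels (%d) != kernel channels (%d)", Cin, wd[3]);
  const long V = (long)D * H * W;
  NumericVector y(V * Cout);
  arma::mat ym(y.begin(), V, Cout, false, true);
  arma::mat Wm(w.begin(), (long)k * k * k * Cin, Cout, false, true);
  if (k == 1) {
    arma::mat Xm(x.begin(), V, Cin, false, true);
    ym = Xm * Wm;
    for (int c = 0; c < Cout; ++c) ym.col(c) += b[c];
    y.attr("dim") = IntegerVector::create(D, H, W, Cout);
    return List::create(_["y"] = y, _["col"] = R_NilValue);
  }
  NumericMatrix colR(V, (long)k * k * k * Cin);
  arma::mat col(colR.begin(), V, (long)k * k * k * Cin, false, true);
  col = im2col3(x.begin(), D, H, W, Cin, k);
  ym = col * Wm;
  for (int c = 0; c < Cout; ++c) ym.col(c) += b[c];
  y.attr("dim") = IntegerVector::create(D, H, W, Cout);
  return List::create(_["y"] = y, _["col"] = colR);
}

// backward reusing a cached im2col matrix
// [[Rcpp::export(name = "cpp_conv3d_backward_col")]]
List cpp_conv3d_backward_col(NumericMatrix colR, NumericVector w,
                             NumericVector gy, IntegerVector xdim) {
  IntegerVector wd = w.attr("dim");
  int D = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3];
  int k = wd[0], Cout = wd[4];
  const long V = (long)D * H * W;
  arma::mat col(colR.begin(), colR.nrow(), colR.ncol(), false, true);
  arma::mat Wm(w.begin(), (long)k * k * k * Cin, Cout, false, true);
  arma::mat G(gy.begin(), V, Cout, false, true);

  NumericVector gw((long)k * k * k * Cin * Cout);
  arma::mat gwm(gw.begin(), (long)k * k * k * Cin, Cout, false, true);
  gwm = col.t() * G;
  gw.attr("dim") = wd;

  NumericVector gb(Cout);
  for (int c = 0; c < Cout; ++c) gb[c] = arma::accu(G.col(c));

  arma::mat gcol = G * Wm.t();
  NumericVector gx(V * Cin);
  col2im3(gcol, gx.begin(), D, H, W, Cin, k);
  gx.attr("dim") = IntegerVector::create(D, H, W, Cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = "cpp_conv3d_backward")]]
List cpp_conv3d_backward(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  int k = wd[0], Cout = wd[4];
  const long V = (long)D * H * W;
  if (k == 1) {
    arma::mat Xm(x.begin(), V, Cin, false, true);
    arma::mat Wm(w.begin(), Cin, Cout, false, true);
    arma::mat G(gy.begin(), V, Cout, false, true);
    NumericVector gw((long)Cin * Cout);
    arma::mat gwm(gw.begin(), Cin, Cout, false, true);
    gwm = Xm.t() * G;
    gw.attr("dim") = wd;
    NumericVector gb(Cout);
    for (int c = 0; c < Cout; ++c) gb[c] = arma::accu(G.col(c));
    NumericVector gx(V * Cin);
    arma::mat gxm(gx.begin(), V, Cin, false, true);
    gxm = G * Wm.t();
    gx.attr("dim") = IntegerVector::create(D, H, W, Cin);
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  arma::mat col = im2col3(x.begin(), D, H, W, Cin, k);
  arma::mat Wm(w.begin(), (long)k * k * k * Cin, Cout, false, true);
  arma::mat G(gy.begin(), V, Cout, false, true);

  NumericVector gw((long)k * k * k * Cin * Cout);
  arma::mat gwm(gw.begin(), (long)k * k * k * Cin, Cout, false, true);
  gwm = col.t() * G;
  gw.attr("dim") = wd;

  NumericVector gb(Cout);
  for (int c = 0; c < Cout; ++c) gb[c] = arma::accu(G.col(c));

  arma::mat gcol = G * Wm.t();
  NumericVector gx(V * Cin);           // zero-initialised
  col2im3(gcol, gx.begin(), D, H, W, Cin, k);
  gx.attr("dim") = IntegerVector::create(D, H, W, Cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling; returns pooled values and 1-based argmax indices into x.
// [[Rcpp::export(name = "cpp_maxpool3d")]]
List cpp_maxpool3d(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  if (D % 2 || H % 2 || W % 2)
    stop("maxpool3d: spatial dims (%d,%d,%d) must be even", D, H, W);
  int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const long Vo = (long)Do * Ho * Wo;
  NumericVector y(Vo * C);
  IntegerVector idx(Vo * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    long offc = (long)c * D * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d) {
          double best = -std::numeric_limits<double>::infinity();
          long bi = -1;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd) {
                long i = offc + (2 * d + dd) +
                  (long)D * ((2 * h + dh) + (long)H * (2 * w + dw));
                if (px[i] > best) { best = px[i]; bi = i; }
              }
          long o = (long)c * Vo + d + (long)Do * (h + (long)Ho * w);
          y[o] = best;
          idx[o] = (int)(bi + 1);
        }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = "cpp_maxpool3d_backward")]]
NumericVector cpp_maxpool3d_backward(NumericVector gy, IntegerVector idx,
                                     IntegerVector xdim) {
  long n = (long)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  for (long i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

struct LinW { int i0, i1; double t; };
static std::vector<LinW> axis_weights(int in, int out) {
  std::vector<LinW> w(out);
  double scale = (out > 1 && in > 1) ? (double)(in - 1) / (out - 1) : 0.0;
  for (int o = 0; o < out; ++o) {
    double s = o * scale;
    int i0 = (int)std::floor(s);
    if (i0 > in - 1) i0 = in - 1;
    int i1 = std::min(i0 + 1, in - 1);
    w[o] = { i0, i1, s - i0 };
  }
  return w;
}

// Separable trilinear interpolation to a larger grid (corner-aligned, so
// aligned corner voxels keep their values exactly).
// [[Rcpp::export(name = "cpp_upsample3d")]]
NumericVector cpp_upsample3d(NumericVector x, int Do, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  std::vector<LinW> wd = axis_weights(D, Do), wh = axis_weights(H, Ho),
                    ww = axis_weights(W, Wo);
  NumericVector y((long)Do * Ho * Wo * C);
  const double* px = x.begin();
  double* py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = px + (long)c * D * H * W;
    double* yc = py + (long)c * Do * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d) {
          const LinW &a = wd[d], &b = wh[h], &g = ww[w];
          double v = 0.0;
          for (int dw = 0; dw < 2; ++dw) {
            int iw = dw ? g.i1 : g.i0;
            double fw = dw ? g.t : 1 - g.t;
            if (fw == 0) continue;
            for (int dh = 0; dh < 2; ++dh) {
              int ih = dh ? b.i1 : b.i0;
              double fh = dh ? b.t : 1 - b.t;
              if (fh == 0) continue;
              for (int dd = 0; dd < 2; ++dd) {
                int id = dd ? a.i1 : a.i0;
                double fd = dd ? a.t : 1 - a.t;
                if (fd == 0) continue;
                v += fw * fh * fd * xc[id + (long)D * (ih + (long)H * iw)];
              }
            }
          }
          yc[d + (long)Do * (h + (long)Ho * w)] = v;
        }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return y;
}

// Transpose (scatter-add) of cpp_upsample3d.
// [[Rcpp::export(name = "cpp_upsample3d_backward")]]
NumericVector cpp_upsample3d_backward(NumericVector gy, int D, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  int Do = yd[0], Ho = yd[1], Wo = yd[2], C = yd[3];
  std::vector<LinW> wd = axis_weights(D, Do), wh = axis_weights(H, Ho),
                    ww = axis_weights(W, Wo);
  NumericVector gx((long)D * H * W * C);
  const double* pg = gy.begin();
  double* px = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double* gc = pg + (long)c * Do * Ho * Wo;
    double* xc = px + (long)c * D * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d) {
          double g0 = gc[d + (long)Do * (h + (long)Ho * w)];
          if (g0 == 0) continue;
          const LinW &a = wd[d], &b = wh[h], &g = ww[w];
          for (int dw = 0; dw < 2; ++dw) {
            int iw = dw ? g.i1 : g.i0;
            double fw = dw ? g.t : 1 - g.t;
            if (fw == 0) continue;
            for (int dh = 0; dh < 2; ++dh) {
              int ih = dh ? b.i1 : b.i0;
              double fh = dh ? b.t : 1 - b.t;
              if (fh == 0) continue;
              for (int dd = 0; dd < 2; ++dd) {
                int id = dd ? a.i1 : a.i0;
                double fd = dd ? a.t : 1 - a.t;
                if (fd == 0) continue;
                xc[id + (long)D * (ih + (long)H * iw)] += fw * fh * fd * g0;
              }
            }
          }
        }
  }
  gx.attr("dim") = IntegerVector::create(D, H, W, C);
  return gx;
}

// Connected components on a binary mask (BFS), connectivity 6/18/26.
// Returns integer label grid; component ids contiguous from 1 in discovery
// order.
// [[Rcpp::export(name = "cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  IntegerVector md = mask.attr("dim");
  int D = md[0], H = md[1], W = md[2];
  std::vector<std::array<int,3>> nb;
  for (int dw = -1; dw <= 1; ++dw)
    for (int dh = -1; dh <= 1; ++dh)
      for (int dd = -1; dd <= 1; ++dd) {
        int m = std::abs(dd) + std::abs(dh) + std::abs(dw);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        nb.push_back({dd, dh, dw});
      }
  long n = (long)D * H * W;
  IntegerVector lab(n);
  int next = 0;
  std::queue<long> q;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      long i = q.front(); q.pop();
      int d = (int)(i % D), h = (int)((i / D) % H), w = (int)(i / ((long)D * H));
      for (auto& o : nb) {
        int nd = d + o[0], nh = h + o[1], nw = w + o[2];
        if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
        long j = nd + (long)D * (nh + (long)H * nw);
        if (mask[j] && !lab[j]) { lab[j] = next; q.push(j); }
      }
    }
  }
  lab.attr("dim") = md;
  return lab;
}

// Symmetric Hausdorff distance between two point sets (rows = points, mm
// coordinates), brute-force max-min in both directions.
// [[Rcpp::export(name = "cpp_hausdorff")]]
double cpp_hausdorff(NumericMatrix P, NumericMatrix T) {
  int np = P.nrow(), nt = T.nrow(), k = P.ncol();
  double hPT = 0.0;
  for (int i = 0; i < np; ++i) {
    double mn = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nt; ++j) {
      double s = 0.0;
      for (int a = 0; a < k; ++a) { double d = P(i,a) - T(j,a); s += d * d; }
      if (s < mn) mn = s;
    }
    if (mn > hPT) hPT = mn;
  }
  double hTP = 0.0;
  for (int j = 0; j < nt; ++j) {
    double mn = std::numeric_limits<double>::infinity();
    for (int i = 0; i < np; ++i) {
      double s = 0.0;
      for (int a = 0; a < k; ++a) { double d = P(i,a) - T(j,a); s += d * d; }
      if (s < mn) mn = s;
    }
    if (mn > hTP) hTP = mn;
  }
  return std::sqrt(std::max(hPT, hTP));
}
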