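// Minimal 2D convolution kernels for the dynamic U-Net.
// Layout convention (R column-major): activations (H, W, C, N),
// conv weights (k1, k2, Cin, Cout), transposed-conv weights (k1, k2, Cin, Cout)
// with kernel == stride per axis. im2col + BLAS GEMM via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat im2col(const double* x, int H, int W, int C,
                               int k1, int k2, int s1, int s2, int p1, int p2,
                               int Ho, int Wo) {
  // rows: output positions (oi fastest), cols: kernel entries (ki, kj, c)
  arma::mat M(Ho * Wo, k1 * k2 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k2; ++kj) {
      for (int ki = 0; ki < k1; ++ki) {
        int col = ki + k1 * (kj + k2 * c);
        double* Mcol = M.colptr(col);
        for (int oj = 0; oj < Wo; ++oj) {
          int jj = oj * s2 - p2 + kj;
          if (jj < 0 || jj >= W) continue;
          const double* xcol = xc + (size_t)jj * H;
          double* Mo = Mcol + (size_t)oj * Ho;
          for (int oi = 0; oi < Ho; ++oi) {
            int ii = oi * s1 - p1 + ki;
            if (ii >= 0 && ii < H) Mo[oi] = xcol[ii];
          }
        }
      }
    }
  }
  return M;
}

static inline void col2im_acc(const arma::mat& M, double* gx, int H, int W, int C,
                              int k1, int k2, int s1, int s2, int p1, int p2,
                              int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * H * W;
    for (int kj = 0; kj < k2; ++kj) {
      for (int ki = 0; ki < k1; ++ki) {
        int col = ki + k1 * (kj + k2 * c);
        const double* Mcol = M.colptr(col);
        for (int oj = 0; oj < Wo; ++oj) {
          int jj = oj * s2 - p2 + kj;
          if (jj < 0 || jj >= W) continue;
          double* gcol = gc + (size_t)jj * H;
          const double* Mo = Mcol + (size_t)oj * Ho;
          for (int oi = 0; oi < Ho; ++oi) {
            int ii = oi * s1 - p1 + ki;
            if (ii >= 0 && ii < H) gcol[ii] += Mo[oi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int s1, int s2, int p1, int p2) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k1 = wd[0], k2 = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch");
  int Ho = (H + 2 * p1 - k1) / s1 + 1;
  int Wo = (W + 2 * p2 - k2) / s2 + 1;
  arma::mat Wm(const_cast<double*>(w.begin()), k1 * k2 * Cin, Cout, false, true);
  NumericVector out(Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat M = im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
                         k1, k2, s1, s2, p1, p2, Ho, Wo);
    arma::mat Y = M * Wm;  // (HoWo x Cout)
    Y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false, true);
    std::copy(Y.begin(), Y.end(), out.begin() + (size_t)n * Ho * Wo * Cout);
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int s1, int s2, int p1, int p2) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k1 = wd[0], k2 = wd[1], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  arma::mat Wm(const_cast<double*>(w.begin()), k1 * k2 * C, Cout, false, true);
  NumericVector gxv(x.size());
  gxv.attr("dim") = xd;
  arma::mat gW(k1 * k2 * C, Cout, arma::fill::zeros);
  arma::rowvec gB(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat M = im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
                         k1, k2, s1, s2, p1, p2, Ho, Wo);
    arma::mat G(const_cast<double*>(gy.begin()) + (size_t)n * Ho * Wo * Cout,
                Ho * Wo, Cout, false, true);
    gW += M.t() * G;
    gB += arma::sum(G, 0);
    arma::mat dM = G * Wm.t();  // (HoWo x k1k2C)
    col2im_acc(dM, gxv.begin() + (size_t)n * H * W * C, H, W, C,
               k1, k2, s1, s2, p1, p2, Ho, Wo);
  }
  NumericVector gwv(w.size());
  gwv.attr("dim") = wd;
  std::copy(gW.begin(), gW.end(), gwv.begin());
  NumericVector gbv(Cout);
  std::copy(gB.begin(), gB.end(), gbv.begin());
  return List::create(_["gx"] = gxv, _["gw"] = gwv, _["gb"] = gbv);
}

// Transposed conv with kernel == stride (non-overlapping): out[i*s1+ki, j*s2+kj, co]
// = sum_ci w[ki,kj,ci,co] * x[i,j,ci] + b[co]
// [[Rcpp::export(name = ".convt2d_fw")]]
NumericVector convt2d_fw(NumericVector x, NumericVector w, NumericVector b,
                         int s1, int s2) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k1 = wd[0], k2 = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C || k1 != s1 || k2 != s2) stop("transposed conv requires kernel == stride");
  int Ho = H * s1, Wo = W * s2;
  // Wm: (Cin, k1*k2*Cout) with column index ki + k1*(kj + k2*co)
  arma::mat Wm(Cin, k1 * k2 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kj = 0; kj < k2; ++kj)
        for (int ki = 0; ki < k1; ++ki)
          Wm(ci, ki + k1 * (kj + k2 * co)) =
            w[ki + k1 * (kj + k2 * (ci + Cin * co))];
  NumericVector out(Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                H * W, C, false, true);
    arma::mat Y = X * Wm;  // (HW x k1k2Cout)
    double* on = out.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double* oc = on + (size_t)co * Ho * Wo;
      for (int kj = 0; kj < k2; ++kj)
        for (int ki = 0; ki < k1; ++ki) {
          const double* yc = Y.colptr(ki + k1 * (kj + k2 * co));
          for (int j = 0; j < W; ++j) {
            double* od = oc + (size_t)(j * s2 + kj) * Ho + ki;
            const double* ys = yc + (size_t)j * H;
            for (int i = 0; i < H; ++i) od[(size_t)i * s1] = ys[i] + b[co];
          }
        }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".convt2d_bw")]]
List convt2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                int s1, int s2) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k1 = wd[0], k2 = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = H * s1, Wo = W * s2;
  arma::mat Wm(Cin, k1 * k2 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kj = 0; kj < k2; ++kj)
        for (int ki = 0; ki < k1; ++ki)
          Wm(ci, ki + k1 * (kj + k2 * co)) =
            w[ki + k1 * (kj + k2 * (ci + Cin * co))];
  NumericVector gxv(x.size());
  gxv.attr("dim") = xd;
  arma::mat gWm(Cin, k1 * k2 * Cout, arma::fill::zeros);
  arma::vec gB(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    // gather gy into (HW x k1k2Cout)
    arma::mat Gg(H * W, k1 * k2 * Cout);
    const double* gn = gy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* gc = gn + (size_t)co * Ho * Wo;
      for (int kj = 0; kj < k2; ++kj)
        for (int ki = 0; ki < k1; ++ki) {
          double* dst = Gg.colptr(ki + k1 * (kj + k2 * co));
          for (int j = 0; j < W; ++j) {
            const double* gs = gc + (size_t)(j * s2 + kj) * Ho + ki;
            double* dd = dst + (size_t)j * H;
            for (int i = 0; i < H; ++i) dd[i] = gs[(size_t)i * s1];
          }
          gB[co] += arma::accu(arma::vec(dst, H * W, false, true));
        }
    }
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                H * W, C, false, true);
    gWm += X.t() * Gg;
    arma::mat gX = Gg * Wm.t();  // (HW x Cin)
    std::copy(gX.begin(), gX.end(), gxv.begin() + (size_t)n * H * W * C);
  }
  NumericVector gwv(w.size());
  gwv.attr("dim") = wd;
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kj = 0; kj < k2; ++kj)
        for (int ki = 0; ki < k1; ++ki)
          gwv[ki + k1 * (kj + k2 * (ci + Cin * co))] =
            gWm(ci, ki + k1 * (kj + k2 * co));
  NumericVector gbv(Cout);
  std::copy(gB.begin(), gB.end(), gbv.begin());
  return List::create(_["gx"] = gxv, _["gw"] = gwv, _["gb"] = gbv);
}

// Physically centered resampling of a single 2D plane.
// Output pixel center (oi + 0.5) maps to input coordinate
// (oi + 0.5) * (H / Ho) - 0.5 (pure grid-size change; spacing handled upstream).
// [[Rcpp::export(name = ".resample2d")]]
NumericMatrix resample2d(NumericMatrix x, int Ho, int Wo, bool nearest) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(Ho, Wo);
  double fi = (double)H / Ho, fj = (double)W / Wo;
  for (int oj = 0; oj < Wo; ++oj) {
    double cj = (oj + 0.5) * fj - 0.5;
    for (int oi = 0; oi < Ho; ++oi) {
      double ci = (oi + 0.5) * fi - 0.5;
      if (nearest) {
        int ii = (int)std::lround(ci), jj = (int)std::lround(cj);
        ii = std::min(std::max(ii, 0), H - 1);
        jj = std::min(std::max(jj, 0), W - 1);
        out(oi, oj) = x(ii, jj);
      } else {
        int i0 = (int)std::floor(ci), j0 = (int)std::floor(cj);
        double di = ci - i0, dj = cj - j0;
        int i0c = std::min(std::max(i0, 0), H - 1);
        int i1c = std::min(std::max(i0 + 1, 0), H - 1);
        int j0c = std::min(std::max(j0, 0), W - 1);
        int j1c = std::min(std::max(j0 + 1, 0), W - 1);
        out(oi, oj) =
          (1 - di) * (1 - dj) * x(i0c, j0c) + di * (1 - dj) * x(i1c, j0c) +
          (1 - di) * dj * x(i0c, j1c) + di * dj * x(i1c, j1c);
      }
    }
  }
  return out;
}
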