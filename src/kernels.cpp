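#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cmath>
#ifndef FCONE
# define FCONE
#endif
#include <vector>
using namespace Rcpp;

// Dense 2-D convolution with `same` zero padding on an H x W x Cin array.
// Weights are k x k x Cin x Cout (column-major, as R lays them out), so the
// flattened weight array is already the (k*k*Cin) x Cout GEMM operand.
// Convolutions are lowered to im2col + dgemm to ride the linked BLAS.

// Fill the (H*W) x (k*k*Cin) patch matrix.
static void im2col(const double* x, int H, int W, int Cin, int k,
                   double* A) {
  const int pad = k / 2;
  const R_xlen_t HW = static_cast<R_xlen_t>(H) * W;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + HW * ci;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* col = A + HW * (ki + static_cast<R_xlen_t>(k) * kj +
                                static_cast<R_xlen_t>(k) * k * ci);
        const int di = ki - pad, dj = kj - pad;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          double* dst = col + static_cast<R_xlen_t>(H) * j;
          if (jj < 0 || jj >= W) {
            for (int i = 0; i < H; ++i) dst[i] = 0.0;
            continue;
          }
          const double* src = xc + static_cast<R_xlen_t>(H) * jj;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di;
            dst[i] = (ii >= 0 && ii < H) ? src[ii] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the adjoint of im2col: gA is (H*W) x (k*k*Cin).
static void col2im_add(const double* gA, int H, int W, int Cin, int k,
                       double* gx) {
  const int pad = k / 2;
  const R_xlen_t HW = static_cast<R_xlen_t>(H) * W;
  for (int ci = 0; ci < Cin; ++ci) {
    double* gxc = gx + HW * ci;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* col = gA + HW * (ki + static_cast<R_xlen_t>(k) * kj +
                                       static_cast<R_xlen_t>(k) * k * ci);
        const int di = ki - pad, dj = kj - pad;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          const double* src = col + static_cast<R_xlen_t>(H) * j;
          double* dst = gxc + static_cast<R_xlen_t>(H) * jj;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di;
            if (ii >= 0 && ii < H) dst[ii] += src[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(const NumericVector& x, const NumericVector& w,
                            const NumericVector& b, int H, int W, int Cin,
                            int Cout, int k) {
  const R_xlen_t HW = static_cast<R_xlen_t>(H) * W;
  const int K = k * k * Cin;
  NumericVector y(HW * Cout);
  std::vector<double> A(HW * K);
  im2col(x.begin(), H, W, Cin, k, A.data());
  const int M = static_cast<int>(HW);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &M, &Cout, &K, &one, A.data(), &M,
                  w.begin(), &K, &zero, y.begin(), &M FCONE FCONE);
  for (int co = 0; co < Cout; ++co) {
    double* yc = y.begin() + HW * co;
    const double bias = b[co];
    for (R_xlen_t p = 0; p < HW; ++p) yc[p] += bias;
  }
  return y;
}

// Backward pass: given upstream gradient gy (H x W x Cout), return gradients
// with respect to the input, the weights and the bias.

// [[Rcpp::export]]
List cpp_conv2d_bw(const NumericVector& x, const NumericVector& w,
                   const NumericVector& gy, int H, int W, int Cin, int Cout,
                   int k) {
  const R_xlen_t HW = static_cast<R_xlen_t>(H) * W;
  const int K = k * k * Cin;
  const int M = static_cast<int>(HW);
  NumericVector gx(HW * Cin);
  NumericVector gw(static_cast<R_xlen_t>(K) * Cout);
  NumericVector gb(Cout);
  std::vector<double> A(HW * K);
  im2col(x.begin(), H, W, Cin, k, A.data());
  const double one = 1.0, zero = 0.0;
  // gW = A^T %*% gY  : (K x Cout)
  F77_CALL(dgemm)("T", "N", &K, &Cout, &M, &one, A.data(), &M,
                  gy.begin(), &M, &zero, gw.begin(), &K FCONE FCONE);
  // gA = gY %*% W^T  : (HW x K), then scatter back
  std::vector<double> gA(HW * K);
  F77_CALL(dgemm)("N", "T", &M, &K, &Cout, &one, gy.begin(), &M,
                  w.begin(), &K, &zero, gA.data(), &M FCONE FCONE);
  col2im_add(gA.data(), H, W, Cin, k, gx.begin());
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gy.begin() + HW * co;
    double acc = 0.0;
    for (R_xlen_t p = 0; p < HW; ++p) acc += gc[p];
    gb[co] = acc;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling (H, W even). Returns pooled values and 0-based argmax
// indices into the per-channel input plane.

// [[Rcpp::export]]
List cpp_maxpool2_fw(const NumericVector& x, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C);
  IntegerVector idx(static_cast<R_xlen_t>(Ho) * Wo * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + static_cast<R_xlen_t>(H) * W * c;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int best = (2 * i) + H * (2 * j);
        double bv = xc[best];
        const int cand[3] = {2 * i + 1 + H * (2 * j), 2 * i + H * (2 * j + 1),
                             2 * i + 1 + H * (2 * j + 1)};
        for (int t = 0; t < 3; ++t) {
          if (xc[cand[t]] > bv) { bv = xc[cand[t]]; best = cand[t]; }
        }
        y[i + static_cast<R_xlen_t>(Ho) * (j + static_cast<R_xlen_t>(Wo) * c)] = bv;
        idx[i + static_cast<R_xlen_t>(Ho) * (j + static_cast<R_xlen_t>(Wo) * c)] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(const NumericVector& gy, const IntegerVector& idx,
                              int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C);
  for (int c = 0; c < C; ++c) {
    double* gxc = gx.begin() + static_cast<R_xlen_t>(H) * W * c;
    const R_xlen_t off = static_cast<R_xlen_t>(Ho) * Wo * c;
    for (R_xlen_t p = 0; p < static_cast<R_xlen_t>(Ho) * Wo; ++p) {
      gxc[idx[off + p]] += gy[off + p];
    }
  }
  return gx;
}

// Nearest-neighbour 2x upsampling and its adjoint.

// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(const NumericVector& x, int H, int W, int C) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + static_cast<R_xlen_t>(H) * W * c;
    double* yc = y.begin() + static_cast<R_xlen_t>(Ho) * Wo * c;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = xc[i + static_cast<R_xlen_t>(H) * j];
        yc[2 * i + static_cast<R_xlen_t>(Ho) * (2 * j)] = v;
        yc[2 * i + 1 + static_cast<R_xlen_t>(Ho) * (2 * j)] = v;
        yc[2 * i + static_cast<R_xlen_t>(Ho) * (2 * j + 1)] = v;
        yc[2 * i + 1 + static_cast<R_xlen_t>(Ho) * (2 * j + 1)] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(const NumericVector& gy, int H, int W, int C) {
  // H, W are the *input* (coarse) dims
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C);
  for (int c = 0; c < C; ++c) {
    const double* gc = gy.begin() + static_cast<R_xlen_t>(Ho) * Wo * c;
    double* gxc = gx.begin() + static_cast<R_xlen_t>(H) * W * c;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        gxc[i + static_cast<R_xlen_t>(H) * j] =
            gc[2 * i + static_cast<R_xlen_t>(Ho) * (2 * j)] +
            gc[2 * i + 1 + static_cast<R_xlen_t>(Ho) * (2 * j)] +
            gc[2 * i + static_cast<R_xlen_t>(Ho) * (2 * j + 1)] +
            gc[2 * i + 1 + static_cast<R_xlen_t>(Ho) * (2 * j + 1)];
      }
    }
  }
  return gx;
}

// Rigid warp with a replayable record: forward transform is
// flip (h then v) -> rotation about the image centre -> integer translation.
// Implemented by inverse mapping; `bilinear = false` uses nearest-neighbour
// sampling (exact for binary masks). angle in degrees.

// [[Rcpp::export]]
NumericMatrix cpp_warp_rigid(const NumericMatrix& img, bool hflip, bool vflip,
                             double angle, int dy, int dx, bool bilinear,
                             double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double ci = (H - 1) / 2.0, cj = (W - 1) / 2.0;
  const double th = -angle * M_PI / 180.0;  // inverse rotation
  const double ct = std::cos(th), st = std::sin(th);
  const bool rot = (angle != 0.0);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      // undo translation
      double si = i - dy, sj = j - dx;
      // undo rotation
      if (rot) {
        const double di = si - ci, dj = sj - cj;
        si = ci + ct * di - st * dj;
        sj = cj + st * di + ct * dj;
      }
      // undo flips (self-inverse)
      double fi = vflip ? (H - 1 - si) : si;
      double fj = hflip ? (W - 1 - sj) : sj;
      double v;
      if (bilinear) {
        const int i0 = static_cast<int>(std::floor(fi));
        const int j0 = static_cast<int>(std::floor(fj));
        const double ai = fi - i0, aj = fj - j0;
        double acc = 0.0;
        for (int dj2 = 0; dj2 <= 1; ++dj2) {
          for (int di2 = 0; di2 <= 1; ++di2) {
            const int ii = i0 + di2, jj = j0 + dj2;
            const double wgt = (di2 ? ai : 1 - ai) * (dj2 ? aj : 1 - aj);
            const double pv = (ii >= 0 && ii < H && jj >= 0 && jj < W)
                                  ? img(ii, jj)
                                  : fill;
            acc += wgt * pv;
          }
        }
        v = acc;
      } else {
        const int ii = static_cast<int>(std::lround(fi));
        const int jj = static_cast<int>(std::lround(fj));
        v = (ii >= 0 && ii < H && jj >= 0 && jj < W) ? img(ii, jj) : fill;
      }
      out(i, j) = v;
    }
  }
  return out;
}
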