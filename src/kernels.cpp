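// Low-level numerical kernels for the CNN: batched dilated convolution
// (im2col + GEMM), 2x2 max pooling, 8-connected component labelling and
// IEEE binary16 quantisation used by the mixed-precision training mode.
//
// Array layout convention throughout: images / feature maps are R arrays
// with dim c(H, W, C, N) (channel-last, column-major), matching the R side.

#include <RcppArmadillo.h>
#include <cstdint>
#include <cstring>
#include <vector>

using namespace Rcpp;

// column ordering of the unrolled kernel: for c in 0..C-1, kj in 0..w-1,
// ki in 0..w-1 -> column index ((c * w) + kj) * w + ki.  Weight matrices on
// the R side follow the same ordering.
static void im2col_one(const double* x, int H, int W, int C,
                       int w, int l, arma::mat& cols) {
  const int Ho = H - (w - 1) * l;
  const int Wo = W - (w - 1) * l;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < w; ++kj) {
      for (int ki = 0; ki < w; ++ki) {
        const int col = (c * w + kj) * w + ki;
        double* dst = cols.colptr(col);
        for (int j = 0; j < Wo; ++j) {
          const double* src = xc + (size_t)(j + kj * l) * H + ki * l;
          std::memcpy(dst + (size_t)j * Ho, src, sizeof(double) * Ho);
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix Wm,
                           NumericVector bias, int w, int l) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H - (w - 1) * l, Wo = W - (w - 1) * l;
  const int Cout = Wm.ncol();
  if (Ho < 1 || Wo < 1) stop("input too small for the effective receptive field");
  if (Wm.nrow() != w * w * C) stop("weight matrix has wrong number of rows");

  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat cols(Ho * Wo, w * w * C);
  for (int n = 0; n < N; ++n) {
    im2col_one(&x[(size_t)n * H * W * C], H, W, C, w, l, cols);
    arma::mat o = cols * Wa;
    o.each_row() += arma::rowvec(bias.begin(), Cout);
    std::memcpy(&out[(size_t)n * Ho * Wo * Cout], o.memptr(),
                sizeof(double) * o.n_elem);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericMatrix Wm, NumericVector dout,
                  int w, int l) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H - (w - 1) * l, Wo = W - (w - 1) * l;
  const int Cout = Wm.ncol();

  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = d;
  arma::mat dW(w * w * C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  arma::mat cols(Ho * Wo, w * w * C);
  for (int n = 0; n < N; ++n) {
    im2col_one(&x[(size_t)n * H * W * C], H, W, C, w, l, cols);
    arma::mat dn(const_cast<double*>(&dout[(size_t)n * Ho * Wo * Cout]),
                 Ho * Wo, Cout, false);
    dW += cols.t() * dn;
    db += arma::sum(dn, 0).t();
    arma::mat dcols = dn * Wa.t();
    // scatter-add (col2im)
    double* dxn = &dx[(size_t)n * H * W * C];
    for (int c = 0; c < C; ++c) {
      double* dxc = dxn + (size_t)c * H * W;
      for (int kj = 0; kj < w; ++kj) {
        for (int ki = 0; ki < w; ++ki) {
          const int col = (c * w + kj) * w + ki;
          const double* src = dcols.colptr(col);
          for (int j = 0; j < Wo; ++j) {
            double* dst = dxc + (size_t)(j + kj * l) * H + ki * l;
            const double* s = src + (size_t)j * Ho;
            for (int i = 0; i < Ho; ++i) dst[i] += s[i];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx,
                      _["dW"] = NumericMatrix(dW.n_rows, dW.n_cols, dW.memptr()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2, floor on odd sides. argmax stores the linear
// offset (0-based, within the H*W plane of one channel) of the winner.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector amax((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  amax.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = &x[((size_t)n * C + c) * H * W];
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++o) {
          int base = (2 * j) * H + 2 * i;
          int best = base;
          double bv = xp[base];
          if (xp[base + 1] > bv) { bv = xp[base + 1]; best = base + 1; }
          if (xp[base + H] > bv) { bv = xp[base + H]; best = base + H; }
          if (xp[base + H + 1] > bv) { bv = xp[base + H + 1]; best = base + H + 1; }
          out[o] = bv;
          amax[o] = best;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector amax,
                              int H, int W) {
  IntegerVector d = dout.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dxp = &dx[((size_t)n * C + c) * H * W];
      for (size_t k = 0; k < (size_t)Ho * Wo; ++k, ++o) dxp[amax[o]] += dout[o];
    }
  }
  return dx;
}

// 8-connected component labelling of a logical matrix (flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j0 = 0; j0 < W; ++j0) {
    for (int i0 = 0; i0 < H; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      ++next;
      stack.push_back(j0 * H + i0);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int i = p % H, j = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di, jj = j + dj;
            if (ii < 0 || jj < 0 || ii >= H || jj >= W) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              stack.push_back(jj * H + ii);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Round a double through IEEE 754 binary16 (round-to-nearest-even) and back.
static double to_half(double v) {
  float f = (float)v;
  uint32_t x;
  std::memcpy(&x, &f, 4);
  uint32_t sign = (x >> 16) & 0x8000u;
  int32_t exp = (int32_t)((x >> 23) & 0xFF) - 127 + 15;
  uint32_t mant = x & 0x7FFFFFu;
  uint16_t h;
  if (((x >> 23) & 0xFF) == 0xFF) {            // inf / nan
    h = (uint16_t)(sign | 0x7C00u | (mant ? 0x200u : 0u));
  } else if (exp >= 0x1F) {                    // overflow -> inf
    h = (uint16_t)(sign | 0x7C00u);
  } else if (exp <= 0) {                       // subnormal / underflow
    if (exp < -10) {
      h = (uint16_t)sign;
    } else {
      mant |= 0x800000u;
      int shift = 14 - exp;
      uint32_t half_mant = mant >> shift;
      uint32_t rem = mant & ((1u << shift) - 1);
      uint32_t halfway = 1u << (shift - 1);
      if (rem > halfway || (rem == halfway && (half_mant & 1u))) ++half_mant;
      h = (uint16_t)(sign | half_mant);
    }
  } else {
    uint32_t half_mant = mant >> 13;
    uint32_t rem = mant & 0x1FFFu;
    if (rem > 0x1000u || (rem == 0x1000u && (half_mant & 1u))) ++half_mant;
    h = (uint16_t)(sign | ((uint32_t)exp << 10) | half_mant);
    if (half_mant == 0x400u) h = (uint16_t)(sign | ((uint32_t)(exp + 1) << 10));
  }
  // decode
  uint32_t hs = (uint32_t)(h & 0x8000u) << 16;
  uint32_t he = (h >> 10) & 0x1F;
  uint32_t hm = h & 0x3FFu;
  uint32_t out;
  if (he == 0) {
    if (hm == 0) { out = hs; }
    else {
      int e = -1;
      do { ++e; hm <<= 1; } while (!(hm & 0x400u));
      out = hs | ((uint32_t)(127 - 15 - e) << 23) | ((hm & 0x3FFu) << 13);
    }
  } else if (he == 0x1F) {
    out = hs | 0x7F800000u | (hm << 13);
  } else {
    out = hs | ((he - 15 + 127) << 23) | (hm << 13);
  }
  std::memcpy(&f, &out, 4);
  return (double)f;
}

// [[Rcpp::export]]
NumericVector cpp_round_half(NumericVector x) {
  NumericVector out = clone(x);
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = to_half(out[i]);
  return out;
}
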