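// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Feature maps are numeric arrays laid out (H, W, B, C), column-major, so a
// channel plane is contiguous and channel concatenation is a plain vector
// concatenation. Convolutions run through float32 im2col + sgemm: position
// rows m = oh + Ho*(ow + Wo*b), patch columns r = kh + k*(kw + k*c), and the
// weight matrix is (k*k*C_in) x C_out, giving the BLAS-friendly tall-matrix
// product cols %*% W. Single precision more than doubles gemm throughput on
// one CPU at accuracy far beyond what SGD training resolves.

static void im2col_f32(const double* xp, int H, int W, int B, int C,
                       int k, int s, int p, arma::fmat& cols) {
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  const size_t M = (size_t)Ho * Wo * B;
  const size_t plane = (size_t)H * W * B;
  cols.set_size(M, (size_t)k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + plane * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        float* col = cols.colptr(kh + (size_t)k * (kw + (size_t)k * c));
        for (int b = 0; b < B; ++b) {
          for (int ow = 0; ow < Wo; ++ow) {
            int ww = ow * s - p + kw;
            float* dst = col + (size_t)Ho * (ow + (size_t)Wo * b);
            if (ww < 0 || ww >= W) {
              for (int oh = 0; oh < Ho; ++oh) dst[oh] = 0.0f;
              continue;
            }
            const double* src = xc + (size_t)H * (ww + (size_t)W * b);
            for (int oh = 0; oh < Ho; ++oh) {
              int hh = oh * s - p + kh;
              dst[oh] = (hh < 0 || hh >= H) ? 0.0f : (float)src[hh];
            }
          }
        }
      }
    }
  }
}

static void col2im_f32(const arma::fmat& dcols, int H, int W, int B, int C,
                       int k, int s, int p, double* dxp) {
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  const size_t plane = (size_t)H * W * B;
  std::fill(dxp, dxp + plane * C, 0.0);
  for (int c = 0; c < C; ++c) {
    double* xc = dxp + plane * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const float* col = dcols.colptr(kh + (size_t)k * (kw + (size_t)k * c));
        for (int b = 0; b < B; ++b) {
          for (int ow = 0; ow < Wo; ++ow) {
            int ww = ow * s - p + kw;
            if (ww < 0 || ww >= W) continue;
            const float* src = col + (size_t)Ho * (ow + (size_t)Wo * b);
            double* dst = xc + (size_t)H * (ww + (size_t)W * b);
            for (int oh = 0; oh < Ho; ++oh) {
              int hh = oh * s - p + kh;
              if (hh >= 0 && hh < H) dst[hh] += src[oh];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_f32_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix W, NumericVector b,
                             int k, int s, int p, bool relu) {
  const int H = dims[0], Wd = dims[1], B = dims[2], C = dims[3];
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (Wd + 2 * p - k) / s + 1;
  const int Co = W.ncol();
  const size_t M = (size_t)Ho * Wo * B;
  arma::fmat cols;
  if (k == 1 && s == 1 && p == 0) {
    cols.set_size((size_t)H * Wd * B, C);
    const double* xp = x.begin();
    float* cp = cols.memptr();
    const size_t n = cols.n_elem;
    for (size_t i = 0; i < n; ++i) cp[i] = (float)xp[i];
  } else {
    im2col_f32(x.begin(), H, Wd, B, C, k, s, p, cols);
  }
  arma::fmat Wf(W.nrow(), Co);
  std::copy(W.begin(), W.end(), Wf.memptr());
  arma::fmat O = cols * Wf;
  NumericVector out(M * Co);
  double* op = out.begin();
  const float* Op = O.memptr();
  for (int c = 0; c < Co; ++c) {
    const double bc = b[c];
    const float* src = Op + M * c;
    double* dst = op + M * c;
    if (relu) {
      for (size_t m = 0; m < M; ++m) {
        double v = (double)src[m] + bc;
        dst[m] = v > 0 ? v : 0.0;
      }
    } else {
      for (size_t m = 0; m < M; ++m) dst[m] = (double)src[m] + bc;
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, B, Co);
  return out;
}

// [[Rcpp::export]]
List conv2d_f32_bwd(NumericVector dout, NumericVector act, NumericVector x,
                    IntegerVector dims, NumericMatrix W,
                    int k, int s, int p, bool relu, bool need_dx) {
  const int H = dims[0], Wd = dims[1], B = dims[2], C = dims[3];
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (Wd + 2 * p - k) / s + 1;
  const int Co = W.ncol();
  const size_t M = (size_t)Ho * Wo * B;
  arma::fmat G(M, Co);
  {
    const double* gp = dout.begin();
    float* Gp = G.memptr();
    const size_t n = G.n_elem;
    if (relu) {
      const double* ap = act.begin();
      for (size_t i = 0; i < n; ++i) Gp[i] = ap[i] > 0 ? (float)gp[i] : 0.0f;
    } else {
      for (size_t i = 0; i < n; ++i) Gp[i] = (float)gp[i];
    }
  }
  arma::fmat cols;
  if (k == 1 && s == 1 && p == 0) {
    cols.set_size((size_t)H * Wd * B, C);
    const double* xp = x.begin();
    float* cp = cols.memptr();
    const size_t n = cols.n_elem;
    for (size_t i = 0; i < n; ++i) cp[i] = (float)xp[i];
  } else {
    im2col_f32(x.begin(), H, Wd, B, C, k, s, p, cols);
  }
  arma::fmat dWf = cols.t() * G;
  NumericMatrix dW(W.nrow(), Co);
  std::copy(dWf.begin(), dWf.end(), dW.begin());
  NumericVector db(Co);
  for (int c = 0; c < Co; ++c) {
    double acc = 0.0;
    const float* gc = G.colptr(c);
    for (size_t m = 0; m < M; ++m) acc += gc[m];
    db[c] = acc;
  }
  List res = List::create(_["dW"] = dW, _["db"] = db);
  if (need_dx) {
    arma::fmat Wf(W.nrow(), Co);
    std::copy(W.begin(), W.end(), Wf.memptr());
    NumericVector dx((size_t)H * Wd * B * C);
    if (k == 1 && s == 1 && p == 0) {
      arma::fmat dcols = G * Wf.t();
      double* dp = dx.begin();
      const float* sp = dcols.memptr();
      const size_t n = dcols.n_elem;
      for (size_t i = 0; i < n; ++i) dp[i] = (double)sp[i];
    } else {
      arma::fmat dcols = G * Wf.t();
      col2im_f32(dcols, H, Wd, B, C, k, s, p, dx.begin());
    }
    dx.attr("dim") = IntegerVector::create(H, Wd, B, C);
    res["dx"] = dx;
  }
  return res;
}

// 3x3-style max pooling on (H, W, B, C) arrays, argmax kept for backward.

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, IntegerVector dims,
                     int k, int s, int p) {
  const int H = dims[0], W = dims[1], B = dims[2], C = dims[3];
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  NumericVector out((size_t)Ho * Wo * B * C);
  IntegerVector arg((size_t)Ho * Wo * B * C);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  const size_t plane_in = (size_t)H * W * B;
  size_t o = 0;
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int kw = 0; kw < k; ++kw) {
            int ww = ow * s - p + kw;
            if (ww < 0 || ww >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hh = oh * s - p + kh;
              if (hh < 0 || hh >= H) continue;
              size_t idx = plane_in * c + hh +
                (size_t)H * (ww + (size_t)W * b);
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          }
          // column-major output order is oh fastest, then ow, b, c
          size_t oidx = (size_t)oh + (size_t)Ho *
            (ow + (size_t)Wo * (b + (size_t)B * c));
          op[oidx] = best;
          ap[oidx] = (int)besti + 1;  // 1-based for R
          ++o;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg,
                      _["Ho"] = Ho, _["Wo"] = Wo);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector argmax,
                              int n_in) {
  NumericVector dx(n_in);
  double* dp = dx.begin();
  const double* gp = dout.begin();
  const int* ap = argmax.begin();
  const size_t n = dout.size();
  for (size_t i = 0; i < n; ++i) dp[ap[i] - 1] += gp[i];
  return dx;
}

// Multi-head scaled dot-product attention over token arrays (d, N, S):
// S independent sequences of N tokens; d split into `heads` contiguous
// blocks. Scores are scaled by 1/sqrt(d_head) before a row-wise softmax.

// [[Rcpp::export]]
List attn_fwd_cpp(NumericVector Q, NumericVector K, NumericVector V,
                  int d, int N, int S, int heads) {
  const int dh = d / heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  NumericVector out((size_t)d * N * S);
  NumericVector A((size_t)N * N * heads * S);
  const double *qp = Q.begin(), *kp = K.begin(), *vp = V.begin();
  double *op = out.begin(), *apn = A.begin();
  std::vector<double> row(N);
  for (int s = 0; s < S; ++s) {
    const double* qs = qp + (size_t)d * N * s;
    const double* ks = kp + (size_t)d * N * s;
    const double* vs = vp + (size_t)d * N * s;
    double* os = op + (size_t)d * N * s;
    for (int h = 0; h < heads; ++h) {
      const int m0 = h * dh;
      double* As = apn + (size_t)N * N * (h + (size_t)heads * s);
      for (int i = 0; i < N; ++i) {
        double mx = R_NegInf;
        for (int j = 0; j < N; ++j) {
          double acc = 0.0;
          const double* qi = qs + m0 + (size_t)d * i;
          const double* kj = ks + m0 + (size_t)d * j;
          for (int m = 0; m < dh; ++m) acc += qi[m] * kj[m];
          row[j] = acc * scale;
          if (row[j] > mx) mx = row[j];
        }
        double z = 0.0;
        for (int j = 0; j < N; ++j) { row[j] = std::exp(row[j] - mx); z += row[j]; }
        for (int j = 0; j < N; ++j) As[i + (size_t)N * j] = row[j] / z;
      }
      for (int i = 0; i < N; ++i) {
        double* oi = os + m0 + (size_t)d * i;
        for (int m = 0; m < dh; ++m) oi[m] = 0.0;
        for (int j = 0; j < N; ++j) {
          const double a = As[i + (size_t)N * j];
          const double* vj = vs + m0 + (size_t)d * j;
          for (int m = 0; m < dh; ++m) oi[m] += a * vj[m];
        }
      }
    }
  }
  return List::create(_["out"] = out, _["attn"] = A);
}

// [[Rcpp::export]]
List attn_bwd_cpp(NumericVector dout, NumericVector Q, NumericVector K,
                  NumericVector V, NumericVector A,
                  int d, int N, int S, int heads) {
  const int dh = d / heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  NumericVector dQ((size_t)d * N * S), dK((size_t)d * N * S), dV((size_t)d * N * S);
  const double *gp = dout.begin(), *qp = Q.begin(), *kp = K.begin(),
               *vp = V.begin(), *apn = A.begin();
  double *dqp = dQ.begin(), *dkp = dK.begin(), *dvp = dV.begin();
  std::vector<double> dA((size_t)N * N), dS_((size_t)N * N);
  for (int s = 0; s < S; ++s) {
    const size_t base = (size_t)d * N * s;
    const double* gs = gp + base;
    const double* qs = qp + base;
    const double* ks = kp + base;
    const double* vs = vp + base;
    double* dqs = dqp + base;
    double* dks = dkp + base;
    double* dvs = dvp + base;
    for (int h = 0; h < heads; ++h) {
      const int m0 = h * dh;
      const double* As = apn + (size_t)N * N * (h + (size_t)heads * s);
      for (int j = 0; j < N; ++j) {
        double* dvj = dvs + m0 + (size_t)d * j;
        for (int m = 0; m < dh; ++m) dvj[m] = 0.0;
      }
      for (int i = 0; i < N; ++i) {
        const double* gi = gs + m0 + (size_t)d * i;
        for (int j = 0; j < N; ++j) {
          const double a = As[i + (size_t)N * j];
          const double* vj = vs + m0 + (size_t)d * j;
          double* dvj = dvs + m0 + (size_t)d * j;
          double acc = 0.0;
          for (int m = 0; m < dh; ++m) {
            dvj[m] += a * gi[m];
            acc += gi[m] * vj[m];
          }
          dA[i + (size_t)N * j] = acc;
        }
      }
      // softmax backward: dS = A * (dA - rowSums(dA * A))
      for (int i = 0; i < N; ++i) {
        double dot = 0.0;
        for (int j = 0; j < N; ++j)
          dot += dA[i + (size_t)N * j] * As[i + (size_t)N * j];
        for (int j = 0; j < N; ++j) {
          const size_t ij = i + (size_t)N * j;
          dS_[ij] = As[ij] * (dA[ij] - dot);
        }
      }
      for (int i = 0; i < N; ++i) {
        double* dqi = dqs + m0 + (size_t)d * i;
        for (int m = 0; m < dh; ++m) dqi[m] = 0.0;
      }
      for (int j = 0; j < N; ++j) {
        double* dkj = dks + m0 + (size_t)d * j;
        for (int m = 0; m < dh; ++m) dkj[m] = 0.0;
      }
      for (int i = 0; i < N; ++i) {
        double* dqi = dqs + m0 + (size_t)d * i;
        const double* qi = qs + m0 + (size_t)d * i;
        for (int j = 0; j < N; ++j) {
          const double ds = dS_[i + (size_t)N * j] * scale;
          const double* kj = ks + m0 + (size_t)d * j;
          double* dkj = dks + m0 + (size_t)d * j;
          for (int m = 0; m < dh; ++m) {
            dqi[m] += ds * kj[m];
            dkj[m] += ds * qi[m];
          }
        }
      }
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
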