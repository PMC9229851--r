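// Hot numerical kernels for the autodiff engine: image-to-column expansion
// for convolutions, batched matrix multiply for attention, and softmax.
// Feature maps are column-major (C, H, W, N) arrays.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// (C,H,W,N) -> (C*k*k, oh*ow*N); zero padding `pad`, square kernel `k`
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int C, int H, int W, int N,
                         int k, int stride, int pad, int oh, int ow) {
  const double *px = x.begin();
  NumericMatrix out(C * k * k, oh * ow * N);
  double *po = out.begin();
  const R_xlen_t colrows = (R_xlen_t)C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        R_xlen_t colidx = (R_xlen_t)i + (R_xlen_t)oh * (j + (R_xlen_t)ow * n);
        double *dst = po + colidx * colrows;
        for (int kw = 0; kw < k; ++kw) {
          int wsrc = j * stride + kw - pad;
          for (int kh = 0; kh < k; ++kh) {
            int hsrc = i * stride + kh - pad;
            double *d = dst + (R_xlen_t)C * (kh + k * kw);
            if (hsrc < 0 || hsrc >= H || wsrc < 0 || wsrc >= W) {
              std::fill(d, d + C, 0.0);
            } else {
              const double *s = px + (R_xlen_t)C *
                (hsrc + (R_xlen_t)H * (wsrc + (R_xlen_t)W * n));
              std::copy(s, s + C, d);
            }
          }
        }
      }
    }
  }
  return out;
}

// scatter-add inverse of cpp_im2col; returns (C,H,W,N)
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcol, int C, int H, int W, int N,
                         int k, int stride, int pad, int oh, int ow) {
  NumericVector out((R_xlen_t)C * H * W * N);
  double *po = out.begin();
  const double *pc = dcol.begin();
  const R_xlen_t colrows = (R_xlen_t)C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        R_xlen_t colidx = (R_xlen_t)i + (R_xlen_t)oh * (j + (R_xlen_t)ow * n);
        const double *src = pc + colidx * colrows;
        for (int kw = 0; kw < k; ++kw) {
          int wdst = j * stride + kw - pad;
          if (wdst < 0 || wdst >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int hdst = i * stride + kh - pad;
            if (hdst < 0 || hdst >= H) continue;
            const double *s = src + (R_xlen_t)C * (kh + k * kw);
            double *d = po + (R_xlen_t)C *
              (hdst + (R_xlen_t)H * (wdst + (R_xlen_t)W * n));
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, H, W, N);
  return out;
}

// shifted copy of x (C,H,W,N) by (dh,dw) with zero fill:
// out[:,i,j,n] = x[:,i+dh,j+dw,n]
static void shift_copy(const double *px, double *po,
                       int C, int H, int W, int N, int dh, int dw) {
  const int i0 = std::max(0, -dh), i1 = std::min(H, H - dh);
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < W; ++j) {
      int jsrc = j + dw;
      double *dst = po + (R_xlen_t)C * (0 + (R_xlen_t)H * (j + (R_xlen_t)W * n));
      if (jsrc < 0 || jsrc >= W || i1 <= i0) {
        std::fill(dst, dst + (R_xlen_t)C * H, 0.0);
        continue;
      }
      std::fill(dst, dst + (R_xlen_t)C * i0, 0.0);
      const double *src = px + (R_xlen_t)C *
        ((i0 + dh) + (R_xlen_t)H * (jsrc + (R_xlen_t)W * n));
      std::copy(src, src + (R_xlen_t)C * (i1 - i0), dst + (R_xlen_t)C * i0);
      std::fill(dst + (R_xlen_t)C * i1, dst + (R_xlen_t)C * H, 0.0);
    }
  }
}

// scatter-add of src into x shifted by (dh,dw): x[:,i+dh,j+dw,n] += src[:,i,j,n]
static void shift_add(const double *psrc, double *px,
                      int C, int H, int W, int N, int dh, int dw) {
  const int i0 = std::max(0, -dh), i1 = std::min(H, H - dh);
  if (i1 <= i0) return;
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < W; ++j) {
      int jdst = j + dw;
      if (jdst < 0 || jdst >= W) continue;
      const double *s = psrc + (R_xlen_t)C * (i0 + (R_xlen_t)H * (j + (R_xlen_t)W * n));
      double *d = px + (R_xlen_t)C * ((i0 + dh) + (R_xlen_t)H * (jdst + (R_xlen_t)W * n));
      R_xlen_t len = (R_xlen_t)C * (i1 - i0);
      for (R_xlen_t t = 0; t < len; ++t) d[t] += s[t];
    }
  }
}

// direct stride-1 'same' convolution via shift-and-GEMM over the k*k taps;
// w is (Co,Ci,k,k); pad = (k-1)/2
// [[Rcpp::export]]
NumericVector cpp_conv_same_fwd(NumericVector x, NumericVector w,
                                int C, int H, int W, int N, int Co, int k) {
  const int pad = (k - 1) / 2;
  const R_xlen_t M = (R_xlen_t)H * W * N;
  NumericVector y((R_xlen_t)Co * M);
  std::vector<double> xs((R_xlen_t)C * M);
  std::vector<double> wk((R_xlen_t)Co * C);
  arma::mat Y(y.begin(), Co, M, false, true);
  arma::mat Xs(xs.data(), C, M, false, true);
  arma::mat Wk(wk.data(), Co, C, false, true);
  const double *pw = w.begin();
  for (int kw = 0; kw < k; ++kw) {
    for (int kh = 0; kh < k; ++kh) {
      // w[o,c,kh,kw] -> Wk(o,c)
      for (int c = 0; c < C; ++c)
        for (int o = 0; o < Co; ++o)
          wk[o + (R_xlen_t)Co * c] =
            pw[o + (R_xlen_t)Co * (c + (R_xlen_t)C * (kh + (R_xlen_t)k * kw))];
      shift_copy(x.begin(), xs.data(), C, H, W, N, kh - pad, kw - pad);
      Y += Wk * Xs;
    }
  }
  y.attr("dim") = IntegerVector::create(Co, H, W, N);
  return y;
}

// backward of cpp_conv_same_fwd: returns dx (C,H,W,N) and dw (Co,Ci,k,k)
// [[Rcpp::export]]
List cpp_conv_same_bwd(NumericVector x, NumericVector w, NumericVector gy,
                       int C, int H, int W, int N, int Co, int k) {
  const int pad = (k - 1) / 2;
  const R_xlen_t M = (R_xlen_t)H * W * N;
  NumericVector dx((R_xlen_t)C * M);
  NumericVector dw(w.size());
  std::vector<double> xs((R_xlen_t)C * M);
  std::vector<double> dxs((R_xlen_t)C * M);
  std::vector<double> wk((R_xlen_t)Co * C);
  arma::mat G(const_cast<double*>(gy.begin()), Co, M, false, true);
  arma::mat Xs(xs.data(), C, M, false, true);
  arma::mat dXs(dxs.data(), C, M, false, true);
  arma::mat Wk(wk.data(), Co, C, false, true);
  const double *pw = w.begin();
  double *pdw = dw.begin();
  for (int kw = 0; kw < k; ++kw) {
    for (int kh = 0; kh < k; ++kh) {
      for (int c = 0; c < C; ++c)
        for (int o = 0; o < Co; ++o)
          wk[o + (R_xlen_t)Co * c] =
            pw[o + (R_xlen_t)Co * (c + (R_xlen_t)C * (kh + (R_xlen_t)k * kw))];
      shift_copy(x.begin(), xs.data(), C, H, W, N, kh - pad, kw - pad);
      arma::mat dWk = G * Xs.t();
      for (int c = 0; c < C; ++c)
        for (int o = 0; o < Co; ++o)
          pdw[o + (R_xlen_t)Co * (c + (R_xlen_t)C * (kh + (R_xlen_t)k * kw))] = dWk(o, c);
      dXs = Wk.t() * G;
      shift_add(dxs.data(), dx.begin(), C, H, W, N, kh - pad, kw - pad);
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  dw.attr("dim") = IntegerVector::create(Co, C, k, k);
  return List::create(Named("dx") = dx, Named("dw") = dw);
}

// depthwise 3x3 stride-1 pad-1 convolution; w (C,3,3)
// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w,
                             int C, int H, int W, int N) {
  NumericVector y(x.size());
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  for (int kw = 0; kw < 3; ++kw) {
    int dw_ = kw - 1;
    for (int kh = 0; kh < 3; ++kh) {
      int dh = kh - 1;
      const int i0 = std::max(0, -dh), i1 = std::min(H, H - dh);
      if (i1 <= i0) continue;
      const double *wk = pw + (R_xlen_t)C * (kh + 3 * kw);
      for (int n = 0; n < N; ++n) {
        for (int j = 0; j < W; ++j) {
          int jsrc = j + dw_;
          if (jsrc < 0 || jsrc >= W) continue;
          const double *s = px + (R_xlen_t)C * ((i0 + dh) + (R_xlen_t)H * (jsrc + (R_xlen_t)W * n));
          double *d = py + (R_xlen_t)C * (i0 + (R_xlen_t)H * (j + (R_xlen_t)W * n));
          for (int i = i0; i < i1; ++i) {
            for (int c = 0; c < C; ++c) d[c] += wk[c] * s[c];
            s += C; d += C;
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, H, W, N);
  return y;
}

// backward of depthwise conv: returns dx and dw given upstream g
// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector g,
                    int C, int H, int W, int N) {
  NumericVector dx(x.size());
  NumericVector dwv(w.size());
  const double *px = x.begin(), *pw = w.begin(), *pg = g.begin();
  double *pdx = dx.begin(), *pdw = dwv.begin();
  for (int kw = 0; kw < 3; ++kw) {
    int dw_ = kw - 1;
    for (int kh = 0; kh < 3; ++kh) {
      int dh = kh - 1;
      const int i0 = std::max(0, -dh), i1 = std::min(H, H - dh);
      if (i1 <= i0) continue;
      const double *wk = pw + (R_xlen_t)C * (kh + 3 * kw);
      double *dwk = pdw + (R_xlen_t)C * (kh + 3 * kw);
      for (int n = 0; n < N; ++n) {
        for (int j = 0; j < W; ++j) {
          int jsrc = j + dw_;
          if (jsrc < 0 || jsrc >= W) continue;
          const double *s = px + (R_xlen_t)C * ((i0 + dh) + (R_xlen_t)H * (jsrc + (R_xlen_t)W * n));
          double *ds = pdx + (R_xlen_t)C * ((i0 + dh) + (R_xlen_t)H * (jsrc + (R_xlen_t)W * n));
          const double *gg = pg + (R_xlen_t)C * (i0 + (R_xlen_t)H * (j + (R_xlen_t)W * n));
          for (int i = i0; i < i1; ++i) {
            for (int c = 0; c < C; ++c) {
              ds[c] += wk[c] * gg[c];
              dwk[c] += s[c] * gg[c];
            }
            s += C; ds += C; gg += C;
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  dwv.attr("dim") = IntegerVector::create(C, 3, 3);
  return List::create(Named("dx") = dx, Named("dw") = dwv);
}

// batched matmul with optional per-slice transposes:
// a (p,q,B), b (q,r,B) -> (p,r,B); ta/tb transpose the slices first
// [[Rcpp::export]]
NumericVector cpp_bmm(NumericVector a, NumericVector b,
                      int p, int q, int B, int r, bool ta, bool tb) {
  // slice dims as stored: a is (ta ? (q,p) : (p,q)), b is (tb ? (r,q) : (q,r))
  int a1 = ta ? q : p, a2 = ta ? p : q;
  int b1 = tb ? r : q, b2 = tb ? q : r;
  NumericVector out((R_xlen_t)p * r * B);
  double *pa = a.begin(), *pb = b.begin(), *po = out.begin();
  for (int s = 0; s < B; ++s) {
    arma::mat A(pa + (R_xlen_t)a1 * a2 * s, a1, a2, false, true);
    arma::mat Bm(pb + (R_xlen_t)b1 * b2 * s, b1, b2, false, true);
    arma::mat O(po + (R_xlen_t)p * r * s, p, r, false, true);
    if (!ta && !tb)      O = A * Bm;
    else if (ta && !tb)  O = A.t() * Bm;
    else if (!ta && tb)  O = A * Bm.t();
    else                 O = A.t() * Bm.t();
  }
  out.attr("dim") = IntegerVector::create(p, r, B);
  return out;
}

// ---- fused elementwise / normalization kernels -----------------------------

// tanh-approximated GELU, forward
// [[Rcpp::export]]
NumericVector cpp_gelu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double k = std::sqrt(2.0 / M_PI);
  const double *px = x.begin(); double *py = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = px[i];
    double t = std::tanh(k * (v + 0.044715 * v * v * v));
    py[i] = 0.5 * v * (1.0 + t);
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// GELU backward from the input
// [[Rcpp::export]]
NumericVector cpp_gelu_bwd(NumericVector x, NumericVector g) {
  NumericVector dx(x.size());
  const double k = std::sqrt(2.0 / M_PI);
  const double *px = x.begin(), *pg = g.begin(); double *pd = dx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = px[i];
    double t = std::tanh(k * (v + 0.044715 * v * v * v));
    double du = k * (1.0 + 3.0 * 0.044715 * v * v);
    pd[i] = pg[i] * (0.5 * (1.0 + t) + 0.5 * v * (1.0 - t * t) * du);
  }
  dx.attr("dim") = x.attr("dim");
  return dx;
}

// layer norm over the leading (channel) dimension of runs of length C;
// returns y and per-run mu / invstd for the backward pass
// [[Rcpp::export]]
List cpp_ln_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                int C, double eps) {
  R_xlen_t M = x.size() / C;
  NumericVector y(x.size());
  NumericVector mu(M), invstd(M);
  const double *px = x.begin(), *pgm = gamma.begin(), *pbt = beta.begin();
  double *py = y.begin(), *pmu = mu.begin(), *pis = invstd.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *c = px + m * C;
    double s = 0.0;
    for (int i = 0; i < C; ++i) s += c[i];
    double mean = s / C, v = 0.0;
    for (int i = 0; i < C; ++i) { double d = c[i] - mean; v += d * d; }
    double is = 1.0 / std::sqrt(v / C + eps);
    pmu[m] = mean; pis[m] = is;
    double *o = py + m * C;
    for (int i = 0; i < C; ++i) o[i] = (c[i] - mean) * is * pgm[i] + pbt[i];
  }
  y.attr("dim") = x.attr("dim");
  return List::create(Named("y") = y, Named("mu") = mu, Named("invstd") = invstd);
}

// layer norm backward
// [[Rcpp::export]]
List cpp_ln_bwd(NumericVector x, NumericVector gamma, NumericVector g,
                NumericVector mu, NumericVector invstd, int C) {
  R_xlen_t M = x.size() / C;
  NumericVector dx(x.size());
  NumericVector dgamma(C), dbeta(C);
  const double *px = x.begin(), *pgm = gamma.begin(), *pg = g.begin();
  const double *pmu = mu.begin(), *pis = invstd.begin();
  double *pdx = dx.begin(), *pdg = dgamma.begin(), *pdb = dbeta.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *c = px + m * C, *gg = pg + m * C;
    double *o = pdx + m * C;
    double mean = pmu[m], is = pis[m];
    double t1 = 0.0, t2 = 0.0;
    for (int i = 0; i < C; ++i) {
      double xh = (c[i] - mean) * is;
      double dxh = gg[i] * pgm[i];
      t1 += dxh; t2 += dxh * xh;
      pdg[i] += gg[i] * xh;
      pdb[i] += gg[i];
    }
    for (int i = 0; i < C; ++i) {
      double xh = (c[i] - mean) * is;
      double dxh = gg[i] * pgm[i];
      o[i] = (is / C) * (C * dxh - t1 - xh * t2);
    }
  }
  dx.attr("dim") = x.attr("dim");
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// per-channel mean and variance over (H,W,N) of a (C,...) array
// [[Rcpp::export]]
List cpp_channel_stats(NumericVector x, int C) {
  R_xlen_t M = x.size() / C;
  NumericVector mu(C), var(C);
  const double *px = x.begin();
  double *pmu = mu.begin(), *pv = var.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *c = px + m * C;
    for (int i = 0; i < C; ++i) pmu[i] += c[i];
  }
  for (int i = 0; i < C; ++i) pmu[i] /= M;
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *c = px + m * C;
    for (int i = 0; i < C; ++i) { double d = c[i] - pmu[i]; pv[i] += d * d; }
  }
  for (int i = 0; i < C; ++i) pv[i] /= M;
  return List::create(Named("mean") = mu, Named("var") = var);
}

// batch norm forward given channel stats: y = (x-mu)*invstd*gamma + beta
// [[Rcpp::export]]
NumericVector cpp_bn_apply(NumericVector x, NumericVector mu,
                           NumericVector invstd, NumericVector gamma,
                           NumericVector beta, int C) {
  R_xlen_t M = x.size() / C;
  NumericVector y(x.size());
  const double *px = x.begin(), *pmu = mu.begin(), *pis = invstd.begin();
  const double *pgm = gamma.begin(), *pbt = beta.begin();
  double *py = y.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *c = px + m * C;
    double *o = py + m * C;
    for (int i = 0; i < C; ++i) o[i] = (c[i] - pmu[i]) * pis[i] * pgm[i] + pbt[i];
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// batch norm backward (training mode: stats were computed from the batch)
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gamma, NumericVector g,
                NumericVector mu, NumericVector invstd, int C, bool train) {
  R_xlen_t M = x.size() / C;
  NumericVector dx(x.size());
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> t1(C, 0.0), t2(C, 0.0);
  const double *px = x.begin(), *pgm = gamma.begin(), *pg = g.begin();
  const double *pmu = mu.begin(), *pis = invstd.begin();
  double *pdx = dx.begin(), *pdg = dgamma.begin(), *pdb = dbeta.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *c = px + m * C, *gg = pg + m * C;
    for (int i = 0; i < C; ++i) {
      double xh = (c[i] - pmu[i]) * pis[i];
      double dxh = gg[i] * pgm[i];
      pdg[i] += gg[i] * xh;
      pdb[i] += gg[i];
      t1[i] += dxh; t2[i] += dxh * xh;
    }
  }
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *c = px + m * C, *gg = pg + m * C;
    double *o = pdx + m * C;
    for (int i = 0; i < C; ++i) {
      double dxh = gg[i] * pgm[i];
      if (train) {
        double xh = (c[i] - pmu[i]) * pis[i];
        o[i] = (pis[i] / M) * (M * dxh - t1[i] - xh * t2[i]);
      } else {
        o[i] = dxh * pis[i];
      }
    }
  }
  dx.attr("dim") = x.attr("dim");
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// ---- fused criss-cross position attention ---------------------------------
//
// For every pixel x, logits of its query vector (from M) against the key
// vectors (from N) at the H+W-1 positions sharing x's row or column are
// softmax-normalized and used to aggregate the value map V over that set.
// Slot layout: s in [0,H) column direction (s==i masked to -inf so the
// pixel itself is counted once), s in [H,H+W) row direction.

// forward: returns Y (C,H,W,Nb) aggregation (no residual) and A (H+W,H,W,Nb)
// [[Rcpp::export]]
List cpp_cc_fwd(NumericVector M, NumericVector N, NumericVector V,
                int C, int H, int W, int Nb) {
  const int S = H + W;
  NumericVector Y((R_xlen_t)C * H * W * Nb);
  NumericVector A((R_xlen_t)S * H * W * Nb);
  const double *pM = M.begin(), *pN = N.begin(), *pV = V.begin();
  double *pY = Y.begin(), *pA = A.begin();
  arma::mat Mrow(C, W), Nrow(C, W), Vrow(C, W), Trow(W, W), Arow(W, W), Yrow(C, W);
  arma::mat Tcol(H, H), Acol(H, H);
  for (int n = 0; n < Nb; ++n) {
    const R_xlen_t imgoff = (R_xlen_t)C * H * W * n;
    // column-direction logits -> A slots [0,H)
    for (int j = 0; j < W; ++j) {
      const double *mj = pM + imgoff + (R_xlen_t)C * H * j;
      const double *nj = pN + imgoff + (R_xlen_t)C * H * j;
      arma::mat Mj(const_cast<double*>(mj), C, H, false, true);
      arma::mat Nj(const_cast<double*>(nj), C, H, false, true);
      Tcol = Nj.t() * Mj;   // (i', i)
      double *az = pA + (R_xlen_t)S * H * (j + (R_xlen_t)W * n);
      for (int i = 0; i < H; ++i)
        for (int s = 0; s < H; ++s)
          az[s + (R_xlen_t)S * i] = Tcol(s, i);
    }
    // row-direction logits -> A slots [H,H+W)
    for (int i = 0; i < H; ++i) {
      for (int j = 0; j < W; ++j) {
        const double *src = pM + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        const double *srn = pN + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        std::copy(src, src + C, Mrow.colptr(j));
        std::copy(srn, srn + C, Nrow.colptr(j));
      }
      Trow = Nrow.t() * Mrow;  // (j', j)
      for (int j = 0; j < W; ++j) {
        double *az = pA + (R_xlen_t)S * (i + (R_xlen_t)H * (j + (R_xlen_t)W * n));
        for (int s = 0; s < W; ++s) az[H + s] = Trow(s, j);
      }
    }
    // mask self column slot + softmax per pixel
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double *az = pA + (R_xlen_t)S * (i + (R_xlen_t)H * (j + (R_xlen_t)W * n));
        az[i] = -INFINITY;
        double mx = az[0];
        for (int s = 1; s < S; ++s) if (az[s] > mx) mx = az[s];
        double sum = 0.0;
        for (int s = 0; s < S; ++s) { az[s] = std::exp(az[s] - mx); sum += az[s]; }
        for (int s = 0; s < S; ++s) az[s] /= sum;
      }
    }
    // aggregation: column direction
    for (int j = 0; j < W; ++j) {
      const double *vj = pV + imgoff + (R_xlen_t)C * H * j;
      arma::mat Vj(const_cast<double*>(vj), C, H, false, true);
      const double *az = pA + (R_xlen_t)S * H * (j + (R_xlen_t)W * n);
      for (int i = 0; i < H; ++i)
        for (int s = 0; s < H; ++s)
          Acol(s, i) = az[s + (R_xlen_t)S * i];
      arma::mat Yj(pY + imgoff + (R_xlen_t)C * H * j, C, H, false, true);
      Yj = Vj * Acol;
    }
    // aggregation: row direction
    for (int i = 0; i < H; ++i) {
      for (int j = 0; j < W; ++j) {
        const double *srv = pV + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        std::copy(srv, srv + C, Vrow.colptr(j));
        const double *az = pA + (R_xlen_t)S * (i + (R_xlen_t)H * (j + (R_xlen_t)W * n));
        for (int s = 0; s < W; ++s) Arow(s, j) = az[H + s];
      }
      Yrow = Vrow * Arow;
      for (int j = 0; j < W; ++j) {
        double *dst = pY + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        const double *src = Yrow.colptr(j);
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(C, H, W, Nb);
  A.attr("dim") = IntegerVector::create(S, H, W, Nb);
  return List::create(Named("Y") = Y, Named("A") = A);
}

// backward of cpp_cc_fwd given retained A and upstream gradient dY
// [[Rcpp::export]]
List cpp_cc_bwd(NumericVector M, NumericVector N, NumericVector V,
                NumericVector A, NumericVector dY,
                int C, int H, int W, int Nb) {
  const int S = H + W;
  NumericVector dM(M.size()), dN(N.size()), dV(V.size());
  NumericVector dZ(A.size());
  const double *pM = M.begin(), *pN = N.begin(), *pV = V.begin();
  const double *pA = A.begin(), *pG = dY.begin();
  double *pdM = dM.begin(), *pdN = dN.begin(), *pdV = dV.begin();
  double *pdZ = dZ.begin();
  arma::mat Acol(H, H), dAcol(H, H), dZcol(H, H);
  arma::mat Arow(W, W), dArow(W, W), dZrow(W, W);
  arma::mat Mrow(C, W), Nrow(C, W), Vrow(C, W), Grow(C, W), Tmp(C, W);
  for (int n = 0; n < Nb; ++n) {
    const R_xlen_t imgoff = (R_xlen_t)C * H * W * n;
    // dA (both directions) into dZ buffer first
    for (int j = 0; j < W; ++j) {
      const double *vj = pV + imgoff + (R_xlen_t)C * H * j;
      const double *gj = pG + imgoff + (R_xlen_t)C * H * j;
      arma::mat Vj(const_cast<double*>(vj), C, H, false, true);
      arma::mat Gj(const_cast<double*>(gj), C, H, false, true);
      dAcol = Vj.t() * Gj;     // (i', i)
      double *dz = pdZ + (R_xlen_t)S * H * (j + (R_xlen_t)W * n);
      for (int i = 0; i < H; ++i)
        for (int s = 0; s < H; ++s)
          dz[s + (R_xlen_t)S * i] = dAcol(s, i);
    }
    for (int i = 0; i < H; ++i) {
      for (int j = 0; j < W; ++j) {
        const double *srv = pV + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        const double *srg = pG + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        std::copy(srv, srv + C, Vrow.colptr(j));
        std::copy(srg, srg + C, Grow.colptr(j));
      }
      dArow = Vrow.t() * Grow;  // (j', j)
      for (int j = 0; j < W; ++j) {
        double *dz = pdZ + (R_xlen_t)S * (i + (R_xlen_t)H * (j + (R_xlen_t)W * n));
        for (int s = 0; s < W; ++s) dz[H + s] = dArow(s, j);
      }
    }
    // softmax backward per pixel: dZ = A * (dA - sum(A*dA))
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        R_xlen_t off = (R_xlen_t)S * (i + (R_xlen_t)H * (j + (R_xlen_t)W * n));
        const double *a = pA + off;
        double *dz = pdZ + off;
        double sum = 0.0;
        for (int s = 0; s < S; ++s) sum += a[s] * dz[s];
        for (int s = 0; s < S; ++s) dz[s] = a[s] * (dz[s] - sum);
      }
    }
    // dV and dM/dN, column direction
    for (int j = 0; j < W; ++j) {
      const double *gj = pG + imgoff + (R_xlen_t)C * H * j;
      const double *mj = pM + imgoff + (R_xlen_t)C * H * j;
      const double *nj = pN + imgoff + (R_xlen_t)C * H * j;
      arma::mat Gj(const_cast<double*>(gj), C, H, false, true);
      arma::mat Mj(const_cast<double*>(mj), C, H, false, true);
      arma::mat Nj(const_cast<double*>(nj), C, H, false, true);
      const double *az = pA + (R_xlen_t)S * H * (j + (R_xlen_t)W * n);
      const double *dz = pdZ + (R_xlen_t)S * H * (j + (R_xlen_t)W * n);
      for (int i = 0; i < H; ++i)
        for (int s = 0; s < H; ++s) {
          Acol(s, i) = az[s + (R_xlen_t)S * i];
          dZcol(s, i) = dz[s + (R_xlen_t)S * i];
        }
      arma::mat dVj(pdV + imgoff + (R_xlen_t)C * H * j, C, H, false, true);
      dVj += Gj * Acol.t();
      arma::mat dMj(pdM + imgoff + (R_xlen_t)C * H * j, C, H, false, true);
      dMj += Nj * dZcol;
      arma::mat dNj(pdN + imgoff + (R_xlen_t)C * H * j, C, H, false, true);
      dNj += Mj * dZcol.t();
    }
    // dV and dM/dN, row direction
    for (int i = 0; i < H; ++i) {
      for (int j = 0; j < W; ++j) {
        const double *srv = pV + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        const double *srg = pG + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        const double *srm = pM + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        const double *srn = pN + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        std::copy(srv, srv + C, Vrow.colptr(j));
        std::copy(srg, srg + C, Grow.colptr(j));
        std::copy(srm, srm + C, Mrow.colptr(j));
        std::copy(srn, srn + C, Nrow.colptr(j));
        const double *az = pA + (R_xlen_t)S * (i + (R_xlen_t)H * (j + (R_xlen_t)W * n));
        const double *dz = pdZ + (R_xlen_t)S * (i + (R_xlen_t)H * (j + (R_xlen_t)W * n));
        for (int s = 0; s < W; ++s) {
          Arow(s, j) = az[H + s];
          dZrow(s, j) = dz[H + s];
        }
      }
      // accumulate strided back into row i
      Tmp = Grow * Arow.t();          // dVrow
      for (int j = 0; j < W; ++j) {
        double *dst = pdV + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        const double *src = Tmp.colptr(j);
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
      Tmp = Nrow * dZrow;             // dMrow
      for (int j = 0; j < W; ++j) {
        double *dst = pdM + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        const double *src = Tmp.colptr(j);
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
      Tmp = Mrow * dZrow.t();         // dNrow
      for (int j = 0; j < W; ++j) {
        double *dst = pdN + imgoff + (R_xlen_t)C * (i + (R_xlen_t)H * j);
        const double *src = Tmp.colptr(j);
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
  IntegerVector dm = IntegerVector::create(C, H, W, Nb);
  dM.attr("dim") = dm; dN.attr("dim") = dm; dV.attr("dim") = dm;
  return List::create(Named("dM") = dM, Named("dN") = dN, Named("dV") = dV);
}

// softmax over consecutive runs of length K (the first array dimension);
// -inf entries get zero weight
// [[Rcpp::export]]
NumericVector cpp_softmax_cols(NumericVector x, int K) {
  R_xlen_t M = x.size() / K;
  NumericVector out(x.size());
  const double *px = x.begin();
  double *po = out.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *c = px + m * K;
    double *o = po + m * K;
    double mx = c[0];
    for (int i = 1; i < K; ++i) if (c[i] > mx) mx = c[i];
    double s = 0.0;
    for (int i = 0; i < K; ++i) { o[i] = std::exp(c[i] - mx); s += o[i]; }
    for (int i = 0; i < K; ++i) o[i] /= s;
  }
  return out;
}

// backward of run-wise softmax: dx = a * (g - runsum(a*g))
// [[Rcpp::export]]
NumericVector cpp_softmax_cols_bw(NumericVector a, NumericVector g, int K) {
  R_xlen_t M = a.size() / K;
  NumericVector out(a.size());
  const double *pa0 = a.begin(), *pg0 = g.begin();
  double *po = out.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *pa = pa0 + m * K, *pg = pg0 + m * K;
    double *o = po + m * K;
    double s = 0.0;
    for (int i = 0; i < K; ++i) s += pa[i] * pg[i];
    for (int i = 0; i < K; ++i) o[i] = pa[i] * (pg[i] - s);
  }
  return out;
}
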