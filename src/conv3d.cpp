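#include <Rcpp.h>
using namespace Rcpp;

// 3x3x3 im2col with zero padding 1 for a (D,H,W,C) column-major array.
// Row r of the output corresponds to output voxel r in column-major (d,h,w)
// order; columns are ordered channel-major: c * 27 + offset, offsets in
// column-major (dz,dy,dx) order over {-1,0,1}^3.
// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector x, int D, int H, int W, int C) {
  const int nvox = D * H * W;
  NumericMatrix out(nvox, 27 * C);
  const double *xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (R_xlen_t)c * nvox;
    for (int off = 0; off < 27; ++off) {
      const int dz = off % 3 - 1;
      const int dy = (off / 3) % 3 - 1;
      const int dx = off / 9 - 1;
      double *col = &out(0, c * 27 + off);
      R_xlen_t r = 0;
      for (int w = 0; w < W; ++w) {
        const int ww = w + dx;
        for (int h = 0; h < H; ++h) {
          const int hh = h + dy;
          for (int d = 0; d < D; ++d, ++r) {
            const int dd = d + dz;
            if (dd < 0 || dd >= D || hh < 0 || hh >= H || ww < 0 || ww >= W)
              col[r] = 0.0;
            else
              col[r] = xc[dd + (R_xlen_t)D * (hh + (R_xlen_t)H * ww)];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3d: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix dP, int D, int H, int W, int C) {
  const int nvox = D * H * W;
  NumericVector dx_(nvox * (R_xlen_t)C);
  double *gp = dx_.begin();
  for (int c = 0; c < C; ++c) {
    double *gc = gp + (R_xlen_t)c * nvox;
    for (int off = 0; off < 27; ++off) {
      const int dz = off % 3 - 1;
      const int dy = (off / 3) % 3 - 1;
      const int dx = off / 9 - 1;
      const double *col = &dP(0, c * 27 + off);
      R_xlen_t r = 0;
      for (int w = 0; w < W; ++w) {
        const int ww = w + dx;
        for (int h = 0; h < H; ++h) {
          const int hh = h + dy;
          for (int d = 0; d < D; ++d, ++r) {
            const int dd = d + dz;
            if (dd >= 0 && dd < D && hh >= 0 && hh < H && ww >= 0 && ww < W)
              gc[dd + (R_xlen_t)D * (hh + (R_xlen_t)H * ww)] += col[r];
          }
        }
      }
    }
  }
  return dx_;
}

// Per-column mean and (biased) variance in one pass.
// [[Rcpp::export]]
List bn_stats(NumericMatrix Z) {
  const R_xlen_t n = Z.nrow();
  const int p = Z.ncol();
  NumericVector mean(p), var(p);
  for (int j = 0; j < p; ++j) {
    const double *z = &Z(0, j);
    double s = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) { s += z[i]; s2 += z[i] * z[i]; }
    const double mu = s / n;
    mean[j] = mu;
    var[j] = s2 / n - mu * mu;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// Fused batch-norm + affine + ReLU forward. Returns the normalized values
// (zhat, needed for the gamma gradient) and the post-ReLU activations.
// [[Rcpp::export]]
List bn_relu_fwd(NumericMatrix Z, NumericVector mean, NumericVector inv_sd,
                 NumericVector gamma, NumericVector beta) {
  const R_xlen_t n = Z.nrow();
  const int p = Z.ncol();
  NumericMatrix zhat(n, p), act(n, p);
  for (int j = 0; j < p; ++j) {
    const double *z = &Z(0, j);
    double *zh = &zhat(0, j);
    double *a = &act(0, j);
    const double mu = mean[j], is = inv_sd[j], g = gamma[j], b = beta[j];
    for (R_xlen_t i = 0; i < n; ++i) {
      const double v = (z[i] - mu) * is;
      zh[i] = v;
      const double av = g * v + b;
      a[i] = av > 0.0 ? av : 0.0;
    }
  }
  return List::create(_["zhat"] = zhat, _["act"] = act);
}

// Fused ReLU + batch-norm backward. act > 0 marks the active ReLU units
// (pre-ReLU value equal to the post-ReLU value there). In train mode the
// batch-statistics terms are included; in eval mode the affine-only path.
// [[Rcpp::export]]
List bn_relu_bwd(NumericMatrix dR, NumericMatrix act, NumericMatrix zhat,
                 NumericVector gamma, NumericVector inv_sd, bool train) {
  const R_xlen_t n = dR.nrow();
  const int p = dR.ncol();
  NumericMatrix dZ(n, p);
  NumericVector dgamma(p), dbeta(p);
  for (int j = 0; j < p; ++j) {
    const double *dr = &dR(0, j);
    const double *a = &act(0, j);
    const double *zh = &zhat(0, j);
    double *dz = &dZ(0, j);
    const double g = gamma[j], is = inv_sd[j];
    double sum_da = 0.0, sum_dazh = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double da = a[i] > 0.0 ? dr[i] : 0.0;
      dz[i] = da;            // store dA temporarily
      sum_da += da;
      sum_dazh += da * zh[i];
    }
    dgamma[j] = sum_dazh;
    dbeta[j] = sum_da;
    if (train) {
      const double m1 = sum_da / n, m2 = sum_dazh / n;
      for (R_xlen_t i = 0; i < n; ++i)
        dz[i] = (dz[i] * g - m1 * g - zh[i] * m2 * g) * is;
    } else {
      for (R_xlen_t i = 0; i < n; ++i) dz[i] = dz[i] * g * is;
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Batched 2x max-pool over a (B*D*H*W) x C activation matrix whose rows are
// B contiguous sample blocks in column-major (d,h,w) order. Returns the
// pooled (B*D2*H2*W2) x C matrix and the source row of each pooled element
// (1-based, for the scatter in the backward pass).
// [[Rcpp::export]]
List maxpool3d_fwd(NumericMatrix R_, int D, int H, int W, int B) {
  const int C = R_.ncol();
  const int nvox = D * H * W;
  const int D2 = D / 2, H2 = H / 2, W2 = W / 2;
  const int nout = D2 * H2 * W2;
  NumericMatrix pooled((R_xlen_t)B * nout, C);
  IntegerMatrix sel((R_xlen_t)B * nout, C);
  for (int j = 0; j < C; ++j) {
    const double *r = &R_(0, j);
    double *po = &pooled(0, j);
    int *se = &sel(0, j);
    for (int b = 0; b < B; ++b) {
      const R_xlen_t base_in = (R_xlen_t)b * nvox;
      const R_xlen_t base_out = (R_xlen_t)b * nout;
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h2 = 0; h2 < H2; ++h2) {
          for (int d2 = 0; d2 < D2; ++d2) {
            double best = -1e300;
            R_xlen_t best_row = 0;
            for (int ow = 0; ow < 2; ++ow)
              for (int oh = 0; oh < 2; ++oh)
                for (int od = 0; od < 2; ++od) {
                  const R_xlen_t row = base_in + (2 * d2 + od) +
                    (R_xlen_t)D * (2 * h2 + oh) +
                    (R_xlen_t)D * H * (2 * w2 + ow);
                  if (r[row] > best) { best = r[row]; best_row = row; }
                }
            const R_xlen_t out_row = base_out + d2 + (R_xlen_t)D2 * h2 +
              (R_xlen_t)D2 * H2 * w2;
            po[out_row] = best;
            se[out_row] = (int)best_row + 1;
          }
        }
      }
    }
  }
  return List::create(_["pooled"] = pooled, _["sel"] = sel);
}

// Scatter pooled gradients back to the selected pre-pool rows.
// [[Rcpp::export]]
NumericMatrix maxpool3d_bwd(NumericMatrix dpool, IntegerMatrix sel, int n_in) {
  const int C = dpool.ncol();
  NumericMatrix dR(n_in, C);
  for (int j = 0; j < C; ++j) {
    const double *dp = &dpool(0, j);
    const int *se = &sel(0, j);
    double *dr = &dR(0, j);
    for (R_xlen_t i = 0; i < dpool.nrow(); ++i) dr[se[i] - 1] += dp[i];
  }
  return dR;
}

// Batched im2col: xbig is a (B*D*H*W) x C activation matrix (B contiguous
// sample blocks); returns the (B*D*H*W) x 27C patch matrix without an
// intermediate zero-fill in R.
// [[Rcpp::export]]
NumericMatrix im2col3d_batch(NumericMatrix xbig, int D, int H, int W, int B) {
  const int C = xbig.ncol();
  const int nvox = D * H * W;
  NumericMatrix P((R_xlen_t)B * nvox, 27 * C);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double *xc = &xbig((R_xlen_t)b * nvox, c);
      for (int off = 0; off < 27; ++off) {
        const int dz = off % 3 - 1;
        const int dy = (off / 3) % 3 - 1;
        const int dx = off / 9 - 1;
        double *col = &P((R_xlen_t)b * nvox, c * 27 + off);
        R_xlen_t r = 0;
        for (int w = 0; w < W; ++w) {
          const int ww = w + dx;
          for (int h = 0; h < H; ++h) {
            const int hh = h + dy;
            for (int d = 0; d < D; ++d, ++r) {
              const int dd = d + dz;
              if (dd < 0 || dd >= D || hh < 0 || hh >= H || ww < 0 || ww >= W)
                col[r] = 0.0;
              else
                col[r] = xc[dd + (R_xlen_t)D * (hh + (R_xlen_t)H * ww)];
            }
          }
        }
      }
    }
  }
  return P;
}

// Batched adjoint: scatter-add (B*nvox) x 27C patch gradients back to the
// (B*nvox) x C activation layout.
// [[Rcpp::export]]
NumericMatrix col2im3d_batch(NumericMatrix dP, int D, int H, int W, int B) {
  const int C = dP.ncol() / 27;
  const int nvox = D * H * W;
  NumericMatrix dx_((R_xlen_t)B * nvox, C);
  std::fill(dx_.begin(), dx_.end(), 0.0);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      double *gc = &dx_((R_xlen_t)b * nvox, c);
      for (int off = 0; off < 27; ++off) {
        const int dz = off % 3 - 1;
        const int dy = (off / 3) % 3 - 1;
        const int dx = off / 9 - 1;
        const double *col = &dP((R_xlen_t)b * nvox, c * 27 + off);
        R_xlen_t r = 0;
        for (int w = 0; w < W; ++w) {
          const int ww = w + dx;
          for (int h = 0; h < H; ++h) {
            const int hh = h + dy;
            for (int d = 0; d < D; ++d, ++r) {
              const int dd = d + dz;
              if (dd >= 0 && dd < D && hh >= 0 && hh < H && ww >= 0 && ww < W)
                gc[dd + (R_xlen_t)D * (hh + (R_xlen_t)H * ww)] += col[r];
            }
          }
        }
      }
    }
  }
  return dx_;
}
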