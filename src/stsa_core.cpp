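// Numerical core: per-batch forward/backward of the spatial-temporal
// self-attention network and the causal exponential-moving standardizer.
//
// The network runs in single precision (the standard precision for EEG deep
// learning) with double-precision reduction accumulators; gradients and
// log-probabilities are returned to R as doubles. The standardizer is double
// precision end to end.
//
// Parameter layout (shared with the R side, see R/model.R):
//   sw1, sb1, sw2, sb2   length-F weights/biases of the two 1x1 spatial
//                        query/key projections (input has a single map, so a
//                        1x1 conv to F maps is F scalar weights + F biases)
//   tw1, tb1, tw2, tb2   same for the temporal module
//   lam1, lam2           residual scalars (lambda1 spatial, lambda2 temporal)
//   W2 (K x 3*tk), b2    temporal conv over the 3 stacked maps {M,S,T}
//   W3 (K x K*H)         spatial conv across all H channels, no bias
//   gamma, beta (K)      batch-norm affine parameters
//   W4 (ncls x K*P), b4  full-width classifier conv (a dense layer)
//   bn_rmean, bn_rvar    running statistics, used in evaluation mode only
//
// The attention scores are computed in the collapsed form of the
// 1x1-projection dot product: with q_f = w1_f*M + b1_f and k_f = w2_f*M + b2_f,
//   score = A*G + B*u*1' + C*1*u' + D,
// where for the spatial module G = M M', u = rowsums(M), D = W*sum_f b1_f b2_f
// and for the temporal module G = M' M, u = colsums(M), D = H*sum_f b1_f b2_f,
// with A = sum_f w1_f w2_f, B = sum_f w1_f b2_f, C = sum_f b1_f w2_f.
// This is exactly the reshape+matmul formulation of the architecture tables;
// tests assert equivalence against the plain-R reference implementation.

#include <RcppArmadillo.h>
#include <random>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

struct Cfg {
  int H, W, F, K, tk, pk, ps, ncls;
  float dropout_p, bn_eps, eps_log;
  int Wc, P;
  explicit Cfg(const List& cfg) {
    H = cfg["H"]; W = cfg["W"]; F = cfg["F"]; K = cfg["K"];
    tk = cfg["tk"]; pk = cfg["pk"]; ps = cfg["ps"]; ncls = cfg["ncls"];
    dropout_p = Rcpp::as<double>(cfg["dropout_p"]);
    bn_eps = Rcpp::as<double>(cfg["bn_eps"]);
    eps_log = Rcpp::as<double>(cfg["eps_log"]);
    Wc = W - tk + 1;
    P = (Wc - pk) / ps + 1;
    if (Wc < pk) Rcpp::stop("time axis too short after temporal convolution (stage: pooling)");
  }
};

struct ParamsF {
  fvec sw1, sb1, sw2, sb2, tw1, tb1, tw2, tb2;
  float lam1, lam2;
  fmat W2; fvec b2; fmat W3; fvec gamma, beta; fmat W4; fvec b4;
  fvec bn_rmean, bn_rvar;
  explicit ParamsF(const List& p) :
    sw1(Rcpp::as<fvec>(p["sw1"])), sb1(Rcpp::as<fvec>(p["sb1"])),
    sw2(Rcpp::as<fvec>(p["sw2"])), sb2(Rcpp::as<fvec>(p["sb2"])),
    tw1(Rcpp::as<fvec>(p["tw1"])), tb1(Rcpp::as<fvec>(p["tb1"])),
    tw2(Rcpp::as<fvec>(p["tw2"])), tb2(Rcpp::as<fvec>(p["tb2"])),
    lam1(float(Rcpp::as<double>(p["lam1"]))), lam2(float(Rcpp::as<double>(p["lam2"]))),
    W2(Rcpp::as<fmat>(p["W2"])), b2(Rcpp::as<fvec>(p["b2"])),
    W3(Rcpp::as<fmat>(p["W3"])),
    gamma(Rcpp::as<fvec>(p["gamma"])), beta(Rcpp::as<fvec>(p["beta"])),
    W4(Rcpp::as<fmat>(p["W4"])), b4(Rcpp::as<fvec>(p["b4"])),
    bn_rmean(Rcpp::as<fvec>(p["bn_rmean"])), bn_rvar(Rcpp::as<fvec>(p["bn_rvar"])) {}
};

struct AttCoef { float A, B, C, D; };

static AttCoef att_coef(const fvec& w1, const fvec& b1, const fvec& w2, const fvec& b2,
                        float dfac) {
  AttCoef c;
  c.A = dot(w1, w2); c.B = dot(w1, b2); c.C = dot(b1, w2);
  c.D = dfac * dot(b1, b2);
  return c;
}

// fused scores + row softmax: P = row_softmax(A*G + B*u*1' + C*1*u' + D)
static fmat fused_softmax_map(const fmat& G, const fvec& u, const AttCoef& c) {
  const uword n = G.n_rows;
  fmat S(n, n);
  fvec rmax(n);
  rmax.fill(-std::numeric_limits<float>::infinity());
  for (uword q = 0; q < n; ++q) {
    const float cq = c.C * u(q) + c.D;
    const float* g = G.colptr(q);
    float* s = S.colptr(q);
    for (uword i = 0; i < n; ++i) {
      const float v = c.A * g[i] + c.B * u(i) + cq;
      s[i] = v;
      if (v > rmax(i)) rmax(i) = v;
    }
  }
  fvec rsum(n, fill::zeros);
  for (uword q = 0; q < n; ++q) {
    float* s = S.colptr(q);
    for (uword i = 0; i < n; ++i) {
      const float e = std::exp(s[i] - rmax(i));
      s[i] = e;
      rsum(i) += e;
    }
  }
  for (uword q = 0; q < n; ++q) {
    float* s = S.colptr(q);
    for (uword i = 0; i < n; ++i) s[i] /= rsum(i);
  }
  return S;
}

// backward through the fused scores: given the softmax output P, its upstream
// gradient dP, G and u, accumulate the gradients of the four collapsed score
// coefficients without materializing dScore:
//   dScore = P % (dP - rowsum(dP % P));  dA = sum(dScore % G);
//   dB = u' * rowsums(dScore);  dC = colsums(dScore) * u;  dD = sum(dScore)
static void fused_score_grads(const fmat& P, const fmat& dP, const fmat& G,
                              const fvec& u, double& dA, double& dB,
                              double& dC, double& dD) {
  const uword n = P.n_rows;
  vec r(n, fill::zeros);
  for (uword q = 0; q < n; ++q) {
    const float* pp = P.colptr(q);
    const float* dd = dP.colptr(q);
    for (uword i = 0; i < n; ++i) r(i) += double(pp[i]) * dd[i];
  }
  vec rs(n, fill::zeros);
  dA = dB = dC = dD = 0.0;
  for (uword q = 0; q < n; ++q) {
    const float* pp = P.colptr(q);
    const float* dd = dP.colptr(q);
    const float* g = G.colptr(q);
    double csum = 0.0;
    for (uword i = 0; i < n; ++i) {
      const double v = double(pp[i]) * (double(dd[i]) - r(i));
      dA += v * g[i];
      rs(i) += v;
      csum += v;
    }
    dC += double(u(q)) * csum;
    dD += csum;
  }
  dB = dot(conv_to<vec>::from(u), rs);
}

// im2col for the 1 x tk temporal convolution over 3 stacked H x W maps.
// Output: (H*Wc) x (3*tk); row index c*Wc + t, column index i*tk + k.
static void im2col3(const fmat& M, const fmat& S, const fmat& T, const Cfg& g, fmat& col) {
  const fmat* maps[3] = { &M, &S, &T };
  for (int i = 0; i < 3; ++i)
    for (int k = 0; k < g.tk; ++k) {
      float* dst = col.colptr(i * g.tk + k);
      for (int c = 0; c < g.H; ++c) {
        const fmat& A = *maps[i];
        for (int t = 0; t < g.Wc; ++t) dst[c * g.Wc + t] = A(c, t + k);
      }
    }
}

// adjoint of im2col3 for the S and T slices (the raw-signal slice is data,
// its gradient is never needed)
static void col2im_ST(const fmat& dcol, const Cfg& g, fmat& dS, fmat& dT) {
  dS.zeros(g.H, g.W); dT.zeros(g.H, g.W);
  fmat* maps[2] = { &dS, &dT };
  for (int i = 1; i < 3; ++i)
    for (int k = 0; k < g.tk; ++k) {
      const float* src = dcol.colptr(i * g.tk + k);
      fmat& D = *maps[i - 1];
      for (int c = 0; c < g.H; ++c)
        for (int t = 0; t < g.Wc; ++t) D(c, t + k) += src[c * g.Wc + t];
    }
}

// rearrange Y2 ((H*Wc) x K) to Yr ((K*H) x Wc) with Yr(m*H + c, t) = Y2(c*Wc + t, m)
static void to_Yr(const fmat& Y2, const Cfg& g, fmat& Yr) {
  for (int m = 0; m < g.K; ++m) {
    const float* src = Y2.colptr(m);
    for (int t = 0; t < g.Wc; ++t) {
      float* dst = Yr.colptr(t) + m * g.H;
      for (int c = 0; c < g.H; ++c) dst[c] = src[c * g.Wc + t];
    }
  }
}

static void from_Yr(const fmat& dYr, const Cfg& g, fmat& dY2) {
  for (int m = 0; m < g.K; ++m) {
    float* dst = dY2.colptr(m);
    for (int t = 0; t < g.Wc; ++t) {
      const float* src = dYr.colptr(t) + m * g.H;
      for (int c = 0; c < g.H; ++c) dst[c * g.Wc + t] = src[c];
    }
  }
}

// square -> average pool (1 x pk, stride 1 x ps)
static fmat pool_forward(const fmat& sq, const Cfg& g) {
  fmat P(g.K, g.P);
  for (int j = 0; j < g.P; ++j)
    P.col(j) = mean(sq.cols(j * g.ps, j * g.ps + g.pk - 1), 1);
  return P;
}

static fmat pool_backward(const fmat& dP, const Cfg& g) {
  fmat dsq(g.K, g.Wc, fill::zeros);
  for (int j = 0; j < g.P; ++j)
    dsq.cols(j * g.ps, j * g.ps + g.pk - 1).each_col() += dP.col(j) / float(g.pk);
  return dsq;
}

// flatten K x P row-major: f[m*P + j] = L(m, j)
static fvec flat_rowmajor(const fmat& L) { return vectorise(L.t()); }
static fmat unflat_rowmajor(const fvec& f, int K, int P) {
  return fmat(const_cast<float*>(f.memptr()), P, K, false).t();
}

// forward through both attention modules and the two convolutions (up to the
// pre-batch-norm activation Z); optionally keeps the temporal map for backward
static void trunk_forward(const fmat& M, const ParamsF& p, const Cfg& g,
                          fmat& Smat, fmat& Tmat, fmat& s3, fmat& s4, fmat& t4,
                          fmat& Yr, fmat& Z, fmat* t3keep) {
  AttCoef cs = att_coef(p.sw1, p.sb1, p.sw2, p.sb2, float(g.W));
  fvec v = sum(M, 1);
  s3 = fused_softmax_map(M * M.t(), v, cs);
  s4 = s3 * M;
  Smat = p.lam1 * s4 + M;

  AttCoef ct = att_coef(p.tw1, p.tb1, p.tw2, p.tb2, float(g.H));
  fvec u = sum(M, 0).t();
  fmat t3 = fused_softmax_map(M.t() * M, u, ct);
  t4 = M * t3.t();
  Tmat = p.lam2 * t4 + M;
  if (t3keep) *t3keep = std::move(t3);

  fmat col(g.H * g.Wc, 3 * g.tk);
  im2col3(M, Smat, Tmat, g, col);
  fmat Y2 = col * p.W2.t();
  Y2.each_row() += p.b2.t();
  Yr.set_size(g.K * g.H, g.Wc);
  to_Yr(Y2, g, Yr);
  Z = p.W3 * Yr;
}

static rowvec logsoftmax_row(const frowvec& zf) {
  rowvec z = conv_to<rowvec>::from(zf);
  z -= z.max();
  return z - std::log(accu(exp(z)));
}

// Evaluation-mode forward: running batch-norm statistics, no dropout.
// Returns n x ncls log-probabilities.
// [[Rcpp::export]]
arma::mat cpp_eval_forward(const Rcpp::List& params, const arma::cube& X,
                           const Rcpp::List& cfg) {
  Cfg g(cfg); ParamsF p(params);
  const int n = X.n_slices;
  mat logp(n, g.ncls);
  fvec sd = sqrt(p.bn_rvar + g.bn_eps);
  fmat Smat, Tmat, s3, s4, t4, Yr, Z;
  for (int i = 0; i < n; ++i) {
    fmat M = conv_to<fmat>::from(X.slice(i));
    trunk_forward(M, p, g, Smat, Tmat, s3, s4, t4, Yr, Z, nullptr);
    Z.each_col() -= p.bn_rmean;
    Z.each_col() /= sd;
    Z.each_col() %= p.gamma;
    Z.each_col() += p.beta;
    fmat pooled = pool_forward(square(Z), g);
    fmat L = log(clamp(pooled, g.eps_log, std::numeric_limits<float>::max()));
    fvec f = flat_rowmajor(L);
    fvec z = p.W4 * f + p.b4;
    logp.row(i) = logsoftmax_row(z.t());
  }
  return logp;
}

// Training-mode forward + backward over one mini-batch.
// y holds 0-based class labels. Returns the mean NLL loss, log-probabilities,
// gradients for every trainable parameter, and the batch BN statistics
// (mean + unbiased variance) for the running-statistics update in R.
// [[Rcpp::export]]
Rcpp::List cpp_train_batch(const Rcpp::List& params, const arma::cube& X,
                           const arma::ivec& y, const Rcpp::List& cfg,
                           unsigned long drop_seed) {
  Cfg g(cfg); ParamsF p(params);
  const int n = X.n_slices;
  const double Ntot = double(n) * g.Wc;

  fcube Zall(g.K, g.Wc, n), Scube(g.H, g.W, n), Tcube(g.H, g.W, n),
        s4cube(g.H, g.W, n), t4cube(g.H, g.W, n), s3cube(g.H, g.H, n),
        Mcube(g.H, g.W, n);
  std::vector<fmat> Yrs(n), t3s(n);

  for (int i = 0; i < n; ++i) {
    Mcube.slice(i) = conv_to<fmat>::from(X.slice(i));
    fmat Smat, Tmat, s3, s4, t4, Yr, Z;
    trunk_forward(Mcube.slice(i), p, g, Smat, Tmat, s3, s4, t4, Yr, Z, &t3s[i]);
    Scube.slice(i) = std::move(Smat); Tcube.slice(i) = std::move(Tmat);
    s3cube.slice(i) = std::move(s3);
    s4cube.slice(i) = std::move(s4); t4cube.slice(i) = std::move(t4);
    Yrs[i] = std::move(Yr);
    Zall.slice(i) = std::move(Z);
  }

  // batch-norm statistics per feature map over batch x time (double accumulation)
  vec muAcc(g.K, fill::zeros), varAcc(g.K, fill::zeros);
  for (int i = 0; i < n; ++i) muAcc += conv_to<vec>::from(sum(Zall.slice(i), 1));
  muAcc /= Ntot;
  fvec mu = conv_to<fvec>::from(muAcc);
  for (int i = 0; i < n; ++i) {
    fmat d = Zall.slice(i);
    d.each_col() -= mu;
    varAcc += conv_to<vec>::from(sum(square(d), 1));
  }
  varAcc /= Ntot;                    // biased, used for normalization
  fvec var = conv_to<fvec>::from(varAcc);
  fvec sd = sqrt(var + g.bn_eps);

  std::mt19937_64 rng(drop_seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const float keep = 1.0f - g.dropout_p;

  mat logp(n, g.ncls);
  fcube masks(g.K, g.P, n), Pcube(g.K, g.P, n);
  fmat fmat_all(g.K * g.P, n);
  for (int i = 0; i < n; ++i) {
    fmat Zh = Zall.slice(i);
    Zh.each_col() -= mu; Zh.each_col() /= sd;
    fmat out = Zh; out.each_col() %= p.gamma; out.each_col() += p.beta;
    fmat pooled = pool_forward(square(out), g);
    Pcube.slice(i) = pooled;
    fmat L = log(clamp(pooled, g.eps_log, std::numeric_limits<float>::max()));
    fmat mask(g.K, g.P);
    if (g.dropout_p > 0.0f) {
      for (uword uu = 0; uu < mask.n_elem; ++uu)
        mask(uu) = (unif(rng) < keep) ? 1.0f / keep : 0.0f;
    } else mask.ones();
    masks.slice(i) = mask;
    fvec f = flat_rowmajor(L % mask);
    fmat_all.col(i) = f;
    fvec z = p.W4 * f + p.b4;
    logp.row(i) = logsoftmax_row(z.t());
  }

  double loss = 0.0;
  fmat dlogits(n, g.ncls);
  for (int i = 0; i < n; ++i) {
    loss -= logp(i, y(i));
    rowvec soft = exp(logp.row(i));
    soft(y(i)) -= 1.0;
    dlogits.row(i) = conv_to<frowvec>::from(soft / n);
  }
  loss /= n;

  // ---- backward ----
  fmat dW4 = dlogits.t() * fmat_all.t();
  fvec db4 = sum(dlogits, 0).t();
  fmat dfall = p.W4.t() * dlogits.t();     // (K*P) x n

  vec dgamma(g.K, fill::zeros), dbeta(g.K, fill::zeros);
  vec Sd(g.K, fill::zeros), Sz(g.K, fill::zeros);
  fcube douts(g.K, g.Wc, n);
  for (int i = 0; i < n; ++i) {
    fmat dL = unflat_rowmajor(dfall.col(i), g.K, g.P) % masks.slice(i);
    fmat dP = dL / clamp(Pcube.slice(i), g.eps_log, std::numeric_limits<float>::max());
    dP.elem(find(Pcube.slice(i) < g.eps_log)).zeros();
    fmat dsq = pool_backward(dP, g);
    fmat Zh = Zall.slice(i);
    Zh.each_col() -= mu; Zh.each_col() /= sd;
    fmat out = Zh; out.each_col() %= p.gamma; out.each_col() += p.beta;
    fmat dout = 2.0f * (out % dsq);
    dgamma += conv_to<vec>::from(sum(dout % Zh, 1));
    dbeta += conv_to<vec>::from(sum(dout, 1));
    douts.slice(i) = std::move(dout);
  }
  Sd = dbeta; Sz = dgamma;

  fmat dW2(size(p.W2), fill::zeros); vec db2(g.K, fill::zeros);
  fmat dW3(size(p.W3), fill::zeros);
  vec dsw1(g.F, fill::zeros), dsb1(g.F, fill::zeros), dsw2(g.F, fill::zeros), dsb2(g.F, fill::zeros);
  vec dtw1(g.F, fill::zeros), dtb1(g.F, fill::zeros), dtw2(g.F, fill::zeros), dtb2(g.F, fill::zeros);
  double dlam1 = 0.0, dlam2 = 0.0;

  const fvec gam_over_sd = p.gamma / sd;
  const fvec SdN = conv_to<fvec>::from(Sd / Ntot);
  const fvec SzN = conv_to<fvec>::from(Sz / Ntot);

  fmat col(g.H * g.Wc, 3 * g.tk), dY2(g.H * g.Wc, g.K);
  for (int i = 0; i < n; ++i) {
    const fmat& M = Mcube.slice(i);
    // batch-norm backward (biased-variance formulation)
    fmat Zh = Zall.slice(i);
    Zh.each_col() -= mu; Zh.each_col() /= sd;
    fmat dZ = douts.slice(i);
    dZ.each_col() -= SdN;
    dZ -= Zh.each_col() % SzN;
    dZ.each_col() %= gam_over_sd;

    dW3 += dZ * Yrs[i].t();
    fmat dYr = p.W3.t() * dZ;
    from_Yr(dYr, g, dY2);

    im2col3(M, Scube.slice(i), Tcube.slice(i), g, col);
    dW2 += dY2.t() * col;
    db2 += conv_to<vec>::from(sum(dY2, 0).t());
    fmat dcol = dY2 * p.W2;
    fmat dS, dT;
    col2im_ST(dcol, g, dS, dT);

    // spatial attention backward
    dlam1 += double(accu(dS % s4cube.slice(i)));
    if (p.lam1 != 0.0f) {
      fmat ds4 = p.lam1 * dS;
      fmat ds3 = ds4 * M.t();
      fvec v = sum(M, 1);
      double dA, dB, dC, dD;
      fused_score_grads(s3cube.slice(i), ds3, M * M.t(), v, dA, dB, dC, dD);
      dsw1 += dA * conv_to<vec>::from(p.sw2) + dB * conv_to<vec>::from(p.sb2);
      dsb1 += dC * conv_to<vec>::from(p.sw2) + dD * g.W * conv_to<vec>::from(p.sb2);
      dsw2 += dA * conv_to<vec>::from(p.sw1) + dC * conv_to<vec>::from(p.sb1);
      dsb2 += dB * conv_to<vec>::from(p.sw1) + dD * g.W * conv_to<vec>::from(p.sb1);
    }

    // temporal attention backward
    dlam2 += double(accu(dT % t4cube.slice(i)));
    if (p.lam2 != 0.0f) {
      fmat dt4 = p.lam2 * dT;
      fmat dt3 = dt4.t() * M;                 // W x W
      fvec u = sum(M, 0).t();
      double dA, dB, dC, dD;
      fused_score_grads(t3s[i], dt3, M.t() * M, u, dA, dB, dC, dD);
      dtw1 += dA * conv_to<vec>::from(p.tw2) + dB * conv_to<vec>::from(p.tb2);
      dtb1 += dC * conv_to<vec>::from(p.tw2) + dD * g.H * conv_to<vec>::from(p.tb2);
      dtw2 += dA * conv_to<vec>::from(p.tw1) + dC * conv_to<vec>::from(p.tb1);
      dtb2 += dB * conv_to<vec>::from(p.tw1) + dD * g.H * conv_to<vec>::from(p.tb1);
    }
  }

  List grads = List::create(
    Named("sw1") = dsw1, Named("sb1") = dsb1, Named("sw2") = dsw2, Named("sb2") = dsb2,
    Named("tw1") = dtw1, Named("tb1") = dtb1, Named("tw2") = dtw2, Named("tb2") = dtb2,
    Named("lam1") = dlam1, Named("lam2") = dlam2,
    Named("W2") = conv_to<mat>::from(dW2), Named("b2") = db2,
    Named("W3") = conv_to<mat>::from(dW3),
    Named("gamma") = dgamma, Named("beta") = dbeta,
    Named("W4") = conv_to<mat>::from(dW4), Named("b4") = conv_to<vec>::from(db4));

  double ub = Ntot > 1 ? Ntot / (Ntot - 1.0) : 1.0;
  return List::create(
    Named("loss") = loss, Named("logp") = logp, Named("grads") = grads,
    Named("bn_mean") = muAcc, Named("bn_var") = varAcc * ub);
}

// Causal per-channel exponential moving standardization (double precision).
// m_1 = x_1, v_1 = 0; for t > 1:
//   m_t = decay*m_{t-1} + (1-decay)*x_t
//   v_t = decay*v_{t-1} + (1-decay)*(x_t - m_t)^2
//   out_t = (x_t - m_t) / max(sqrt(v_t), sqrt(eps_var))
// [[Rcpp::export]]
arma::mat cpp_ems(const arma::mat& x, double decay, double eps_var) {
  mat out(size(x));
  const double a = 1.0 - decay, floor_sd = std::sqrt(eps_var);
  for (uword c = 0; c < x.n_rows; ++c) {
    double m = x(c, 0), v = 0.0;
    out(c, 0) = 0.0;
    for (uword t = 1; t < x.n_cols; ++t) {
      m = decay * m + a * x(c, t);
      const double d = x(c, t) - m;
      v = decay * v + a * d * d;
      out(c, t) = d / std::max(std::sqrt(v), floor_sd);
    }
  }
  return out;
}
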