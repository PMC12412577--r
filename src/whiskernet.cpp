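// Encoder-attention-decoder sequence regression core.
//
// Layout (all parameters are plain R matrices/vectors in named lists):
//   encoder: c1w 16x7, c1b 16          1-D conv over the normalized window
//            c2w 3x3, c2b 1            single-channel 2-D conv
//            c3w 3x3, c3b 1            single-channel 2-D conv
//            lcx 120x1, lch 120x30, lcb 120   recurrent unit, CNN pathway
//            lhx 120x10, lhh 120x30, lhb 120  recurrent unit, handcrafted
//            hdw 30x30, hdb 30         dense after handcrafted recurrence
//   decoder: fw 60x60, fb 60           fusion dense producing F_t
//            kw/qw/vw 30x60, kb/qb/vb 30      key/query/value (ReLU)
//            ow 30, ob 1               many-to-one output + sigmoid
//
// Average pools are fixed 2 (channel axis) x 4 (time axis). Gate order in
// the recurrent units is [input; forget; cell; output], 30 rows each.
// Backpropagation through the 16-slot attention buffer is truncated: lagged
// feature vectors are constants, but key/query/value *parameter* gradients
// flow through every lag.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const int H = 30;       // recurrent hidden size
static const int NBUF = 16;    // attention buffer (current + 15 lags)
static const int NFEAT = 10;   // handcrafted features per sub-window
static const int NWIN = 16;    // handcrafted sub-windows per input window
static const int PR = 2, PC = 4;  // average pool extents (rows x cols)

struct EncParams {
  mat c1w; vec c1b; mat c2w; double c2b; mat c3w; double c3b;
  mat lcx, lch; vec lcb;
  mat lhx, lhh; vec lhb;
  mat hdw; vec hdb;
};
struct DecParams {
  mat fw; vec fb;
  mat kw, qw, vw; vec kb, qb, vb;
  vec ow; double ob;
};
struct NormParams {
  double raw_mean, raw_std, wamp_thr;
  vec fmean, fstd;
};

static EncParams enc_from_list(const Rcpp::List& L) {
  EncParams p;
  p.c1w = Rcpp::as<mat>(L["c1w"]); p.c1b = Rcpp::as<vec>(L["c1b"]);
  p.c2w = Rcpp::as<mat>(L["c2w"]); p.c2b = Rcpp::as<double>(L["c2b"]);
  p.c3w = Rcpp::as<mat>(L["c3w"]); p.c3b = Rcpp::as<double>(L["c3b"]);
  p.lcx = Rcpp::as<mat>(L["lcx"]); p.lch = Rcpp::as<mat>(L["lch"]);
  p.lcb = Rcpp::as<vec>(L["lcb"]);
  p.lhx = Rcpp::as<mat>(L["lhx"]); p.lhh = Rcpp::as<mat>(L["lhh"]);
  p.lhb = Rcpp::as<vec>(L["lhb"]);
  p.hdw = Rcpp::as<mat>(L["hdw"]); p.hdb = Rcpp::as<vec>(L["hdb"]);
  return p;
}
static DecParams dec_from_list(const Rcpp::List& L) {
  DecParams p;
  p.fw = Rcpp::as<mat>(L["fw"]); p.fb = Rcpp::as<vec>(L["fb"]);
  p.kw = Rcpp::as<mat>(L["kw"]); p.kb = Rcpp::as<vec>(L["kb"]);
  p.qw = Rcpp::as<mat>(L["qw"]); p.qb = Rcpp::as<vec>(L["qb"]);
  p.vw = Rcpp::as<mat>(L["vw"]); p.vb = Rcpp::as<vec>(L["vb"]);
  p.ow = Rcpp::as<vec>(L["ow"]); p.ob = Rcpp::as<double>(L["ob"]);
  return p;
}
static NormParams norm_from_list(const Rcpp::List& L) {
  NormParams n;
  n.raw_mean = Rcpp::as<double>(L["raw_mean"]);
  n.raw_std = Rcpp::as<double>(L["raw_std"]);
  n.wamp_thr = Rcpp::as<double>(L["wamp_thr"]);
  n.fmean = Rcpp::as<vec>(L["feature_means"]);
  n.fstd = Rcpp::as<vec>(L["feature_stds"]);
  return n;
}

// ---------- handcrafted features ------------------------------------------

// 10 features of one sub-window (raw microvolt samples)
static void subwindow_features(const double* x, int m, double wamp_thr,
                               double* out) {
  double sa = 0, ss = 0, sm = 0;
  for (int i = 0; i < m; ++i) {
    sa += std::fabs(x[i]); ss += x[i] * x[i]; sm += x[i];
  }
  double mu = sm / m;
  double var = ss / m - mu * mu; if (var < 0) var = 0;
  double aac = 0, wl = 0; int zc = 0, ssc = 0, wamp = 0;
  for (int i = 0; i + 1 < m; ++i) {
    double d = x[i + 1] - x[i];
    wl += std::fabs(d);
    if (std::fabs(d) > wamp_thr) ++wamp;
    if (x[i] * x[i + 1] < 0) ++zc;
  }
  aac = (m > 1) ? wl / (m - 1) : 0.0;
  for (int i = 1; i + 1 < m; ++i)
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > 0) ++ssc;
  out[0] = sa / m;            // MAV
  out[1] = ss;                // SSI
  out[2] = aac;               // AAC
  out[3] = std::sqrt(var);    // STD
  out[4] = std::sqrt(ss / m); // RMS
  out[5] = wl;                // waveform length
  out[6] = zc;                // zero crossings
  out[7] = ssc;               // slope sign changes
  out[8] = wamp;              // Willison amplitude
  out[9] = var;               // variance
}

// features of a full n_pad window: NFEAT x NWIN, raw (not normalized)
static mat window_features_raw(const double* xw, int n_pad, double wamp_thr) {
  int m = n_pad / NWIN;
  mat F(NFEAT, NWIN);
  for (int wdx = 0; wdx < NWIN; ++wdx)
    subwindow_features(xw + wdx * m, m, wamp_thr, F.colptr(wdx));
  return F;
}

// [[Rcpp::export]]
arma::mat wn_window_features(const arma::vec& xw, double wamp_thr) {
  if ((int)xw.n_elem % NWIN != 0)
    Rcpp::stop("window length must be a multiple of 16");
  return window_features_raw(xw.memptr(), xw.n_elem, wamp_thr);
}

// mean/sd of handcrafted features across all sub-windows of all windows
// [[Rcpp::export]]
Rcpp::List wn_feature_stats(const arma::vec& x, const arma::ivec& starts,
                            int n_pad, double wamp_thr) {
  vec s1(NFEAT, fill::zeros), s2(NFEAT, fill::zeros);
  long long cnt = 0;
  for (uword t = 0; t < starts.n_elem; ++t) {
    int s0 = starts[t] - 1;
    if (s0 < 0 || s0 + n_pad > (int)x.n_elem) Rcpp::stop("window out of range");
    mat F = window_features_raw(x.memptr() + s0, n_pad, wamp_thr);
    s1 += sum(F, 1);
    s2 += sum(square(F), 1);
    cnt += NWIN;
  }
  vec mu = s1 / cnt;
  vec var = s2 / cnt - square(mu);
  var.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  return Rcpp::List::create(Rcpp::Named("mean") = mu,
                            Rcpp::Named("sd") = sqrt(var));
}

// ---------- recurrent unit -------------------------------------------------

struct LstmCache {
  mat G;   // 4H x T activated gates [i; f; g; o]
  mat C;   // H x T cell states
  mat Hm;  // H x T hidden states
};

static vec lstm_forward(const mat& X, const mat& Wx, const mat& Wh,
                        const vec& b, LstmCache* cache) {
  int T = X.n_cols;
  vec h(H, fill::zeros), c(H, fill::zeros);
  mat ZX = Wx * X;                 // 4H x T input projections
  if (cache) { cache->G.set_size(4 * H, T); cache->C.set_size(H, T);
               cache->Hm.set_size(H, T); }
  for (int t = 0; t < T; ++t) {
    vec z = ZX.col(t) + Wh * h + b;
    vec gi = 1.0 / (1.0 + exp(-z.subvec(0, H - 1)));
    vec gf = 1.0 / (1.0 + exp(-z.subvec(H, 2 * H - 1)));
    vec gg = tanh(z.subvec(2 * H, 3 * H - 1));
    vec go = 1.0 / (1.0 + exp(-z.subvec(3 * H, 4 * H - 1)));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    if (cache) {
      cache->G.col(t) = join_cols(join_cols(gi, gf), join_cols(gg, go));
      cache->C.col(t) = c;
      cache->Hm.col(t) = h;
    }
  }
  return h;
}

// backward from a gradient on the final hidden state; returns dX if wanted
static void lstm_backward(const mat& X, const mat& Wx, const mat& Wh,
                          const LstmCache& cache, const vec& dh_last,
                          mat& gWx, mat& gWh, vec& gb, mat* dX) {
  int T = X.n_cols;
  vec dh = dh_last, dc(H, fill::zeros);
  if (dX) dX->zeros(X.n_rows, T);
  for (int t = T - 1; t >= 0; --t) {
    vec gi = cache.G.col(t).subvec(0, H - 1);
    vec gf = cache.G.col(t).subvec(H, 2 * H - 1);
    vec gg = cache.G.col(t).subvec(2 * H, 3 * H - 1);
    vec go = cache.G.col(t).subvec(3 * H, 4 * H - 1);
    vec c = cache.C.col(t);
    vec c_prev = (t > 0) ? vec(cache.C.col(t - 1)) : vec(H, fill::zeros);
    vec h_prev = (t > 0) ? vec(cache.Hm.col(t - 1)) : vec(H, fill::zeros);
    vec tc = tanh(c);
    vec dgo = dh % tc;
    vec dct = dh % go % (1.0 - square(tc)) + dc;
    vec dgi = dct % gg;
    vec dgf = dct % c_prev;
    vec dgg = dct % gi;
    vec dz = join_cols(join_cols(dgi % gi % (1.0 - gi),
                                 dgf % gf % (1.0 - gf)),
                       join_cols(dgg % (1.0 - square(gg)),
                                 dgo % go % (1.0 - go)));
    gWx += dz * X.col(t).t();
    gWh += dz * h_prev.t();
    gb += dz;
    if (dX) dX->col(t) = Wx.t() * dz;
    dh = Wh.t() * dz;
    dc = dct % gf;
  }
}

// ---------- encoder --------------------------------------------------------

struct EncDims {
  int n_pad, C1, K1, L1, R1, T1, R2, T2, R3, T3, T4;
};
static EncDims enc_dims(const EncParams& p, int n_pad) {
  EncDims d;
  d.n_pad = n_pad;
  d.C1 = p.c1w.n_rows; d.K1 = p.c1w.n_cols;
  d.L1 = n_pad - d.K1 + 1;
  d.R1 = d.C1 / PR; d.T1 = d.L1 / PC;
  d.R2 = d.R1 - 2; d.T2 = d.T1 - 2;
  d.R3 = d.R2 / PR; d.T3 = d.T2 / PC;
  d.T4 = d.T3 - 2;
  if (d.R3 - 2 != 1) Rcpp::stop("conv stack does not reduce to one row");
  return d;
}

struct EncCache {
  mat feats;      // NFEAT x NWIN (normalized)
  LstmCache lh;   // handcrafted recurrence
  vec h16;
  mat a1, p1, a2, p2;  // pre-ReLU conv outs and pooled maps
  rowvec a3;           // pre-ReLU final conv out (1 x T4)
  mat xseq;            // 1 x T4 recurrent input (post-ReLU)
  LstmCache lc;
  mat X1;              // im2col of the normalized window (K1 x L1)
};

// 2-row x 4-col average pool, direct indexing
static void avgpool24(const mat& A, int R_out, int T_out, mat& P) {
  P.set_size(R_out, T_out);
  for (int c = 0; c < T_out; ++c) {
    int c0 = c * PC;
    for (int r = 0; r < R_out; ++r) {
      int r0 = r * PR;
      double s = 0;
      for (int dc = 0; dc < PC; ++dc)
        s += A(r0, c0 + dc) + A(r0 + 1, c0 + dc);
      P(r, c) = s / (PR * PC);
    }
  }
}

// valid 3x3 single-channel convolution
static void conv33(const mat& X, const mat& W, double b, mat& A) {
  int R = X.n_rows - 2, T = X.n_cols - 2;
  A.set_size(R, T);
  for (int c = 0; c < T; ++c)
    for (int r = 0; r < R; ++r) {
      double s = b;
      for (int v = 0; v < 3; ++v)
        for (int u = 0; u < 3; ++u)
          s += W(u, v) * X(r + u, c + v);
      A(r, c) = s;
    }
}

// forward one window; lat is 60 (handcrafted 0..29, CNN 30..59)
static void enc_window_forward(const double* xraw, const EncParams& p,
                               const NormParams& nm, const EncDims& d,
                               vec& lat, EncCache* cc) {
  // handcrafted pathway
  mat F = window_features_raw(xraw, d.n_pad, nm.wamp_thr);
  F.each_col() -= nm.fmean;
  F.each_col() /= nm.fstd;
  LstmCache lhc;
  vec h16 = lstm_forward(F, p.lhx, p.lhh, p.lhb, cc ? &lhc : nullptr);
  vec lat_h = p.hdw * h16 + p.hdb;
  // CNN pathway: im2col then one GEMM for the 1-D convolution
  mat X1(d.K1, d.L1);
  double inv_sd = 1.0 / nm.raw_std;
  for (int j = 0; j < d.L1; ++j)
    for (int k = 0; k < d.K1; ++k)
      X1(k, j) = (xraw[j + k] - nm.raw_mean) * inv_sd;
  mat a1 = p.c1w * X1;
  a1.each_col() += p.c1b;
  mat r1 = clamp(a1, 0.0, datum::inf);
  mat p1, a2, p2;
  avgpool24(r1, d.R1, d.T1, p1);
  conv33(p1, p.c2w, p.c2b, a2);
  mat r2 = clamp(a2, 0.0, datum::inf);
  avgpool24(r2, d.R3, d.T3, p2);
  rowvec a3(d.T4);
  for (int c = 0; c < d.T4; ++c) {
    double s = p.c3b;
    for (int v = 0; v < 3; ++v)
      for (int u = 0; u < 3; ++u)
        s += p.c3w(u, v) * p2(u, c + v);
    a3[c] = s;
  }
  mat xseq = clamp(mat(a3), 0.0, datum::inf);  // 1 x T4
  LstmCache lcc;
  vec lat_c = lstm_forward(xseq, p.lcx, p.lch, p.lcb, cc ? &lcc : nullptr);
  lat.set_size(2 * H);
  lat.subvec(0, H - 1) = lat_h;
  lat.subvec(H, 2 * H - 1) = lat_c;
  if (cc) {
    cc->feats = F; cc->lh = lhc; cc->h16 = h16;
    cc->a1 = a1; cc->p1 = p1; cc->a2 = a2; cc->p2 = p2; cc->a3 = a3;
    cc->xseq = xseq; cc->lc = lcc; cc->X1 = X1;
  }
}

struct EncGrads {
  mat c1w; vec c1b; mat c2w; double c2b; mat c3w; double c3b;
  mat lcx, lch; vec lcb; mat lhx, lhh; vec lhb; mat hdw; vec hdb;
  void init(const EncParams& p) {
    c1w.zeros(size(p.c1w)); c1b.zeros(size(p.c1b));
    c2w.zeros(size(p.c2w)); c2b = 0;
    c3w.zeros(size(p.c3w)); c3b = 0;
    lcx.zeros(size(p.lcx)); lch.zeros(size(p.lch)); lcb.zeros(size(p.lcb));
    lhx.zeros(size(p.lhx)); lhh.zeros(size(p.lhh)); lhb.zeros(size(p.lhb));
    hdw.zeros(size(p.hdw)); hdb.zeros(size(p.hdb));
  }
};

static void enc_window_backward(const EncParams& p, const EncDims& d,
                                const EncCache& cc, const vec& dlat,
                                EncGrads& g) {
  // handcrafted pathway
  vec dlat_h = dlat.subvec(0, H - 1);
  g.hdw += dlat_h * cc.h16.t();
  g.hdb += dlat_h;
  vec dh16 = p.hdw.t() * dlat_h;
  lstm_backward(cc.feats, p.lhx, p.lhh, cc.lh, dh16,
                g.lhx, g.lhh, g.lhb, nullptr);
  // CNN pathway
  vec dlat_c = dlat.subvec(H, 2 * H - 1);
  mat dxseq;
  lstm_backward(cc.xseq, p.lcx, p.lch, cc.lc, dlat_c,
                g.lcx, g.lch, g.lcb, &dxseq);
  rowvec da3 = conv_to<rowvec>::from(dxseq.row(0));
  for (int c = 0; c < d.T4; ++c) if (cc.a3[c] <= 0) da3[c] = 0;
  mat dp2(d.R3, d.T3, fill::zeros);
  for (int c = 0; c < d.T4; ++c) {
    g.c3w += da3[c] * cc.p2.submat(0, c, 2, c + 2);
    g.c3b += da3[c];
    dp2.submat(0, c, 2, c + 2) += da3[c] * p.c3w;
  }
  mat da2(d.R2, d.T2, fill::zeros);
  for (int r = 0; r < d.R3; ++r)
    for (int c = 0; c < d.T3; ++c) {
      double v = dp2(r, c) / (PR * PC);
      for (int dc = 0; dc < PC; ++dc) {
        int cc2 = c * PC + dc;
        if (cc.a2(r * PR, cc2) > 0) da2(r * PR, cc2) += v;
        if (cc.a2(r * PR + 1, cc2) > 0) da2(r * PR + 1, cc2) += v;
      }
    }
  mat dp1(d.R1, d.T1, fill::zeros);
  for (int c = 0; c < d.T2; ++c)
    for (int r = 0; r < d.R2; ++r) {
      double v = da2(r, c);
      if (v == 0) continue;
      g.c2b += v;
      for (int vv = 0; vv < 3; ++vv)
        for (int u = 0; u < 3; ++u) {
          g.c2w(u, vv) += v * cc.p1(r + u, c + vv);
          dp1(r + u, c + vv) += v * p.c2w(u, vv);
        }
    }
  mat da1(d.C1, d.L1, fill::zeros);
  for (int r = 0; r < d.R1; ++r)
    for (int c = 0; c < d.T1; ++c) {
      double v = dp1(r, c) / (PR * PC);
      if (v == 0) continue;
      for (int dc = 0; dc < PC; ++dc) {
        int cc1 = c * PC + dc;
        if (cc.a1(r * PR, cc1) > 0) da1(r * PR, cc1) += v;
        if (cc.a1(r * PR + 1, cc1) > 0) da1(r * PR + 1, cc1) += v;
      }
    }
  g.c1w += da1 * cc.X1.t();
  g.c1b += sum(da1, 1);
}

// [[Rcpp::export]]
arma::mat wn_encoder_forward(const arma::vec& x, const arma::ivec& starts,
                             int n_pad, const Rcpp::List& norm,
                             const Rcpp::List& enc) {
  EncParams p = enc_from_list(enc);
  NormParams nm = norm_from_list(norm);
  EncDims d = enc_dims(p, n_pad);
  int T = starts.n_elem;
  mat lat(2 * H, T);
  vec l;
  for (int t = 0; t < T; ++t) {
    int s0 = starts[t] - 1;
    if (s0 < 0 || s0 + n_pad > (int)x.n_elem) Rcpp::stop("window out of range");
    enc_window_forward(x.memptr() + s0, p, nm, d, l, nullptr);
    lat.col(t) = l;
  }
  return lat;
}

// ---------- decoder --------------------------------------------------------

struct DecCache {
  mat F;          // 60 x T
  mat K, Q, V;    // 30 x T (per-step transforms of F_t)
  vec e;          // T salience scalars k_t' q_t / 4
  mat S;          // NBUF x T attention scores
  mat O;          // 30 x T context vectors
  vec y;          // T outputs
};

static void decoder_run(const mat& lat, const DecParams& p, DecCache& cc) {
  int T = lat.n_cols;
  cc.F.set_size(2 * H, T); cc.K.set_size(H, T); cc.Q.set_size(H, T);
  cc.V.set_size(H, T); cc.e.set_size(T); cc.S.set_size(NBUF, T);
  cc.O.set_size(H, T); cc.y.set_size(T);
  vec kpad = clamp(p.kb, 0.0, datum::inf);
  vec qpad = clamp(p.qb, 0.0, datum::inf);
  vec vpad = clamp(p.vb, 0.0, datum::inf);
  double epad = dot(kpad, qpad) / 4.0;
  for (int t = 0; t < T; ++t) {
    vec F = p.fw * lat.col(t) + p.fb;
    cc.F.col(t) = F;
    cc.K.col(t) = clamp(p.kw * F + p.kb, 0.0, datum::inf);
    cc.Q.col(t) = clamp(p.qw * F + p.qb, 0.0, datum::inf);
    cc.V.col(t) = clamp(p.vw * F + p.vb, 0.0, datum::inf);
    cc.e[t] = dot(cc.K.col(t), cc.Q.col(t)) / 4.0;
    vec logits(NBUF);
    for (int i = 0; i < NBUF; ++i) {
      int s = t - i;
      logits[i] = (s >= 0) ? cc.e[s] : epad;
    }
    logits -= logits.max();
    vec sft = exp(logits);
    sft /= accu(sft);
    cc.S.col(t) = sft;
    vec O(H, fill::zeros);
    for (int i = 0; i < NBUF; ++i) {
      int s = t - i;
      O += sft[i] * ((s >= 0) ? vec(cc.V.col(s)) : vpad);
    }
    cc.O.col(t) = O;
    double z = dot(p.ow, O) + p.ob;
    cc.y[t] = 1.0 / (1.0 + std::exp(-z));
  }
}

struct DecGrads {
  mat fw; vec fb; mat kw, qw, vw; vec kb, qb, vb; vec ow; double ob;
  void init(const DecParams& p) {
    fw.zeros(size(p.fw)); fb.zeros(size(p.fb));
    kw.zeros(size(p.kw)); qw.zeros(size(p.qw)); vw.zeros(size(p.vw));
    kb.zeros(size(p.kb)); qb.zeros(size(p.qb)); vb.zeros(size(p.vb));
    ow.zeros(size(p.ow)); ob = 0;
  }
};

// dy: dLoss/dy per step. Fills dec grads and (optionally) dlat.
static void decoder_backward(const mat& lat, const DecParams& p,
                             const DecCache& cc, const vec& dy,
                             DecGrads& g, mat* dlat) {
  int T = lat.n_cols;
  vec vpad = clamp(p.vb, 0.0, datum::inf);
  mat dV_acc(H, T, fill::zeros), dV_lag0(H, T, fill::zeros);
  vec de_acc(T, fill::zeros), de_lag0(T, fill::zeros);
  for (int t = 0; t < T; ++t) {
    double yv = cc.y[t];
    double dz = dy[t] * yv * (1.0 - yv);
    if (dz == 0) continue;
    g.ow += dz * cc.O.col(t);
    g.ob += dz;
    vec dO = dz * p.ow;
    vec ds(NBUF);
    for (int i = 0; i < NBUF; ++i) {
      int s = t - i;
      ds[i] = dot(dO, (s >= 0) ? vec(cc.V.col(s)) : vpad);
    }
    vec sft = cc.S.col(t);
    vec dlog = sft % (ds - dot(sft, ds));
    for (int i = 0; i < NBUF; ++i) {
      int s = t - i;
      if (s < 0) continue;   // zero-padded slots carry no gradient
      de_acc[s] += dlog[i];
      dV_acc.col(s) += sft[i] * dO;
      if (i == 0) { de_lag0[t] += dlog[0]; dV_lag0.col(t) += sft[0] * dO; }
    }
  }
  if (dlat) dlat->zeros(2 * H, T);
  for (int s = 0; s < T; ++s) {
    vec F = cc.F.col(s);
    vec k = cc.K.col(s), q = cc.Q.col(s), v = cc.V.col(s);
    // value path
    vec dv = dV_acc.col(s); dv.elem(find(v <= 0)).zeros();
    g.vw += dv * F.t(); g.vb += dv;
    // salience path e_s = k'q/4
    vec dk = (de_acc[s] / 4.0) * q; dk.elem(find(k <= 0)).zeros();
    vec dq = (de_acc[s] / 4.0) * k; dq.elem(find(q <= 0)).zeros();
    g.kw += dk * F.t(); g.kb += dk;
    g.qw += dq * F.t(); g.qb += dq;
    if (dlat) {
      // only the current-step (lag-0) usage propagates into F_s
      vec dv0 = dV_lag0.col(s); dv0.elem(find(v <= 0)).zeros();
      vec dk0 = (de_lag0[s] / 4.0) * q; dk0.elem(find(k <= 0)).zeros();
      vec dq0 = (de_lag0[s] / 4.0) * k; dq0.elem(find(q <= 0)).zeros();
      vec dF = p.vw.t() * dv0 + p.kw.t() * dk0 + p.qw.t() * dq0;
      g.fw += dF * lat.col(s).t();
      g.fb += dF;
      dlat->col(s) = p.fw.t() * dF;
    }
  }
  if (!dlat) {
    // still need fusion grads when encoder grads are not required
    for (int s = 0; s < T; ++s) {
      vec k = cc.K.col(s), q = cc.Q.col(s), v = cc.V.col(s);
      vec dv0 = dV_lag0.col(s); dv0.elem(find(v <= 0)).zeros();
      vec dk0 = (de_lag0[s] / 4.0) * q; dk0.elem(find(k <= 0)).zeros();
      vec dq0 = (de_lag0[s] / 4.0) * k; dq0.elem(find(q <= 0)).zeros();
      vec dF = p.vw.t() * dv0 + p.kw.t() * dk0 + p.qw.t() * dq0;
      g.fw += dF * lat.col(s).t();
      g.fb += dF;
    }
  }
}

// [[Rcpp::export]]
arma::vec wn_decoder_forward(const arma::mat& lat, const Rcpp::List& dec) {
  DecParams p = dec_from_list(dec);
  DecCache cc;
  decoder_run(lat, p, cc);
  return cc.y;
}

// ---------- concordance loss ----------------------------------------------

static double ccc_loss_grad(const vec& y, const vec& yh, vec& grad) {
  int n = y.n_elem;
  double muy = mean(y), muh = mean(yh);
  double vy = accu(square(y - muy)) / n;
  double vh = accu(square(yh - muh)) / n;
  double cv = dot(y - muy, yh - muh) / n;
  double dmu = muy - muh;
  double D = vy + vh + dmu * dmu + 1e-12;  // epsilon-guarded denominator
  double rho_c = 2.0 * cv / D;
  grad.set_size(n);
  for (int k = 0; k < n; ++k) {
    double drc = 2.0 * (y[k] - muy) / (n * D)
      - (2.0 * cv / (D * D)) * (2.0 * (yh[k] - muh) / n - 2.0 * dmu / n);
    grad[k] = -drc;  // loss = 1 - rho_c
  }
  return 1.0 - rho_c;
}

// [[Rcpp::export]]
Rcpp::List wn_ccc_loss_grad(const arma::vec& y, const arma::vec& yhat) {
  vec g;
  double L = ccc_loss_grad(y, yhat, g);
  return Rcpp::List::create(Rcpp::Named("loss") = L, Rcpp::Named("grad") = g);
}

// ---------- training-sequence gradients ------------------------------------

static Rcpp::List enc_grads_to_list(const EncGrads& g) {
  return Rcpp::List::create(
    Rcpp::Named("c1w") = g.c1w, Rcpp::Named("c1b") = g.c1b,
    Rcpp::Named("c2w") = g.c2w, Rcpp::Named("c2b") = g.c2b,
    Rcpp::Named("c3w") = g.c3w, Rcpp::Named("c3b") = g.c3b,
    Rcpp::Named("lcx") = g.lcx, Rcpp::Named("lch") = g.lch,
    Rcpp::Named("lcb") = g.lcb,
    Rcpp::Named("lhx") = g.lhx, Rcpp::Named("lhh") = g.lhh,
    Rcpp::Named("lhb") = g.lhb,
    Rcpp::Named("hdw") = g.hdw, Rcpp::Named("hdb") = g.hdb);
}
static Rcpp::List dec_grads_to_list(const DecGrads& g) {
  return Rcpp::List::create(
    Rcpp::Named("fw") = g.fw, Rcpp::Named("fb") = g.fb,
    Rcpp::Named("kw") = g.kw, Rcpp::Named("kb") = g.kb,
    Rcpp::Named("qw") = g.qw, Rcpp::Named("qb") = g.qb,
    Rcpp::Named("vw") = g.vw, Rcpp::Named("vb") = g.vb,
    Rcpp::Named("ow") = g.ow, Rcpp::Named("ob") = g.ob);
}

// [[Rcpp::export]]
Rcpp::List wn_seq_grad(const arma::vec& x, const arma::ivec& starts,
                       int n_pad, const Rcpp::List& norm,
                       const Rcpp::List& enc, const Rcpp::List& dec,
                       const arma::vec& y_target, bool grad_encoder) {
  EncParams ep = enc_from_list(enc);
  DecParams dp = dec_from_list(dec);
  NormParams nm = norm_from_list(norm);
  EncDims d = enc_dims(ep, n_pad);
  int T = starts.n_elem;
  if ((int)y_target.n_elem != T) Rcpp::stop("target length mismatch");
  mat lat(2 * H, T);
  vec l;
  for (int t = 0; t < T; ++t) {
    int s0 = starts[t] - 1;
    if (s0 < 0 || s0 + n_pad > (int)x.n_elem) Rcpp::stop("window out of range");
    enc_window_forward(x.memptr() + s0, ep, nm, d, l, nullptr);
    lat.col(t) = l;
  }
  DecCache cc;
  decoder_run(lat, dp, cc);
  vec dy;
  double loss = ccc_loss_grad(y_target, cc.y, dy);
  DecGrads gd; gd.init(dp);
  mat dlat;
  decoder_backward(lat, dp, cc, dy, gd, grad_encoder ? &dlat : nullptr);
  EncGrads ge; ge.init(ep);
  if (grad_encoder) {
    EncCache ec;
    for (int t = 0; t < T; ++t) {
      vec dl = dlat.col(t);
      if (dot(dl, dl) == 0) continue;
      int s0 = starts[t] - 1;
      enc_window_forward(x.memptr() + s0, ep, nm, d, l, &ec);
      enc_window_backward(ep, d, ec, dl, ge);
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("yhat") = cc.y,
    Rcpp::Named("genc") = enc_grads_to_list(ge),
    Rcpp::Named("gdec") = dec_grads_to_list(gd));
}

// Single-window encoder gradient of the linear objective dot(dlat, lat):
// finite-difference validation hook for the conv/pool/recurrent backward.
// [[Rcpp::export]]
Rcpp::List wn_test_encoder_grad(const arma::vec& xw, const Rcpp::List& norm,
                                const Rcpp::List& enc, const arma::vec& dlat) {
  EncParams ep = enc_from_list(enc);
  NormParams nm = norm_from_list(norm);
  EncDims d = enc_dims(ep, xw.n_elem);
  vec lat;
  EncCache cc;
  enc_window_forward(xw.memptr(), ep, nm, d, lat, &cc);
  EncGrads g; g.init(ep);
  enc_window_backward(ep, d, cc, dlat, g);
  return Rcpp::List::create(Rcpp::Named("lat") = lat,
                            Rcpp::Named("genc") = enc_grads_to_list(g));
}

// Single-step decoder gradient of the raw output y_0 (dy = 1): used by the
// finite-difference validation tests, where the one-step case makes the
// buffer-truncated backward exact.
// [[Rcpp::export]]
Rcpp::List wn_test_step_grad(const arma::mat& lat, const Rcpp::List& dec) {
  DecParams dp = dec_from_list(dec);
  if (lat.n_cols != 1) Rcpp::stop("single-step test expects one latent column");
  DecCache cc;
  decoder_run(lat, dp, cc);
  vec dy(1);
  dy[0] = 1.0;  // gradient of the objective J = y_0
  DecGrads gd; gd.init(dp);
  mat dlat;
  decoder_backward(lat, dp, cc, dy, gd, &dlat);
  return Rcpp::List::create(
    Rcpp::Named("y") = cc.y[0],
    Rcpp::Named("gdec") = dec_grads_to_list(gd),
    Rcpp::Named("dlat") = dlat);
}

// [[Rcpp::export]]
Rcpp::List wn_decoder_seq_grad(const arma::mat& lat, const Rcpp::List& dec,
                               const arma::vec& y_target) {
  DecParams dp = dec_from_list(dec);
  int T = lat.n_cols;
  if ((int)y_target.n_elem != T) Rcpp::stop("target length mismatch");
  DecCache cc;
  decoder_run(lat, dp, cc);
  vec dy;
  double loss = ccc_loss_grad(y_target, cc.y, dy);
  DecGrads gd; gd.init(dp);
  decoder_backward(lat, dp, cc, dy, gd, nullptr);
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("yhat") = cc.y,
    Rcpp::Named("gdec") = dec_grads_to_list(gd));
}
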