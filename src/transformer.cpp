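// Two-layer transcriptional-infidelity classifier: transformer encoder with
// ALiBi positional biases, a CLS sequence-level head, and a mean/max
// token-merging subregion head. Forward, analytic backward and AdamW live
// here; the R layer owns configuration, tokenization and datasets.
//
// Parameter list layout (positional, produced by initTTIRI() in R):
//   [0] Emb (V x d)
//   per layer l (16 entries starting at 1 + 16*l):
//     Wq, bq, Wk, bk, Wv, bv, Wo, bo, g1, be1, W1, b1, W2, b2, g2, be2
//   tail: Wc (2d x d), w_seq (d x 1), b_seq (1 x 1), w_sub (d x 1), b_sub (1 x 1)

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

static const double PCLAMP = 1e-7;

struct Cfg {
  int d, nl, h, dk, n_t, m, n_sub, vocab;
  bool alibi;
  double ln_eps;
};

static Cfg read_cfg(const List& cfgL) {
  Cfg c;
  c.d = as<int>(cfgL["d"]);
  c.nl = as<int>(cfgL["n_layers"]);
  c.h = as<int>(cfgL["h"]);
  c.n_t = as<int>(cfgL["n_t"]);
  c.m = as<int>(cfgL["m"]);
  c.vocab = as<int>(cfgL["vocab_total"]);
  c.alibi = as<bool>(cfgL["alibi"]);
  c.ln_eps = cfgL.containsElementNamed("ln_eps") ? as<double>(cfgL["ln_eps"]) : 1e-5;
  if (c.d % c.h != 0) stop("hidden size not divisible by head count");
  c.dk = c.d / c.h;
  if (c.m < 1 || c.m > c.n_t - 1) stop("pooling window m out of range");
  c.n_sub = (c.n_t - 1 + c.m - 1) / c.m;
  return c;
}

static std::vector<mat> read_params(const List& pl) {
  std::vector<mat> P(pl.size());
  for (int i = 0; i < pl.size(); ++i) P[i] = as<mat>(pl[i]);
  return P;
}

static inline int lbase(int l) { return 1 + 16 * l; }
static inline double sigm(double z) { return 1.0 / (1.0 + std::exp(-z)); }
static inline double clampp(double p) {
  return std::min(1.0 - PCLAMP, std::max(PCLAMP, p));
}
// sigmoid-weighted GELU approximation: x * sigmoid(1.702 x). The forward
// stores the sigmoid so the backward needs no further transcendentals.
static const double GELU_A = 1.702;

static mat alibi_bias(int n_t, int h_i_slope_n, int head) {
  // slope_i = 2^(-8 i / h), i = 1..h; symmetric (non-causal) distance penalty
  double slope = std::pow(2.0, -8.0 * (head + 1) / h_i_slope_n);
  mat B(n_t, n_t);
  for (int q = 0; q < n_t; ++q)
    for (int k = 0; k < n_t; ++k) B(q, k) = -slope * std::abs(q - k);
  return B;
}

struct LayerCache {
  mat Xin, Q, K, V, ctx, attn, res1, xhat1, y1, Hpre, Hsig, Hact, f, res2, xhat2;
  vec istd1, istd2;
  cube P;        // n_t x n_t x (B*h)
  mat dm1, dm2;  // dropout masks (empty when unused)
};

struct Cache {
  std::vector<LayerCache> lay;
  mat Y;             // final hidden states, (B*n_t) x d
  mat Mrow, Mm;      // (B*n_sub) x 2d, (B*n_sub) x d
  vec zseq;          // B
  mat zsub;          // B x n_sub
};

static void layernorm_fwd(const mat& X, const vec& g, const vec& b, double eps,
                          mat& xhat, vec& istd, mat& Y) {
  const int n = X.n_rows, d = X.n_cols;
  xhat.set_size(n, d);
  Y.set_size(n, d);
  istd.set_size(n);
  for (int r = 0; r < n; ++r) {
    double mu = arma::mean(X.row(r));
    double va = 0.0;
    for (int c = 0; c < d; ++c) { double t = X(r, c) - mu; va += t * t; }
    va /= d;
    double is = 1.0 / std::sqrt(va + eps);
    istd(r) = is;
    for (int c = 0; c < d; ++c) {
      double xh = (X(r, c) - mu) * is;
      xhat(r, c) = xh;
      Y(r, c) = xh * g(c) + b(c);
    }
  }
}

// dY -> dX; accumulates gamma/beta grads
static mat layernorm_bwd(const mat& dY, const mat& xhat, const vec& istd,
                         const vec& g, mat& g_g, mat& g_b) {
  const int n = dY.n_rows, d = dY.n_cols;
  mat dX(n, d);
  for (int r = 0; r < n; ++r) {
    double s1 = 0.0, s2 = 0.0;
    for (int c = 0; c < d; ++c) {
      double dxh = dY(r, c) * g(c);
      s1 += dxh;
      s2 += dxh * xhat(r, c);
    }
    s1 /= d; s2 /= d;
    for (int c = 0; c < d; ++c) {
      double dxh = dY(r, c) * g(c);
      dX(r, c) = istd(r) * (dxh - s1 - xhat(r, c) * s2);
      g_g(c, 0) += dY(r, c) * xhat(r, c);
      g_b(c, 0) += dY(r, c);
    }
  }
  return dX;
}

static void forward_batch(const std::vector<mat>& P, const Cfg& cfg,
                          const IntegerMatrix& ids, const IntegerMatrix& msk,
                          const std::vector<int>& rows, Cache& C, vec& pseq,
                          mat& psub, bool training, double dropout,
                          std::mt19937_64* rng,
                          const std::vector<mat>& AB) {
  const int B = rows.size(), d = cfg.d, n_t = cfg.n_t, h = cfg.h, dk = cfg.dk;
  const double isdk = 1.0 / std::sqrt((double)dk);
  C.lay.resize(cfg.nl);

  mat X(B * n_t, d);
  const mat& Emb = P[0];
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < n_t; ++t)
      X.row(b * n_t + t) = Emb.row(ids(rows[b], t));

  std::uniform_real_distribution<double> unif(0.0, 1.0);
  bool drop = training && dropout > 0.0 && rng != nullptr;
  double keep = 1.0 - dropout;

  for (int l = 0; l < cfg.nl; ++l) {
    LayerCache& L = C.lay[l];
    int pb = lbase(l);
    const mat &Wq = P[pb], &Wk = P[pb + 2], &Wv = P[pb + 4], &Wo = P[pb + 6];
    const mat &bq = P[pb + 1], &bk = P[pb + 3], &bv = P[pb + 5], &bo = P[pb + 7];
    const mat &g1 = P[pb + 8], &be1 = P[pb + 9];
    const mat &W1 = P[pb + 10], &b1 = P[pb + 11], &W2 = P[pb + 12], &b2 = P[pb + 13];
    const mat &g2 = P[pb + 14], &be2 = P[pb + 15];

    L.Xin = X;
    L.Q = X * Wq; L.Q.each_row() += bq.col(0).t();
    L.K = X * Wk; L.K.each_row() += bk.col(0).t();
    L.V = X * Wv; L.V.each_row() += bv.col(0).t();
    L.P.set_size(n_t, n_t, B * h);
    L.ctx.set_size(B * n_t, d);

    for (int b = 0; b < B; ++b) {
      int r0 = b * n_t, r1 = r0 + n_t - 1;
      for (int i = 0; i < h; ++i) {
        mat Qh = L.Q.submat(r0, i * dk, r1, (i + 1) * dk - 1);
        mat Kh = L.K.submat(r0, i * dk, r1, (i + 1) * dk - 1);
        mat S = Qh * Kh.t() * isdk;
        if (cfg.alibi) S += AB[i];
        for (int k = 0; k < n_t; ++k)
          if (msk(rows[b], k) == 0) S.col(k).fill(-1e30);
        for (int q = 0; q < n_t; ++q) {
          double mx = S.row(q).max();
          arma::rowvec e = arma::exp(S.row(q) - mx);
          S.row(q) = e / arma::accu(e);
        }
        L.P.slice(b * h + i) = S;
        L.ctx.submat(r0, i * dk, r1, (i + 1) * dk - 1) =
          S * L.V.submat(r0, i * dk, r1, (i + 1) * dk - 1);
      }
    }

    L.attn = L.ctx * Wo;
    L.attn.each_row() += bo.col(0).t();
    if (drop) {
      L.dm1.set_size(L.attn.n_rows, L.attn.n_cols);
      for (arma::uword i = 0; i < L.dm1.n_elem; ++i)
        L.dm1(i) = unif(*rng) < keep ? 1.0 / keep : 0.0;
      L.attn %= L.dm1;
    }
    L.res1 = L.Xin + L.attn;
    layernorm_fwd(L.res1, g1.col(0), be1.col(0), cfg.ln_eps, L.xhat1, L.istd1, L.y1);

    L.Hpre = L.y1 * W1;
    L.Hpre.each_row() += b1.col(0).t();
    L.Hsig = 1.0 / (1.0 + arma::exp(-GELU_A * L.Hpre));
    L.Hact = L.Hpre % L.Hsig;
    L.f = L.Hact * W2;
    L.f.each_row() += b2.col(0).t();
    if (drop) {
      L.dm2.set_size(L.f.n_rows, L.f.n_cols);
      for (arma::uword i = 0; i < L.dm2.n_elem; ++i)
        L.dm2(i) = unif(*rng) < keep ? 1.0 / keep : 0.0;
      L.f %= L.dm2;
    }
    L.res2 = L.y1 + L.f;
    layernorm_fwd(L.res2, g2.col(0), be2.col(0), cfg.ln_eps, L.xhat2, L.istd2, X);
  }
  C.Y = X;

  // heads
  int T = lbase(cfg.nl);
  const mat &Wc = P[T], &wseq = P[T + 1], &bseq = P[T + 2];
  const mat &wsub = P[T + 3], &bsub = P[T + 4];
  pseq.set_size(B);
  psub.set_size(B, cfg.n_sub);
  C.zseq.set_size(B);
  C.zsub.set_size(B, cfg.n_sub);
  C.Mrow.zeros(B * cfg.n_sub, 2 * d);
  C.Mm.zeros(B * cfg.n_sub, d);

  for (int b = 0; b < B; ++b) {
    int r0 = b * n_t;
    double z = arma::dot(C.Y.row(r0), wseq.col(0)) + bseq(0, 0);
    C.zseq(b) = z;
    pseq(b) = sigm(z);
    for (int t = 0; t < cfg.n_sub; ++t) {
      int p0 = 1 + t * cfg.m;
      int p1 = std::min(1 + (t + 1) * cfg.m, n_t);
      arma::rowvec mn(d, arma::fill::zeros), mx(d);
      int cnt = 0;
      bool first = true;
      for (int p = p0; p < p1; ++p) {
        if (msk(rows[b], p) == 0) continue;  // PAD excluded from pooling
        const arma::rowvec r = C.Y.row(r0 + p);
        mn += r;
        if (first) { mx = r; first = false; }
        else mx = arma::max(mx, r);
        ++cnt;
      }
      int rr = b * cfg.n_sub + t;
      if (cnt > 0) {
        mn /= cnt;
        C.Mrow(rr, arma::span(0, d - 1)) = mn;
        C.Mrow(rr, arma::span(d, 2 * d - 1)) = mx;
        C.Mm.row(rr) = C.Mrow.row(rr) * Wc;
      }
      double zs = arma::dot(C.Mm.row(rr), wsub.col(0)) + bsub(0, 0);
      C.zsub(b, t) = zs;
      psub(b, t) = sigm(zs);
    }
  }
}

struct LossOut {
  double loss, l_seq, l_tok;
};

// Weighted Eq.-1 token loss + sequence BCE on a scored batch.
static LossOut losses(const vec& pseq, const mat& psub, const vec& y,
                      const mat& ysub, const IntegerMatrix& vsub,
                      const std::vector<int>& rows, double lambda) {
  const int B = pseq.n_elem, n_sub = psub.n_cols;
  if (!pseq.is_finite() || !psub.is_finite())
    stop("training diverged: non-finite predictions");
  double ls = 0.0;
  for (int b = 0; b < B; ++b) {
    double p = clampp(pseq(b));
    ls += -(y(b) * std::log(p) + (1 - y(b)) * std::log(1 - p));
  }
  ls /= B;

  double nvpos = 0, nvneg = 0, sumV = 0;
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < n_sub; ++t) {
      if (vsub(rows[b], t) == 0) continue;
      sumV += 1;
      if (ysub(b, t) > 0.5) nvpos += 1; else nvneg += 1;
    }
  double lt = 0.0;
  if (lambda < 1.0) {
    if (sumV == 0) stop("no valid subregions in batch");
    double w = nvpos > 0 ? nvneg / nvpos : nvneg;
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < n_sub; ++t) {
        if (vsub(rows[b], t) == 0) continue;
        double p = clampp(psub(b, t));
        lt += -(w * ysub(b, t) * std::log(p) +
                (1 - ysub(b, t)) * std::log(1 - p));
      }
    lt /= sumV;
  }
  LossOut o;
  o.l_seq = ls;
  o.l_tok = lt;
  o.loss = lambda * ls + (1.0 - lambda) * lt;
  return o;
}

static void backward_batch(const std::vector<mat>& P, const Cfg& cfg,
                           const IntegerMatrix& ids, const IntegerMatrix& msk,
                           const std::vector<int>& rows, const Cache& C,
                           const vec& pseq, const mat& psub, const vec& y,
                           const mat& ysub, const IntegerMatrix& vsub,
                           double lambda, std::vector<mat>& G) {
  const int B = rows.size(), d = cfg.d, n_t = cfg.n_t, h = cfg.h, dk = cfg.dk;
  const double isdk = 1.0 / std::sqrt((double)dk);
  int T = lbase(cfg.nl);
  const mat &Wc = P[T], &wseq = P[T + 1], &wsub = P[T + 3];

  // dL/dz for both heads
  vec dzseq(B);
  for (int b = 0; b < B; ++b) {
    double p = pseq(b), pc = clampp(p);
    double dldp = -(y(b) / pc - (1 - y(b)) / (1 - pc)) * lambda / B;
    dzseq(b) = (pc == p) ? dldp * p * (1 - p) : 0.0;
  }
  mat dzsub(B, cfg.n_sub, arma::fill::zeros);
  if (lambda < 1.0) {
    double nvpos = 0, nvneg = 0, sumV = 0;
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < cfg.n_sub; ++t) {
        if (vsub(rows[b], t) == 0) continue;
        sumV += 1;
        if (ysub(b, t) > 0.5) nvpos += 1; else nvneg += 1;
      }
    double w = nvpos > 0 ? nvneg / nvpos : nvneg;
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < cfg.n_sub; ++t) {
        if (vsub(rows[b], t) == 0) continue;
        double p = psub(b, t), pc = clampp(p);
        double dldp = -(w * ysub(b, t) / pc - (1 - ysub(b, t)) / (1 - pc)) *
                      (1.0 - lambda) / sumV;
        dzsub(b, t) = (pc == p) ? dldp * p * (1 - p) : 0.0;
      }
  }

  mat dY(B * n_t, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    int r0 = b * n_t;
    dY.row(r0) += dzseq(b) * wseq.col(0).t();
    G[T + 1].col(0) += dzseq(b) * C.Y.row(r0).t();
    G[T + 2](0, 0) += dzseq(b);
    for (int t = 0; t < cfg.n_sub; ++t) {
      double dz = dzsub(b, t);
      int rr = b * cfg.n_sub + t;
      G[T + 4](0, 0) += dz;
      if (dz == 0.0) continue;
      G[T + 3].col(0) += dz * C.Mm.row(rr).t();
      arma::rowvec dMm = dz * wsub.col(0).t();
      arma::rowvec dmrow = dMm * Wc.t();
      G[T] += C.Mrow.row(rr).t() * dMm;
      // redistribute to pooled rows
      int p0 = 1 + t * cfg.m, p1 = std::min(1 + (t + 1) * cfg.m, n_t);
      std::vector<int> pool;
      for (int p = p0; p < p1; ++p)
        if (msk(rows[b], p) != 0) pool.push_back(p);
      if (pool.empty()) continue;
      double ic = 1.0 / pool.size();
      for (size_t pi = 0; pi < pool.size(); ++pi)
        dY.row(r0 + pool[pi]) += dmrow.subvec(0, d - 1) * ic;
      for (int c = 0; c < d; ++c) {
        int am = pool[0];
        double best = C.Y(r0 + pool[0], c);
        for (size_t pi = 1; pi < pool.size(); ++pi)
          if (C.Y(r0 + pool[pi], c) > best) { best = C.Y(r0 + pool[pi], c); am = pool[pi]; }
        dY(r0 + am, c) += dmrow(d + c);
      }
    }
  }

  for (int l = cfg.nl - 1; l >= 0; --l) {
    const LayerCache& L = C.lay[l];
    int pb = lbase(l);
    const mat &Wq = P[pb], &Wk = P[pb + 2], &Wv = P[pb + 4], &Wo = P[pb + 6];
    const mat &g1 = P[pb + 8], &W1 = P[pb + 10], &W2 = P[pb + 12], &g2 = P[pb + 14];

    mat dres2 = layernorm_bwd(dY, L.xhat2, L.istd2, g2.col(0), G[pb + 14], G[pb + 15]);
    mat dy1 = dres2;
    mat df = dres2;
    if (!L.dm2.is_empty()) df %= L.dm2;
    mat dHact = df * W2.t();
    G[pb + 12] += L.Hact.t() * df;
    G[pb + 13].col(0) += arma::sum(df, 0).t();
    // d/dx [x s(ax)] = s + a x s (1 - s), with s cached from the forward
    mat dHpre = dHact % (L.Hsig + GELU_A * L.Hpre % L.Hsig % (1.0 - L.Hsig));
    dy1 += dHpre * W1.t();
    G[pb + 10] += L.y1.t() * dHpre;
    G[pb + 11].col(0) += arma::sum(dHpre, 0).t();

    mat dres1 = layernorm_bwd(dy1, L.xhat1, L.istd1, g1.col(0), G[pb + 8], G[pb + 9]);
    mat dXin = dres1;
    mat dattn = dres1;
    if (!L.dm1.is_empty()) dattn %= L.dm1;
    mat dctx = dattn * Wo.t();
    G[pb + 6] += L.ctx.t() * dattn;
    G[pb + 7].col(0) += arma::sum(dattn, 0).t();

    mat dQ(B * n_t, d, arma::fill::zeros), dK(B * n_t, d, arma::fill::zeros),
        dV(B * n_t, d, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      int r0 = b * n_t, r1 = r0 + n_t - 1;
      for (int i = 0; i < h; ++i) {
        const mat& Pm = L.P.slice(b * h + i);
        mat dctx_h = dctx.submat(r0, i * dk, r1, (i + 1) * dk - 1);
        mat Vh = L.V.submat(r0, i * dk, r1, (i + 1) * dk - 1);
        mat dP = dctx_h * Vh.t();
        dV.submat(r0, i * dk, r1, (i + 1) * dk - 1) += Pm.t() * dctx_h;
        mat dS = Pm % dP;
        vec rs = arma::sum(dS, 1);
        dS -= Pm.each_col() % rs;
        mat Qh = L.Q.submat(r0, i * dk, r1, (i + 1) * dk - 1);
        mat Kh = L.K.submat(r0, i * dk, r1, (i + 1) * dk - 1);
        dQ.submat(r0, i * dk, r1, (i + 1) * dk - 1) += dS * Kh * isdk;
        dK.submat(r0, i * dk, r1, (i + 1) * dk - 1) += dS.t() * Qh * isdk;
      }
    }
    dXin += dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    G[pb] += L.Xin.t() * dQ;
    G[pb + 1].col(0) += arma::sum(dQ, 0).t();
    G[pb + 2] += L.Xin.t() * dK;
    G[pb + 3].col(0) += arma::sum(dK, 0).t();
    G[pb + 4] += L.Xin.t() * dV;
    G[pb + 5].col(0) += arma::sum(dV, 0).t();
    dY = dXin;
  }

  for (int b = 0; b < B; ++b)
    for (int t = 0; t < n_t; ++t)
      G[0].row(ids(rows[b], t)) += dY.row(b * n_t + t);
}

static std::vector<mat> zero_like(const std::vector<mat>& P) {
  std::vector<mat> G(P.size());
  for (size_t i = 0; i < P.size(); ++i) G[i].zeros(P[i].n_rows, P[i].n_cols);
  return G;
}

static std::vector<mat> make_alibi(const Cfg& cfg) {
  std::vector<mat> AB;
  if (cfg.alibi)
    for (int i = 0; i < cfg.h; ++i) AB.push_back(alibi_bias(cfg.n_t, cfg.h, i));
  return AB;
}

// Forward scoring in chunks; returns sequence and subregion probabilities.
// [[Rcpp::export(name = ".cpp_predict")]]
List cpp_predict(IntegerMatrix ids, IntegerMatrix msk, List params, List cfgL) {
  Cfg cfg = read_cfg(cfgL);
  std::vector<mat> P = read_params(params);
  std::vector<mat> AB = make_alibi(cfg);
  const int N = ids.nrow();
  NumericVector pseq_out(N);
  NumericMatrix psub_out(N, cfg.n_sub);
  const int chunk = 512;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    std::vector<int> rows;
    for (int i = s; i < e; ++i) rows.push_back(i);
    Cache C;
    vec pseq;
    mat psub;
    forward_batch(P, cfg, ids, msk, rows, C, pseq, psub, false, 0.0, nullptr, AB);
    for (int i = s; i < e; ++i) {
      pseq_out[i] = pseq(i - s);
      for (int t = 0; t < cfg.n_sub; ++t) psub_out(i, t) = psub(i - s, t);
    }
  }
  return List::create(_["p_seq"] = pseq_out, _["p_sub"] = psub_out);
}

// Loss and analytic gradients for one batch (no dropout); used by training,
// the finite-difference gradient test and the loss-gating test.
// [[Rcpp::export(name = ".cpp_loss_grads")]]
List cpp_loss_grads(IntegerMatrix ids, IntegerMatrix msk, NumericVector yseq,
                    NumericMatrix ysub, IntegerMatrix vsub, List params,
                    List cfgL, double lambda, bool want_grads = true) {
  Cfg cfg = read_cfg(cfgL);
  std::vector<mat> P = read_params(params);
  std::vector<mat> AB = make_alibi(cfg);
  const int N = ids.nrow();
  std::vector<int> rows;
  for (int i = 0; i < N; ++i) rows.push_back(i);
  Cache C;
  vec pseq;
  mat psub;
  forward_batch(P, cfg, ids, msk, rows, C, pseq, psub, false, 0.0, nullptr, AB);
  vec y = as<vec>(yseq);
  mat ys = as<mat>(ysub);
  LossOut lo = losses(pseq, psub, y, ys, vsub, rows, lambda);
  List out = List::create(_["loss"] = lo.loss, _["loss_seq"] = lo.l_seq,
                          _["loss_tok"] = lo.l_tok);
  if (want_grads) {
    std::vector<mat> G = zero_like(P);
    backward_batch(P, cfg, ids, msk, rows, C, pseq, psub, y, ys, vsub, lambda, G);
    List gl(G.size());
    for (size_t i = 0; i < G.size(); ++i) gl[i] = wrap(G[i]);
    gl.attr("names") = params.attr("names");
    out["grads"] = gl;
  }
  return out;
}

static double auroc_cpp(const std::vector<double>& score,
                        const std::vector<double>& lab) {
  const int n = score.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return score[a] < score[b]; });
  std::vector<double> rank(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && score[ord[j + 1]] == score[ord[i]]) ++j;
    double r = (i + j) / 2.0 + 1.0;
    for (int k = i; k <= j; ++k) rank[ord[k]] = r;
    i = j + 1;
  }
  double np = 0, nn = 0, rs = 0;
  for (int k = 0; k < n; ++k) {
    if (lab[k] > 0.5) { np += 1; rs += rank[k]; }
    else nn += 1;
  }
  if (np == 0 || nn == 0) return 0.5;
  return (rs - np * (np + 1) / 2.0) / (np * nn);
}

// AdamW training loop with linear warmup + linear decay, early stopping on
// validation sequence-level AUROC. Returns best parameters and history.
// [[Rcpp::export(name = ".cpp_train")]]
List cpp_train(IntegerMatrix ids, IntegerMatrix msk, NumericVector yseq,
               NumericMatrix ysub, IntegerMatrix vsub, IntegerMatrix vids,
               IntegerMatrix vmsk, NumericVector vyseq, List params0,
               List cfgL, List recipe) {
  Cfg cfg = read_cfg(cfgL);
  std::vector<mat> P = read_params(params0);
  std::vector<mat> AB = make_alibi(cfg);

  const int epochs = as<int>(recipe["epochs"]);
  const int batch = as<int>(recipe["batch_size"]);
  const double lr0 = as<double>(recipe["lr"]);
  const double wd = as<double>(recipe["weight_decay"]);
  const double warm_frac = as<double>(recipe["warmup_frac"]);
  const int patience = as<int>(recipe["patience"]);
  const double lambda = as<double>(recipe["lambda"]);
  const double dropout = as<double>(recipe["dropout"]);
  const unsigned long seed = as<double>(recipe["seed"]);
  const bool verbose = recipe.containsElementNamed("verbose") ?
    as<bool>(recipe["verbose"]) : false;

  const int N = ids.nrow();
  if (N == 0) stop("empty training set");
  const int nb = (N + batch - 1) / batch;
  const long total_steps = (long)epochs * nb;
  const long warm = std::max(1L, (long)std::ceil(warm_frac * total_steps));

  std::mt19937_64 rng(seed);
  std::vector<mat> M = zero_like(P), V2 = zero_like(P);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;

  std::vector<double> h_loss, h_seq, h_tok, h_val;
  double best_val = -1.0;
  int best_epoch = -1, since_best = 0;
  std::vector<mat> bestP = P;
  const bool has_val = vids.nrow() > 0;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle with own RNG for cross-platform determinism
    for (int i = N - 1; i > 0; --i) {
      std::uniform_int_distribution<int> u(0, i);
      std::swap(perm[i], perm[u(rng)]);
    }
    double eloss = 0, eseq = 0, etok = 0;
    for (int bi = 0; bi < nb; ++bi) {
      std::vector<int> rows;
      for (int i = bi * batch; i < std::min(N, (bi + 1) * batch); ++i)
        rows.push_back(perm[i]);
      Cache C;
      vec pseq;
      mat psub;
      forward_batch(P, cfg, ids, msk, rows, C, pseq, psub, true, dropout, &rng, AB);
      vec y(rows.size());
      mat ys(rows.size(), cfg.n_sub);
      for (size_t i = 0; i < rows.size(); ++i) {
        y(i) = yseq[rows[i]];
        for (int t = 0; t < cfg.n_sub; ++t) ys(i, t) = ysub(rows[i], t);
      }
      LossOut lo = losses(pseq, psub, y, ys, vsub, rows, lambda);
      if (!std::isfinite(lo.loss))
        stop("training diverged: non-finite loss at epoch %d", ep + 1);
      eloss += lo.loss * rows.size();
      eseq += lo.l_seq * rows.size();
      etok += lo.l_tok * rows.size();

      std::vector<mat> G = zero_like(P);
      backward_batch(P, cfg, ids, msk, rows, C, pseq, psub, y, ys, vsub, lambda, G);

      ++step;
      double lr = step <= warm ? lr0 * (double)step / warm
                               : lr0 * (double)(total_steps - step) /
                                   std::max(1L, total_steps - warm);
      if (lr < 0) lr = 0;
      double bc1 = 1.0 - std::pow(b1, (double)step);
      double bc2 = 1.0 - std::pow(b2, (double)step);
      for (size_t pi = 0; pi < P.size(); ++pi) {
        M[pi] = b1 * M[pi] + (1 - b1) * G[pi];
        V2[pi] = b2 * V2[pi] + (1 - b2) * (G[pi] % G[pi]);
        if (wd > 0 && P[pi].n_cols > 1) P[pi] -= lr * wd * P[pi];
        P[pi] -= lr * (M[pi] / bc1) / (arma::sqrt(V2[pi] / bc2) + eps);
      }
      if ((step & 0x3f) == 0) Rcpp::checkUserInterrupt();
    }
    h_loss.push_back(eloss / N);
    h_seq.push_back(eseq / N);
    h_tok.push_back(etok / N);

    double va = NA_REAL;
    if (has_val) {
      std::vector<double> vs, vl;
      const int chunk = 512;
      for (int s = 0; s < vids.nrow(); s += chunk) {
        int e = std::min(vids.nrow(), s + chunk);
        std::vector<int> rows;
        for (int i = s; i < e; ++i) rows.push_back(i);
        Cache C;
        vec pseq;
        mat psub;
        forward_batch(P, cfg, vids, vmsk, rows, C, pseq, psub, false, 0.0,
                      nullptr, AB);
        for (int i = s; i < e; ++i) {
          vs.push_back(pseq(i - s));
          vl.push_back(vyseq[i]);
        }
      }
      va = auroc_cpp(vs, vl);
      if (va > best_val + 1e-5) {
        best_val = va;
        best_epoch = ep + 1;
        bestP = P;
        since_best = 0;
      } else {
        ++since_best;
      }
    }
    h_val.push_back(va);
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << " loss " << h_loss.back()
                  << " val_auroc " << va << std::endl;
    if (has_val && since_best >= patience) break;
  }

  if (!has_val) { bestP = P; best_epoch = epochs; }
  List pl(bestP.size());
  for (size_t i = 0; i < bestP.size(); ++i) pl[i] = wrap(bestP[i]);
  pl.attr("names") = params0.attr("names");
  return List::create(
    _["params"] = pl, _["best_epoch"] = best_epoch, _["best_val"] = best_val,
    _["loss"] = wrap(h_loss), _["loss_seq"] = wrap(h_seq),
    _["loss_tok"] = wrap(h_tok), _["val_auroc"] = wrap(h_val));
}
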