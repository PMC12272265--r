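// Forward and backward passes of the quadrant-attention brain-age model.
//
// The R level owns parameter initialization, the Adam updates, fold
// assignment and all bookkeeping; this file only evaluates the network and
// its exact gradients for a batch of subjects.  All paths are
// differentiated exactly -- including the dependence of the degree matrix
// D on the score-weighted adjacency (except at the isolated-node clamp,
// where the derivative is zero anyway) -- and verified against finite
// differences in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

namespace {

struct Config {
  bool use_qam, use_traits, use_behavior, clamp, inv_degree;
  int h, dk;
  double topk_ratio;
};

Config read_config(const List& flags) {
  Config c;
  c.use_qam = as<bool>(flags["use_qam"]);
  c.use_traits = as<bool>(flags["use_traits"]);
  c.use_behavior = as<bool>(flags["use_behavior"]);
  c.clamp = as<bool>(flags["clamp"]);
  c.h = as<int>(flags["h"]);
  c.dk = as<int>(flags["dk"]);
  c.topk_ratio = as<double>(flags["topk_ratio"]);
  c.inv_degree = as<bool>(flags["inv_degree"]);
  return c;
}

mat row_softmax(const mat& Z) {
  mat A = Z;
  A.each_col() -= arma::max(Z, 1);
  A = arma::exp(A);
  A.each_col() /= arma::sum(A, 1);
  return A;
}

// top-k node indices: highest scores, ties to the lowest index,
// returned ascending
uvec topk_indices(const vec& scores, int keep) {
  const int k = scores.n_elem;
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return scores[a] > scores[b]; });
  idx.resize(keep);
  std::sort(idx.begin(), idx.end());
  uvec out(keep);
  for (int i = 0; i < keep; ++i) out[i] = idx[i];
  return out;
}

// diagonal of the degree normalizer D: raw degrees (the update rule's
// literal D, zero-degree isolated nodes set to 1) or inverse degrees
vec degree_diag(const mat& A, bool inverse) {
  vec d = arma::sum(A, 1);
  for (arma::uword i = 0; i < d.n_elem; ++i)
    if (d[i] <= 0.0) d[i] = 1.0;
  return inverse ? vec(1.0 / d) : d;
}

// ------------------------------------------------------------------ QAM
struct HeadCache { mat Q, K, V, A; };
struct QuadCache { mat Xq, C, Sq; std::vector<HeadCache> heads; };

struct QamWeights {
  // [quadrant][head]
  std::vector<std::vector<mat>> WQ, WK, WV;
  std::vector<mat> WO;
};

QamWeights read_qam(const List& qam, int h) {
  QamWeights w;
  w.WQ.resize(4); w.WK.resize(4); w.WV.resize(4); w.WO.resize(4);
  for (int q = 0; q < 4; ++q) {
    List wq = qam[q];
    List LQ = wq["WQ"], LK = wq["WK"], LV = wq["WV"];
    for (int j = 0; j < h; ++j) {
      w.WQ[q].push_back(as<mat>(LQ[j]));
      w.WK[q].push_back(as<mat>(LK[j]));
      w.WV[q].push_back(as<mat>(LV[j]));
    }
    w.WO[q] = as<mat>(wq["WO"]);
  }
  return w;
}

struct QamGrads {
  std::vector<std::vector<mat>> WQ, WK, WV;
  std::vector<mat> WO;
  void init(const QamWeights& w, int h) {
    WQ.resize(4); WK.resize(4); WV.resize(4); WO.resize(4);
    for (int q = 0; q < 4; ++q) {
      for (int j = 0; j < h; ++j) {
        WQ[q].push_back(arma::zeros<mat>(arma::size(w.WQ[q][j])));
        WK[q].push_back(arma::zeros<mat>(arma::size(w.WK[q][j])));
        WV[q].push_back(arma::zeros<mat>(arma::size(w.WV[q][j])));
      }
      WO[q] = arma::zeros<mat>(arma::size(w.WO[q]));
    }
  }
};

// quadrant order LL, LR, RL, RR; block (r, c) of the 2x2 partition
inline void quad_span(int q, int m, int& r0, int& c0) {
  r0 = (q >= 2) ? m : 0;
  c0 = (q % 2 == 1) ? m : 0;
}

mat qam_forward(const mat& X, const QamWeights& w, const Config& cfg,
                std::vector<QuadCache>& caches) {
  const int n = X.n_rows, m = n / 2;
  const double sdk = std::sqrt((double)cfg.dk);
  mat S(n, n);
  caches.resize(4);
  for (int q = 0; q < 4; ++q) {
    int r0, c0; quad_span(q, m, r0, c0);
    QuadCache& qc = caches[q];
    qc.Xq = X.submat(r0, c0, r0 + m - 1, c0 + m - 1);
    qc.heads.resize(cfg.h);
    mat C(m, cfg.h * cfg.dk);
    for (int j = 0; j < cfg.h; ++j) {
      HeadCache& hc = qc.heads[j];
      hc.Q = qc.Xq * w.WQ[q][j];
      hc.K = qc.Xq * w.WK[q][j];
      hc.V = qc.Xq * w.WV[q][j];
      hc.A = row_softmax(hc.Q * hc.K.t() / sdk);
      C.cols(j * cfg.dk, (j + 1) * cfg.dk - 1) = hc.A * hc.V;
    }
    qc.C = C;
    qc.Sq = C * w.WO[q];
    S.submat(r0, c0, r0 + m - 1, c0 + m - 1) = qc.Sq;
  }
  if (cfg.clamp) S.transform([](double v) { return v < 0 ? 0.0 : v; });
  return S;
}

void qam_backward(const mat& dS, const mat& S, const QamWeights& w,
                  const Config& cfg, const std::vector<QuadCache>& caches,
                  bool share, QamGrads& g) {
  const int n = dS.n_rows, m = n / 2;
  const double sdk = std::sqrt((double)cfg.dk);
  for (int q = 0; q < 4; ++q) {
    int r0, c0; quad_span(q, m, r0, c0);
    mat dSq = dS.submat(r0, c0, r0 + m - 1, c0 + m - 1);
    if (cfg.clamp) {
      mat Sq = S.submat(r0, c0, r0 + m - 1, c0 + m - 1);
      dSq.elem(arma::find(Sq <= 0)).zeros();
    }
    const QuadCache& qc = caches[q];
    const int gq = share ? 0 : q;
    g.WO[gq] += qc.C.t() * dSq;
    mat dC = dSq * w.WO[q].t();
    for (int j = 0; j < cfg.h; ++j) {
      const HeadCache& hc = qc.heads[j];
      mat dHd = dC.cols(j * cfg.dk, (j + 1) * cfg.dk - 1);
      mat dA = dHd * hc.V.t();
      mat dV = hc.A.t() * dHd;
      vec rs = arma::sum(dA % hc.A, 1);
      mat dZ = hc.A % (dA.each_col() - rs);
      mat dQ = dZ * hc.K / sdk;
      mat dK = dZ.t() * hc.Q / sdk;
      g.WQ[gq][j] += qc.Xq.t() * dQ;
      g.WK[gq][j] += qc.Xq.t() * dK;
      g.WV[gq][j] += qc.Xq.t() * dV;
    }
  }
}

// ------------------------------------------------------------------ CNNs
struct Conv1Weights { arma::cube W1, W2; vec b1, b2; mat We; vec be; };
struct Conv2Weights {
  NumericVector W1, W2;  // 4D arrays, manual indexing
  IntegerVector d1, d2;
  vec b1, b2; mat We; vec be;
};

Conv1Weights read_c1(const List& c1) {
  Conv1Weights w;
  List conv = c1["conv"];
  List l1 = conv[0], l2 = conv[1], lin = c1["lin"];
  NumericVector W1 = l1["W"], W2 = l2["W"];
  IntegerVector d1 = W1.attr("dim"), d2 = W2.attr("dim");
  w.W1 = arma::cube(W1.begin(), d1[0], d1[1], d1[2]);
  w.W2 = arma::cube(W2.begin(), d2[0], d2[1], d2[2]);
  w.b1 = as<vec>(l1["b"]); w.b2 = as<vec>(l2["b"]);
  w.We = as<mat>(lin["W"]); w.be = as<vec>(lin["b"]);
  return w;
}

Conv2Weights read_c2(const List& c2) {
  Conv2Weights w;
  List conv = c2["conv"];
  List l1 = conv[0], l2 = conv[1], lin = c2["lin"];
  w.W1 = l1["W"]; w.W2 = l2["W"];
  w.d1 = w.W1.attr("dim"); w.d2 = w.W2.attr("dim");
  w.b1 = as<vec>(l1["b"]); w.b2 = as<vec>(l2["b"]);
  w.We = as<mat>(lin["W"]); w.be = as<vec>(lin["b"]);
  return w;
}

struct C1Cache { arma::rowvec x; mat y1, y2; vec gap, emb; };

vec c1_forward(const arma::rowvec& x, const Conv1Weights& w, C1Cache& cc) {
  const int oc1 = w.W1.n_rows, kw1 = w.W1.n_slices;
  const int t1 = x.n_elem - kw1 + 1;
  mat y1(oc1, t1, arma::fill::zeros);
  for (int c = 0; c < oc1; ++c)
    for (int i = 0; i < t1; ++i) {
      double acc = w.b1[c];
      for (int u = 0; u < kw1; ++u) acc += w.W1(c, 0, u) * x[i + u];
      y1(c, i) = acc > 0 ? acc : 0;
    }
  const int oc2 = w.W2.n_rows, ic2 = w.W2.n_cols, kw2 = w.W2.n_slices;
  const int t2 = t1 - kw2 + 1;
  mat y2(oc2, t2, arma::fill::zeros);
  for (int c = 0; c < oc2; ++c)
    for (int i = 0; i < t2; ++i) {
      double acc = w.b2[c];
      for (int ci = 0; ci < ic2; ++ci)
        for (int u = 0; u < kw2; ++u) acc += w.W2(c, ci, u) * y1(ci, i + u);
      y2(c, i) = acc > 0 ? acc : 0;
    }
  cc.x = x; cc.y1 = y1; cc.y2 = y2;
  cc.gap = arma::mean(y2, 1);
  cc.emb = w.We * cc.gap + w.be;
  return cc.emb;
}

struct Conv1Grads { arma::cube W1, W2; vec b1, b2; mat We; vec be; };

void c1_backward(const vec& demb, const Conv1Weights& w, const C1Cache& cc,
                 Conv1Grads& g) {
  g.We += demb * cc.gap.t();
  g.be += demb;
  vec dgap = w.We.t() * demb;
  const int t2 = cc.y2.n_cols;
  mat dy2(cc.y2.n_rows, t2);
  for (arma::uword c = 0; c < cc.y2.n_rows; ++c)
    for (int i = 0; i < t2; ++i)
      dy2(c, i) = cc.y2(c, i) > 0 ? dgap[c] / t2 : 0.0;
  const int oc2 = w.W2.n_rows, ic2 = w.W2.n_cols, kw2 = w.W2.n_slices;
  mat dy1(arma::size(cc.y1), arma::fill::zeros);
  for (int c = 0; c < oc2; ++c)
    for (int i = 0; i < t2; ++i) {
      const double v = dy2(c, i);
      if (v == 0.0) continue;
      g.b2[c] += v;
      for (int ci = 0; ci < ic2; ++ci)
        for (int u = 0; u < kw2; ++u) {
          g.W2(c, ci, u) += v * cc.y1(ci, i + u);
          dy1(ci, i + u) += v * w.W2(c, ci, u);
        }
    }
  const int oc1 = w.W1.n_rows, kw1 = w.W1.n_slices;
  for (int c = 0; c < oc1; ++c)
    for (arma::uword i = 0; i < cc.y1.n_cols; ++i) {
      if (cc.y1(c, i) <= 0) continue;
      const double v = dy1(c, i);
      g.b1[c] += v;
      for (int u = 0; u < kw1; ++u) g.W1(c, 0, u) += v * cc.x[i + u];
    }
}

struct C2Cache { mat x; arma::cube y1, y2; vec gap, emb; };

inline double w4(const NumericVector& W, const IntegerVector& d,
                 int a, int b, int c, int e) {
  return W[a + d[0] * (b + d[1] * (c + d[2] * e))];
}
inline double& w4ref(std::vector<double>& W, const IntegerVector& d,
                     int a, int b, int c, int e) {
  return W[a + d[0] * (b + d[1] * (c + d[2] * e))];
}

vec c2_forward(const mat& B, const Conv2Weights& w, C2Cache& cc) {
  const int oc1 = w.d1[0], kh1 = w.d1[2], kw1 = w.d1[3];
  const int h1 = B.n_rows - kh1 + 1, w1o = B.n_cols - kw1 + 1;
  arma::cube y1(h1, w1o, oc1, arma::fill::zeros);  // (i, j, channel)
  for (int c = 0; c < oc1; ++c)
    for (int i = 0; i < h1; ++i)
      for (int j = 0; j < w1o; ++j) {
        double acc = w.b1[c];
        for (int u = 0; u < kh1; ++u)
          for (int v = 0; v < kw1; ++v)
            acc += w4(w.W1, w.d1, c, 0, u, v) * B(i + u, j + v);
        y1(i, j, c) = acc > 0 ? acc : 0;
      }
  const int oc2 = w.d2[0], ic2 = w.d2[1], kh2 = w.d2[2], kw2 = w.d2[3];
  const int h2 = h1 - kh2 + 1, w2o = w1o - kw2 + 1;
  arma::cube y2(h2, w2o, oc2, arma::fill::zeros);
  for (int c = 0; c < oc2; ++c)
    for (int i = 0; i < h2; ++i)
      for (int j = 0; j < w2o; ++j) {
        double acc = w.b2[c];
        for (int ci = 0; ci < ic2; ++ci)
          for (int u = 0; u < kh2; ++u)
            for (int v = 0; v < kw2; ++v)
              acc += w4(w.W2, w.d2, c, ci, u, v) * y1(i + u, j + v, ci);
        y2(i, j, c) = acc > 0 ? acc : 0;
      }
  cc.x = B; cc.y1 = y1; cc.y2 = y2;
  cc.gap.set_size(oc2);
  for (int c = 0; c < oc2; ++c) cc.gap[c] = arma::accu(y2.slice(c)) / (h2 * w2o);
  cc.emb = w.We * cc.gap + w.be;
  return cc.emb;
}

struct Conv2Grads {
  std::vector<double> W1, W2; vec b1, b2; mat We; vec be;
};

void c2_backward(const vec& demb, const Conv2Weights& w, const C2Cache& cc,
                 Conv2Grads& g) {
  g.We += demb * cc.gap.t();
  g.be += demb;
  vec dgap = w.We.t() * demb;
  const int oc2 = w.d2[0], ic2 = w.d2[1], kh2 = w.d2[2], kw2 = w.d2[3];
  const int h2 = cc.y2.n_rows, w2o = cc.y2.n_cols;
  arma::cube dy1(arma::size(cc.y1), arma::fill::zeros);
  const double inv_area = 1.0 / (h2 * w2o);
  for (int c = 0; c < oc2; ++c)
    for (int i = 0; i < h2; ++i)
      for (int j = 0; j < w2o; ++j) {
        if (cc.y2(i, j, c) <= 0) continue;
        const double v = dgap[c] * inv_area;
        g.b2[c] += v;
        for (int ci = 0; ci < ic2; ++ci)
          for (int u = 0; u < kh2; ++u)
            for (int vv = 0; vv < kw2; ++vv) {
              w4ref(g.W2, w.d2, c, ci, u, vv) += v * cc.y1(i + u, j + vv, ci);
              dy1(i + u, j + vv, ci) += v * w4(w.W2, w.d2, c, ci, u, vv);
            }
      }
  const int oc1 = w.d1[0], kh1 = w.d1[2], kw1 = w.d1[3];
  for (int c = 0; c < oc1; ++c)
    for (arma::uword i = 0; i < cc.y1.n_rows; ++i)
      for (arma::uword j = 0; j < cc.y1.n_cols; ++j) {
        if (cc.y1(i, j, c) <= 0) continue;
        const double v = dy1(i, j, c);
        g.b1[c] += v;
        for (int u = 0; u < kh1; ++u)
          for (int vv = 0; vv < kw1; ++vv)
            w4ref(g.W1, w.d1, c, 0, u, vv) += v * cc.x(i + u, j + vv);
      }
}

}  // namespace

// Evaluate the network on a batch of subjects; optionally accumulate exact
// gradients of the mean squared error w.r.t. every learnable weight.
// [[Rcpp::export]]
List fagnn_core(const List& weights, const List& data, const List& flags,
                const IntegerVector& batch, bool compute_grad,
                bool want_scores) {
  const Config cfg = read_config(flags);
  const bool share = as<bool>(flags["share"]);
  const List Xs = data["X"];
  const NumericMatrix traits = data["traits"];
  const List behaviors = data["behavior"];
  const NumericVector y = data["y"];

  // --- read weights
  QamWeights qw;
  if (cfg.use_qam) qw = read_qam(as<List>(weights["qam"]), cfg.h);
  List gnnw = weights["gnn"];
  const mat W1 = as<mat>(gnnw["W1"]);
  const mat W2 = as<mat>(gnnw["W2"]);
  Conv1Weights c1w; Conv2Weights c2w;
  if (cfg.use_traits) c1w = read_c1(as<List>(weights["c1"]));
  if (cfg.use_behavior) c2w = read_c2(as<List>(weights["c2"]));
  List mlpw = weights["mlp"];
  const int nl = mlpw.size();
  std::vector<mat> MW(nl); std::vector<vec> Mb(nl);
  for (int i = 0; i < nl; ++i) {
    List li = mlpw[i];
    MW[i] = as<mat>(li["W"]);
    Mb[i] = as<vec>(li["b"]);
  }

  // --- gradient accumulators
  QamGrads qg; if (compute_grad && cfg.use_qam) qg.init(qw, cfg.h);
  mat gW1, gW2;
  Conv1Grads c1g; Conv2Grads c2g;
  std::vector<mat> gMW(nl); std::vector<vec> gMb(nl);
  if (compute_grad) {
    gW1 = arma::zeros<mat>(arma::size(W1));
    gW2 = arma::zeros<mat>(arma::size(W2));
    if (cfg.use_traits) {
      c1g.W1 = arma::zeros<arma::cube>(arma::size(c1w.W1));
      c1g.W2 = arma::zeros<arma::cube>(arma::size(c1w.W2));
      c1g.b1 = arma::zeros<vec>(c1w.b1.n_elem);
      c1g.b2 = arma::zeros<vec>(c1w.b2.n_elem);
      c1g.We = arma::zeros<mat>(arma::size(c1w.We));
      c1g.be = arma::zeros<vec>(c1w.be.n_elem);
    }
    if (cfg.use_behavior) {
      c2g.W1.assign(c2w.W1.size(), 0.0);
      c2g.W2.assign(c2w.W2.size(), 0.0);
      c2g.b1 = arma::zeros<vec>(c2w.b1.n_elem);
      c2g.b2 = arma::zeros<vec>(c2w.b2.n_elem);
      c2g.We = arma::zeros<mat>(arma::size(c2w.We));
      c2g.be = arma::zeros<vec>(c2w.be.n_elem);
    }
    for (int i = 0; i < nl; ++i) {
      gMW[i] = arma::zeros<mat>(arma::size(MW[i]));
      gMb[i] = arma::zeros<vec>(Mb[i].n_elem);
    }
  }

  const int B = batch.size();
  NumericVector yhat(B);
  List Sout(want_scores ? B : 0);
  double loss = 0.0;

  for (int bi = 0; bi < B; ++bi) {
    const int s = batch[bi];
    const mat X = as<mat>(Xs[s]);
    const int n = X.n_rows;
    const int k1 = (int)std::ceil(cfg.topk_ratio * n);
    const int k2 = (int)std::ceil(cfg.topk_ratio * k1);

    // ---- forward: QAM
    std::vector<QuadCache> qcache;
    mat S;
    if (cfg.use_qam) S = qam_forward(X, qw, cfg, qcache);

    // ---- forward: GNN
    const mat A1 = cfg.use_qam ? mat(X % S) : X;
    const vec dinv1 = degree_diag(A1, cfg.inv_degree);
    mat P1 = arma::eye(n, n) + A1;
    P1.each_row() %= dinv1.t();
    const mat Z1 = P1 * W1;
    const mat H1 = arma::clamp(Z1, 0.0, arma::datum::inf);
    const uvec kept1 = topk_indices(arma::mean(H1, 1), k1);
    const mat H1p = H1.submat(kept1, kept1);
    const vec dinv2 = degree_diag(H1p, cfg.inv_degree);
    mat P2 = arma::eye(k1, k1) + H1p;
    P2.each_row() %= dinv2.t();
    const mat Z2 = P2 * W2;
    const mat H2 = arma::clamp(Z2, 0.0, arma::datum::inf);
    const uvec kept2 = topk_indices(arma::mean(H2, 1), k2);
    const mat H2p = H2.submat(kept2, kept2);
    const vec g = arma::vectorise(H2p);   // row-flatten readout

    // ---- forward: CNNs
    C1Cache c1c; C2Cache c2c;
    vec e1, e2;
    if (cfg.use_traits) {
      arma::rowvec tr(traits.ncol());
      for (int j = 0; j < traits.ncol(); ++j) tr[j] = traits(s, j);
      e1 = c1_forward(tr, c1w, c1c);
    }
    if (cfg.use_behavior) e2 = c2_forward(as<mat>(behaviors[s]), c2w, c2c);

    // ---- forward: fusion MLP
    vec f = g;
    if (cfg.use_traits) f = arma::join_cols(f, e1);
    if (cfg.use_behavior) f = arma::join_cols(f, e2);
    std::vector<vec> acts(nl + 1);
    acts[0] = f;
    for (int i = 0; i < nl; ++i) {
      vec z = MW[i] * acts[i] + Mb[i];
      if (i < nl - 1) z = arma::clamp(z, 0.0, arma::datum::inf);
      acts[i + 1] = z;
    }
    const double pred = acts[nl][0];
    yhat[bi] = pred;
    const double err = pred - y[s];
    loss += err * err / B;
    if (want_scores)
      Sout[bi] = cfg.use_qam ? wrap(S) : wrap(arma::ones<mat>(n, n));

    if (!compute_grad) continue;

    // ---- backward: MLP
    vec dz(1); dz[0] = 2.0 * err / B;
    for (int i = nl - 1; i >= 0; --i) {
      gMW[i] += dz * acts[i].t();
      gMb[i] += dz;
      vec da = MW[i].t() * dz;
      if (i > 0) {
        // ReLU mask of the hidden activation
        for (arma::uword u = 0; u < da.n_elem; ++u)
          if (acts[i][u] <= 0) da[u] = 0.0;
      }
      dz = da;
    }
    // dz now holds the gradient w.r.t. the concatenated embedding
    const int glen = k2 * k2;
    vec dg = dz.subvec(0, glen - 1);
    int off = glen;
    if (cfg.use_traits) {
      vec de1 = dz.subvec(off, off + e1.n_elem - 1);
      off += e1.n_elem;
      c1_backward(de1, c1w, c1c, c1g);
    }
    if (cfg.use_behavior) {
      vec de2 = dz.subvec(off, off + e2.n_elem - 1);
      c2_backward(de2, c2w, c2c, c2g);
    }

    // ---- backward: GNN
    mat dH2p = arma::reshape(dg, k2, k2);
    mat dH2 = arma::zeros<mat>(k1, k1);
    dH2.submat(kept2, kept2) = dH2p;
    mat dZ2 = dH2;
    dZ2.elem(arma::find(Z2 <= 0)).zeros();
    gW2 += P2.t() * dZ2;
    mat dP2 = dZ2 * W2.t();
    // P2 = M2 * diag(g(d2)); exact product rule:
    //   dM2 = dP2 * diag(g(d2));  dd2_j = sum_i dP2_ij M2_ij g'(d2_j)
    mat dM2 = dP2;
    dM2.each_row() %= dinv2.t();
    const mat M2 = arma::eye(k1, k1) + H1p;
    vec dd2 = arma::sum(dP2 % M2, 0).t();
    if (cfg.inv_degree) dd2 %= -dinv2 % dinv2;   // g(d)=1/d, g'=-1/d^2
    {
      vec d2raw = arma::sum(H1p, 1);
      dd2.elem(arma::find(d2raw <= 0)).zeros();  // clamped entries
    }
    // A2 = H1p enters both M2 and the degrees (row sums)
    mat dH1p = dM2;
    dH1p.each_col() += dd2;
    mat dH1 = arma::zeros<mat>(n, n);
    dH1.submat(kept1, kept1) = dH1p;
    mat dZ1 = dH1;
    dZ1.elem(arma::find(Z1 <= 0)).zeros();
    gW1 += P1.t() * dZ1;
    if (cfg.use_qam) {
      mat dP1 = dZ1 * W1.t();
      mat dM1 = dP1;
      dM1.each_row() %= dinv1.t();
      const mat M1 = arma::eye(n, n) + A1;
      vec dd1 = arma::sum(dP1 % M1, 0).t();
      if (cfg.inv_degree) dd1 %= -dinv1 % dinv1;
      {
        vec d1raw = arma::sum(A1, 1);
        dd1.elem(arma::find(d1raw <= 0)).zeros();
      }
      mat dA1 = dM1;
      dA1.each_col() += dd1;
      mat dS = dA1 % X;                   // A1 = X (.) S
      qam_backward(dS, S, qw, cfg, qcache, share, qg);
    }
  }

  List out = List::create(_["loss"] = loss, _["yhat"] = yhat);
  if (want_scores) out["S"] = Sout;
  if (compute_grad) {
    List grad;
    if (cfg.use_qam) {
      List gq(4);
      for (int q = 0; q < 4; ++q) {
        List LQ(cfg.h), LK(cfg.h), LV(cfg.h);
        for (int j = 0; j < cfg.h; ++j) {
          LQ[j] = wrap(qg.WQ[q][j]);
          LK[j] = wrap(qg.WK[q][j]);
          LV[j] = wrap(qg.WV[q][j]);
        }
        gq[q] = List::create(_["WQ"] = LQ, _["WK"] = LK, _["WV"] = LV,
                             _["WO"] = wrap(qg.WO[q]));
      }
      gq.attr("names") = CharacterVector::create("LL", "LR", "RL", "RR");
      grad["qam"] = gq;
    }
    grad["gnn"] = List::create(_["W1"] = wrap(gW1), _["W2"] = wrap(gW2));
    if (cfg.use_traits) {
      NumericVector gw1(c1g.W1.begin(), c1g.W1.end());
      gw1.attr("dim") = IntegerVector::create(c1w.W1.n_rows, c1w.W1.n_cols,
                                              c1w.W1.n_slices);
      NumericVector gw2(c1g.W2.begin(), c1g.W2.end());
      gw2.attr("dim") = IntegerVector::create(c1w.W2.n_rows, c1w.W2.n_cols,
                                              c1w.W2.n_slices);
      grad["c1"] = List::create(
        _["conv"] = List::create(
          List::create(_["W"] = gw1, _["b"] = wrap(c1g.b1)),
          List::create(_["W"] = gw2, _["b"] = wrap(c1g.b2))),
        _["lin"] = List::create(_["W"] = wrap(c1g.We), _["b"] = wrap(c1g.be)));
    }
    if (cfg.use_behavior) {
      NumericVector gw1(c2g.W1.begin(), c2g.W1.end());
      gw1.attr("dim") = c2w.d1;
      NumericVector gw2(c2g.W2.begin(), c2g.W2.end());
      gw2.attr("dim") = c2w.d2;
      grad["c2"] = List::create(
        _["conv"] = List::create(
          List::create(_["W"] = gw1, _["b"] = wrap(c2g.b1)),
          List::create(_["W"] = gw2, _["b"] = wrap(c2g.b2))),
        _["lin"] = List::create(_["W"] = wrap(c2g.We), _["b"] = wrap(c2g.be)));
    }
    List gm(nl);
    for (int i = 0; i < nl; ++i)
      gm[i] = List::create(_["W"] = wrap(gMW[i]), _["b"] = wrap(gMb[i]));
    grad["mlp"] = gm;
    out["grad"] = grad;
  }
  return out;
}
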