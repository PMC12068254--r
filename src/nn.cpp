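// CNN-LSTM-attention regressor: forward pass and analytic backpropagation.
//
// Layouts:
//   R-facing input  : cube B x C x L (batch, channels, time)
//   internal "big"  : mat (L*B) x D, row index t*B + b, so a time-major block
//                     of B rows per step; convolutions and attention scoring
//                     then reduce to a handful of large matrix products.
//   conv weights    : cube C_in x F x k (one slice per kernel offset),
//                     zero "same" padding, stride 1
//   LSTM weights    : Wx (C_in x 4H), Wh (H x 4H), b (1 x 4H); gates i,f,g,o
//   attention       : additive scoring e_t = tanh(h_t W + b) v, softmax over
//                     time, context = sum_t a_t h_t
//
// Architectures:
//   "cla"  : conv -> conv -> LSTM(seq); one attention layer pools each conv
//            block's output and one pools the LSTM sequence; the three
//            contexts are concatenated into dense_1 (ReLU, the embedding)
//            and a sigmoid output unit.
//   "lstm" : LSTM over raw channels, last hidden state -> dense_1 -> sigmoid
//            (the no-convolution, no-attention baseline).
//
// The backward pass takes dL/dscore (post-sigmoid) and dL/dembedding so that
// losses operating on the embedding space (patient-invariance,
// unlabeled-separation) can inject gradients. A cached forward
// (cpp_nn_forward_cache / cpp_nn_backward_cache) lets the trainer compute
// loss gradients in R between the two passes without repeating the forward.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct AttCache {
  mat U;   // (L*B) x A
  mat a;   // B x L
  mat ctx; // B x D
};

struct Cache {
  std::string arch;
  uword B = 0, L = 0;
  mat Xb;                  // (L*B) x C
  mat Z1, A1, Z2, A2;      // conv blocks, (L*B) x F
  AttCache at1, at2, at3;
  mat Pl;                  // precomputed Xin*Wx + b, (L*B) x 4H
  mat Hs, Cs, Ig, Fg, Gg, Og;  // LSTM caches, (L*B) x H
  mat embed_in, Zd1, Emb;
  vec score;
};

static mat to_big(const cube& X) {
  const uword B = X.n_rows, C = X.n_cols, L = X.n_slices;
  mat Xb(L * B, C);
  for (uword t = 0; t < L; ++t) Xb.rows(t * B, t * B + B - 1) = X.slice(t);
  return Xb;
}

// ---------- convolution ----------

static mat conv_forward_big(const mat& Xb, const cube& W, const rowvec& b,
                            uword B, uword L) {
  const uword F = W.n_cols, k = W.n_slices;
  const int pad = (int(k) - 1) / 2;
  mat Z(L * B, F);
  Z.each_row() = b;
  for (uword d = 0; d < k; ++d) {
    int o = int(d) - pad;  // output t reads input t + o
    uword t0 = (o < 0) ? uword(-o) : 0;
    uword t1 = (o > 0) ? L - 1 - uword(o) : L - 1;
    if (t0 > t1) continue;
    Z.rows(t0 * B, (t1 + 1) * B - 1) +=
        Xb.rows((t0 + o) * B, (t1 + 1 + o) * B - 1) * W.slice(d);
  }
  return Z;
}

static void conv_backward_big(const mat& Xb, const cube& W, const mat& dZ,
                              cube& gW, rowvec& gb, mat* dX, uword B,
                              uword L) {
  const uword k = W.n_slices;
  const int pad = (int(k) - 1) / 2;
  gb = sum(dZ, 0);
  for (uword d = 0; d < k; ++d) {
    int o = int(d) - pad;
    uword t0 = (o < 0) ? uword(-o) : 0;
    uword t1 = (o > 0) ? L - 1 - uword(o) : L - 1;
    if (t0 > t1) continue;
    const uword oa = t0 * B, ob = (t1 + 1) * B - 1;
    const uword ia = (t0 + o) * B, ib = (t1 + 1 + o) * B - 1;
    gW.slice(d) = Xb.rows(ia, ib).t() * dZ.rows(oa, ob);
    if (dX) dX->rows(ia, ib) += dZ.rows(oa, ob) * W.slice(d).t();
  }
}

// ---------- attention ----------

static AttCache att_forward_big(const mat& Hb, const mat& W, const rowvec& b,
                                const vec& v, uword B, uword L) {
  AttCache o;
  o.U = tanh(Hb * W + repmat(b, Hb.n_rows, 1));
  vec evec = o.U * v;
  mat e = reshape(evec, B, L);
  vec mx = max(e, 1);
  mat ex = exp(e.each_col() - mx);
  o.a = ex.each_col() / sum(ex, 1);
  const uword D = Hb.n_cols;
  o.ctx.set_size(B, D);
  for (uword j = 0; j < D; ++j) {
    mat Hj = reshape(Hb.col(j), B, L);
    o.ctx.col(j) = sum(Hj % o.a, 1);
  }
  return o;
}

static void att_backward_big(const mat& Hb, const mat& W, const vec& v,
                             const AttCache& o, const mat& dctx, mat& dHb,
                             mat& gW, rowvec& gb, vec& gv, uword B, uword L) {
  const uword D = Hb.n_cols;
  mat dA(B, L, fill::zeros);
  for (uword j = 0; j < D; ++j) {
    mat Hj = reshape(Hb.col(j), B, L);
    dA += Hj.each_col() % dctx.col(j);
    mat dHj(B, L);
    dHj = o.a.each_col() % dctx.col(j);
    dHb.col(j) += vectorise(dHj);
  }
  vec srow = sum(o.a % dA, 1);
  mat de = o.a % (dA.each_col() - srow);
  vec devec = vectorise(de);
  mat dU = devec * v.t();
  mat dpre = dU % (1.0 - square(o.U));
  gW = Hb.t() * dpre;
  gb = sum(dpre, 0);
  gv = o.U.t() * devec;
  dHb += dpre * W.t();
}

// ---------- LSTM ----------

static void lstm_forward_big(Cache& c, const mat& Xb, const mat& Wx,
                             const mat& Wh, const rowvec& b) {
  const uword B = c.B, L = c.L, H = Wh.n_rows;
  c.Pl = Xb * Wx;
  c.Pl.each_row() += b;
  c.Hs.set_size(L * B, H); c.Cs.set_size(L * B, H);
  c.Ig.set_size(L * B, H); c.Fg.set_size(L * B, H);
  c.Gg.set_size(L * B, H); c.Og.set_size(L * B, H);
  mat h(B, H, fill::zeros), cc(B, H, fill::zeros);
  for (uword t = 0; t < L; ++t) {
    const uword r0 = t * B, r1 = t * B + B - 1;
    mat z = c.Pl.rows(r0, r1) + h * Wh;
    mat i = sigm(z.cols(0, H - 1));
    mat f = sigm(z.cols(H, 2 * H - 1));
    mat g = tanh(z.cols(2 * H, 3 * H - 1));
    mat o = sigm(z.cols(3 * H, 4 * H - 1));
    cc = f % cc + i % g;
    h = o % tanh(cc);
    c.Ig.rows(r0, r1) = i; c.Fg.rows(r0, r1) = f;
    c.Gg.rows(r0, r1) = g; c.Og.rows(r0, r1) = o;
    c.Cs.rows(r0, r1) = cc; c.Hs.rows(r0, r1) = h;
  }
}

static void lstm_backward_big(const Cache& c, const mat& Xb, const mat& Wx,
                              const mat& Wh, const mat& dHext, mat& dXin,
                              mat& gWx, mat& gWh, rowvec& gb) {
  const uword B = c.B, L = c.L, H = Wh.n_rows;
  mat dh(B, H, fill::zeros), dc(B, H, fill::zeros);
  mat dZb(L * B, 4 * H);
  gWh.zeros(H, 4 * H);
  for (uword tt = L; tt-- > 0;) {
    const uword r0 = tt * B, r1 = tt * B + B - 1;
    dh += dHext.rows(r0, r1);
    mat tc = tanh(c.Cs.rows(r0, r1));
    mat I = c.Ig.rows(r0, r1), Fv = c.Fg.rows(r0, r1),
        G = c.Gg.rows(r0, r1), O = c.Og.rows(r0, r1);
    mat dO = dh % tc;
    dc += dh % O % (1.0 - square(tc));
    mat cprev = (tt > 0) ? mat(c.Cs.rows(r0 - B, r0 - 1))
                         : mat(B, H, fill::zeros);
    mat dzi = (dc % G) % I % (1.0 - I);
    mat dzf = (dc % cprev) % Fv % (1.0 - Fv);
    mat dzg = (dc % I) % (1.0 - square(G));
    mat dzo = dO % O % (1.0 - O);
    mat dZ = join_rows(join_rows(dzi, dzf), join_rows(dzg, dzo));
    dZb.rows(r0, r1) = dZ;
    if (tt > 0) gWh += c.Hs.rows(r0 - B, r0 - 1).t() * dZ;
    dh = dZ * Wh.t();
    dc = dc % Fv;
  }
  gWx = Xb.t() * dZb;
  gb = sum(dZb, 0);
  dXin += dZb * Wx.t();
}

// ---------- full network ----------

static void forward_into(Cache& c, List params, std::string arch,
                         const cube& X) {
  c.arch = arch;
  c.B = X.n_rows; c.L = X.n_slices;
  c.Xb = to_big(X);
  mat Wd1 = as<mat>(params["d1_W"]);
  rowvec bd1 = as<rowvec>(params["d1_b"]);
  mat Wout = as<mat>(params["out_W"]);
  double bout = as<double>(params["out_b"]);
  mat Wx = as<mat>(params["lstm_Wx"]);
  mat Wh = as<mat>(params["lstm_Wh"]);
  rowvec bl = as<rowvec>(params["lstm_b"]);

  if (arch == "lstm") {
    lstm_forward_big(c, c.Xb, Wx, Wh, bl);
    mat hlast = c.Hs.rows((c.L - 1) * c.B, c.L * c.B - 1);
    c.embed_in = hlast;
  } else {
    cube W1 = as<cube>(params["conv1_W"]);
    rowvec b1 = as<rowvec>(params["conv1_b"]);
    cube W2 = as<cube>(params["conv2_W"]);
    rowvec b2 = as<rowvec>(params["conv2_b"]);
    c.Z1 = conv_forward_big(c.Xb, W1, b1, c.B, c.L);
    c.A1 = c.Z1; c.A1.elem(find(c.Z1 <= 0)).zeros();
    c.at1 = att_forward_big(c.A1, as<mat>(params["att1_W"]),
                            as<rowvec>(params["att1_b"]),
                            as<vec>(params["att1_v"]), c.B, c.L);
    c.Z2 = conv_forward_big(c.A1, W2, b2, c.B, c.L);
    c.A2 = c.Z2; c.A2.elem(find(c.Z2 <= 0)).zeros();
    c.at2 = att_forward_big(c.A2, as<mat>(params["att2_W"]),
                            as<rowvec>(params["att2_b"]),
                            as<vec>(params["att2_v"]), c.B, c.L);
    lstm_forward_big(c, c.A2, Wx, Wh, bl);
    c.at3 = att_forward_big(c.Hs, as<mat>(params["att3_W"]),
                            as<rowvec>(params["att3_b"]),
                            as<vec>(params["att3_v"]), c.B, c.L);
    c.embed_in = join_rows(join_rows(c.at1.ctx, c.at2.ctx), c.at3.ctx);
  }
  c.Zd1 = c.embed_in * Wd1 + repmat(bd1, c.B, 1);
  c.Emb = c.Zd1; c.Emb.elem(find(c.Zd1 <= 0)).zeros();
  vec z = c.Emb * Wout + bout;
  c.score = 1.0 / (1.0 + exp(-z));
}

static List forward_out(const Cache& c) {
  List out;
  out["score"] = c.score;
  out["embed"] = c.Emb;
  if (c.arch == "lstm") {
    out["att"] = cube(c.B, c.L, 0);
  } else {
    cube att(c.B, c.L, 3);
    att.slice(0) = c.at1.a; att.slice(1) = c.at2.a; att.slice(2) = c.at3.a;
    out["att"] = att;
  }
  return out;
}

static List backward_from(const Cache& c, List params, const vec& dscore,
                          const mat& demb) {
  mat Wd1 = as<mat>(params["d1_W"]);
  mat Wout = as<mat>(params["out_W"]);
  mat Wx = as<mat>(params["lstm_Wx"]);
  mat Wh = as<mat>(params["lstm_Wh"]);
  const uword B = c.B, L = c.L, Hn = Wh.n_rows;

  vec dz = dscore % c.score % (1.0 - c.score);
  mat gWout = c.Emb.t() * dz;
  double gbout = accu(dz);
  mat dEmb = demb + dz * Wout.t();
  mat dZd1 = dEmb; dZd1.elem(find(c.Zd1 <= 0)).zeros();
  mat gWd1 = c.embed_in.t() * dZd1;
  rowvec gbd1 = sum(dZd1, 0);
  mat dembed_in = dZd1 * Wd1.t();

  if (c.arch == "lstm") {
    mat dHext(L * B, Hn, fill::zeros);
    dHext.rows((L - 1) * B, L * B - 1) = dembed_in;
    mat dXin(L * B, c.Xb.n_cols, fill::zeros);
    mat gWx, gWh; rowvec gbl;
    lstm_backward_big(c, c.Xb, Wx, Wh, dHext, dXin, gWx, gWh, gbl);
    return List::create(
        _["lstm_Wx"] = gWx, _["lstm_Wh"] = gWh, _["lstm_b"] = gbl,
        _["d1_W"] = gWd1, _["d1_b"] = gbd1, _["out_W"] = gWout,
        _["out_b"] = gbout);
  }

  cube W1 = as<cube>(params["conv1_W"]);
  cube W2 = as<cube>(params["conv2_W"]);
  mat Wa1 = as<mat>(params["att1_W"]); vec va1 = as<vec>(params["att1_v"]);
  mat Wa2 = as<mat>(params["att2_W"]); vec va2 = as<vec>(params["att2_v"]);
  mat Wa3 = as<mat>(params["att3_W"]); vec va3 = as<vec>(params["att3_v"]);
  const uword F = W1.n_cols;

  mat dctx1 = dembed_in.cols(0, F - 1);
  mat dctx2 = dembed_in.cols(F, 2 * F - 1);
  mat dctx3 = dembed_in.cols(2 * F, 2 * F + Hn - 1);

  mat dA1(L * B, F, fill::zeros), dA2(L * B, F, fill::zeros);
  mat dHs(L * B, Hn, fill::zeros);
  mat gWa1, gWa2, gWa3; rowvec gba1, gba2, gba3; vec gva1, gva2, gva3;
  att_backward_big(c.A1, Wa1, va1, c.at1, dctx1, dA1, gWa1, gba1, gva1, B, L);
  att_backward_big(c.A2, Wa2, va2, c.at2, dctx2, dA2, gWa2, gba2, gva2, B, L);
  att_backward_big(c.Hs, Wa3, va3, c.at3, dctx3, dHs, gWa3, gba3, gva3, B, L);

  mat gWx, gWh; rowvec gbl;
  lstm_backward_big(c, c.A2, Wx, Wh, dHs, dA2, gWx, gWh, gbl);

  mat dZ2 = dA2; dZ2.elem(find(c.Z2 <= 0)).zeros();
  cube gW2(size(W2), fill::zeros); rowvec gb2;
  conv_backward_big(c.A1, W2, dZ2, gW2, gb2, &dA1, B, L);

  mat dZ1 = dA1; dZ1.elem(find(c.Z1 <= 0)).zeros();
  cube gW1(size(W1), fill::zeros); rowvec gb1;
  conv_backward_big(c.Xb, W1, dZ1, gW1, gb1, nullptr, B, L);

  return List::create(
      _["conv1_W"] = gW1, _["conv1_b"] = gb1, _["conv2_W"] = gW2,
      _["conv2_b"] = gb2, _["att1_W"] = gWa1, _["att1_b"] = gba1,
      _["att1_v"] = gva1, _["att2_W"] = gWa2, _["att2_b"] = gba2,
      _["att2_v"] = gva2, _["lstm_Wx"] = gWx, _["lstm_Wh"] = gWh,
      _["lstm_b"] = gbl, _["att3_W"] = gWa3, _["att3_b"] = gba3,
      _["att3_v"] = gva3, _["d1_W"] = gWd1, _["d1_b"] = gbd1,
      _["out_W"] = gWout, _["out_b"] = gbout);
}

// [[Rcpp::export]]
List cpp_nn_forward(List params, std::string arch, arma::cube X) {
  Cache c;
  forward_into(c, params, arch, X);
  return forward_out(c);
}

// [[Rcpp::export]]
List cpp_nn_forward_cache(List params, std::string arch, arma::cube X) {
  XPtr<Cache> ptr(new Cache(), true);
  forward_into(*ptr, params, arch, X);
  List out = forward_out(*ptr);
  out["cache"] = ptr;
  return out;
}

// [[Rcpp::export]]
List cpp_nn_backward_cache(SEXP cache, List params, arma::vec dscore,
                           arma::mat demb) {
  XPtr<Cache> ptr(cache);
  return backward_from(*ptr, params, dscore, demb);
}

// [[Rcpp::export]]
List cpp_nn_grad(List params, std::string arch, arma::cube X,
                 arma::vec dscore, arma::mat demb) {
  Cache c;
  forward_into(c, params, arch, X);
  List out = forward_out(c);
  out["grads"] = backward_from(c, params, dscore, demb);
  return out;
}

// Dynamic time warping with unit steps, absolute-difference local cost,
// no window, no normalization.
// [[Rcpp::export]]
double cpp_dtw(arma::vec a, arma::vec b) {
  const uword n = a.n_elem, m = b.n_elem;
  vec prev(m + 1, fill::value(datum::inf)), cur(m + 1);
  prev(0) = 0.0;
  for (uword i = 1; i <= n; ++i) {
    cur.fill(datum::inf);
    for (uword j = 1; j <= m; ++j) {
      double c = std::abs(a(i - 1) - b(j - 1));
      cur(j) = c + std::min(std::min(prev(j), cur(j - 1)), prev(j - 1));
    }
    prev = cur;
  }
  return prev(m);
}
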