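// Batched two-layer LSTM used by the sliding-window VCG synthesizer.
// Windows of the (standardized) lead-I series are presented as length-L
// sequences of scalars; the final hidden state of the top layer is
// linearly projected to the three Frank-lead targets.  Forward pass and
// full backpropagation-through-time gradients are computed here; the
// optimizer loop lives in R.
//
// For speed the four gate blocks (f, i, c-candidate, o) are stacked into
// single 4H x D / 4H x H matrices so each time step costs a handful of
// large GEMMs instead of dozens of small ones.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat sigm(const arma::mat& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

struct Layer {
  arma::mat W, U;   // 4H x D, 4H x H (rows: f, i, c, o blocks)
  arma::vec b;      // 4H
  arma::uword H;
};

static Layer pack_layer(const List& l) {
  Layer w;
  w.W = arma::join_cols(arma::join_cols(as<arma::mat>(l["Wf"]),
                                        as<arma::mat>(l["Wi"])),
                        arma::join_cols(as<arma::mat>(l["Wc"]),
                                        as<arma::mat>(l["Wo"])));
  w.U = arma::join_cols(arma::join_cols(as<arma::mat>(l["Uf"]),
                                        as<arma::mat>(l["Ui"])),
                        arma::join_cols(as<arma::mat>(l["Uc"]),
                                        as<arma::mat>(l["Uo"])));
  w.b = arma::join_cols(arma::join_cols(as<arma::vec>(l["bf"]),
                                        as<arma::vec>(l["bi"])),
                        arma::join_cols(as<arma::vec>(l["bc"]),
                                        as<arma::vec>(l["bo"])));
  w.H = as<arma::vec>(l["bf"]).n_elem;
  return w;
}

// Gate activations for one step.  Z: 4H x B pre-activations (overwritten
// with activated gates: sigmoid on f/i/o rows, tanh on c rows).
static void activate(arma::mat& Z, arma::uword H) {
  Z.rows(0, 2 * H - 1) = sigm(Z.rows(0, 2 * H - 1));
  Z.rows(2 * H, 3 * H - 1) = arma::tanh(Z.rows(2 * H, 3 * H - 1));
  Z.rows(3 * H, 4 * H - 1) = sigm(Z.rows(3 * H, 4 * H - 1));
}

// Predictions for windows ending at `ends` (1-based indices into x).
// Returns a B x 3 matrix.
// [[Rcpp::export]]
arma::mat cpp_lstm_forward(List layers, const arma::mat& Wout,
                           const arma::vec& bout, const arma::vec& x,
                           const arma::uvec& ends, int L) {
  const int nl = layers.size();
  std::vector<Layer> W(nl);
  for (int l = 0; l < nl; ++l) W[l] = pack_layer(layers[l]);
  const arma::uword B = ends.n_elem;
  std::vector<arma::mat> h(nl), c(nl);
  for (int l = 0; l < nl; ++l) {
    h[l].zeros(W[l].H, B);
    c[l].zeros(W[l].H, B);
  }
  arma::mat in, Z;
  for (int s = 0; s < L; ++s) {
    arma::uvec idx = ends - (L - 1 - s) - 1;  // 0-based sample indices
    in = x.elem(idx).t();                     // 1 x B
    for (int l = 0; l < nl; ++l) {
      const arma::uword H = W[l].H;
      Z = W[l].W * in + W[l].U * h[l];
      Z.each_col() += W[l].b;
      activate(Z, H);
      c[l] = Z.rows(0, H - 1) % c[l] +
             Z.rows(H, 2 * H - 1) % Z.rows(2 * H, 3 * H - 1);
      h[l] = Z.rows(3 * H, 4 * H - 1) % arma::tanh(c[l]);
      in = h[l];
    }
  }
  arma::mat pred = Wout * h[nl - 1];
  pred.each_col() += bout;
  return pred.t();
}

// Mean-squared-error loss over a batch of windows and its gradients with
// respect to every parameter.  Y: B x 3 targets.
// [[Rcpp::export]]
List cpp_lstm_loss_grad(List layers, const arma::mat& Wout,
                        const arma::vec& bout, const arma::vec& x,
                        const arma::mat& Y, const arma::uvec& ends, int L) {
  const int nl = layers.size();
  std::vector<Layer> W(nl);
  for (int l = 0; l < nl; ++l) W[l] = pack_layer(layers[l]);
  const arma::uword B = ends.n_elem;

  // stored per layer, per step: activated gate stack G (4H x B), cell C
  std::vector<std::vector<arma::mat>> G(nl), C(nl), Hs(nl);
  std::vector<arma::mat> ins(L);
  std::vector<arma::mat> h(nl), c(nl);
  for (int l = 0; l < nl; ++l) {
    h[l].zeros(W[l].H, B);
    c[l].zeros(W[l].H, B);
    G[l].resize(L); C[l].resize(L); Hs[l].resize(L);
  }
  arma::mat in, Z;
  for (int s = 0; s < L; ++s) {
    arma::uvec idx = ends - (L - 1 - s) - 1;
    in = x.elem(idx).t();
    ins[s] = in;
    for (int l = 0; l < nl; ++l) {
      const arma::uword H = W[l].H;
      Z = W[l].W * in + W[l].U * h[l];
      Z.each_col() += W[l].b;
      activate(Z, H);
      c[l] = Z.rows(0, H - 1) % c[l] +
             Z.rows(H, 2 * H - 1) % Z.rows(2 * H, 3 * H - 1);
      h[l] = Z.rows(3 * H, 4 * H - 1) % arma::tanh(c[l]);
      G[l][s] = Z; C[l][s] = c[l]; Hs[l][s] = h[l];
      in = h[l];
    }
  }
  arma::mat pred = Wout * h[nl - 1];
  pred.each_col() += bout;
  arma::mat err = pred - Y.t();
  const double loss = arma::accu(arma::square(err)) / (3.0 * B);
  arma::mat dpred = 2.0 * err / (3.0 * B);

  arma::mat gWout = dpred * h[nl - 1].t();
  arma::vec gbout = arma::sum(dpred, 1);

  std::vector<arma::mat> gW(nl), gU(nl);
  std::vector<arma::vec> gb(nl);
  std::vector<arma::mat> dh(nl), dc(nl);
  for (int l = 0; l < nl; ++l) {
    gW[l].zeros(arma::size(W[l].W));
    gU[l].zeros(arma::size(W[l].U));
    gb[l].zeros(W[l].b.n_elem);
    dh[l].zeros(arma::size(h[l]));
    dc[l].zeros(arma::size(c[l]));
  }
  dh[nl - 1] = Wout.t() * dpred;

  arma::mat dZ;
  for (int s = L - 1; s >= 0; --s) {
    for (int l = nl - 1; l >= 0; --l) {
      const arma::uword H = W[l].H;
      const arma::mat& Gs = G[l][s];
      auto f  = Gs.rows(0, H - 1);
      auto ii = Gs.rows(H, 2 * H - 1);
      auto cb = Gs.rows(2 * H, 3 * H - 1);
      auto o  = Gs.rows(3 * H, 4 * H - 1);
      arma::mat tanhc = arma::tanh(C[l][s]);
      arma::mat dO = dh[l] % tanhc;
      arma::mat dC = dc[l] + dh[l] % o % (1.0 - tanhc % tanhc);
      dZ.set_size(4 * H, B);
      if (s > 0) dZ.rows(0, H - 1) = dC % C[l][s - 1] % f % (1.0 - f);
      else       dZ.rows(0, H - 1).zeros();
      dZ.rows(H, 2 * H - 1) = dC % cb % ii % (1.0 - ii);
      dZ.rows(2 * H, 3 * H - 1) = dC % ii % (1.0 - cb % cb);
      dZ.rows(3 * H, 4 * H - 1) = dO % o % (1.0 - o);

      const arma::mat& inp = (l == 0) ? ins[s] : Hs[l - 1][s];
      gW[l] += dZ * inp.t();
      if (s > 0) gU[l] += dZ * Hs[l][s - 1].t();
      gb[l] += arma::sum(dZ, 1);

      dh[l] = W[l].U.t() * dZ;     // carry to step s-1 of this layer
      dc[l] = dC % f;
      if (l > 0) dh[l - 1] += W[l].W.t() * dZ;
    }
  }

  List glayers(nl);
  for (int l = 0; l < nl; ++l) {
    const arma::uword H = W[l].H;
    glayers[l] = List::create(
        _["Wf"] = gW[l].rows(0, H - 1),
        _["Wi"] = gW[l].rows(H, 2 * H - 1),
        _["Wc"] = gW[l].rows(2 * H, 3 * H - 1),
        _["Wo"] = gW[l].rows(3 * H, 4 * H - 1),
        _["Uf"] = gU[l].rows(0, H - 1),
        _["Ui"] = gU[l].rows(H, 2 * H - 1),
        _["Uc"] = gU[l].rows(2 * H, 3 * H - 1),
        _["Uo"] = gU[l].rows(3 * H, 4 * H - 1),
        _["bf"] = arma::vec(gb[l].subvec(0, H - 1)),
        _["bi"] = arma::vec(gb[l].subvec(H, 2 * H - 1)),
        _["bc"] = arma::vec(gb[l].subvec(2 * H, 3 * H - 1)),
        _["bo"] = arma::vec(gb[l].subvec(3 * H, 4 * H - 1)));
  }
  return List::create(_["loss"] = loss,
                      _["layers"] = glayers,
                      _["Wout"] = gWout, _["bout"] = gbout);
}
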