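// Sequence-to-sequence recurrent stack: bidirectional/unidirectional LSTM
// layers and time-distributed linear (fully connected) layers, with
// back-propagation through time. The gated cell follows the standard LSTM
// forward pass: forget/input/output gates with logistic sigmoid, candidate
// and output squashing with tanh,
//   f_t = sig(Wf [h_{t-1}, x_t] + bf)
//   i_t = sig(Wi [h_{t-1}, x_t] + bi)
//   g_t = tanh(Wc [h_{t-1}, x_t] + bc)
//   C_t = f_t * C_{t-1} + i_t * g_t
//   o_t = sig(Wo [h_{t-1}, x_t] + bo)
//   h_t = o_t * tanh(C_t)
// All four gate blocks are stored in one weight matrix W (4H x (I+H)),
// rows ordered [i; f; g; o], columns [x; h_prev].
//
// Sequences are processed in mini-batches: a batch is a cube I x B x T
// (features x sequences x time), so each timestep is one dense B-column
// matrix product.
//
// Dropout is applied only to non-recurrent connections: the activations
// passed between layers, never the recurrent state.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

struct LstmCache {
  cube gates;   // 4H x B x T, activated [i; f; g; o]
  cube C;       // H x B x T cell states
  cube H;       // H x B x T outputs
};

// Forward pass of one unidirectional LSTM over a batch cube (I x B x T).
LstmCache lstm_forward(const mat& W, const vec& b, const cube& X) {
  const uword I = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = W.n_rows / 4;
  LstmCache cc;
  cc.gates.set_size(4 * H, B, T);
  cc.C.set_size(H, B, T);
  cc.H.set_size(H, B, T);
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  mat xin(I + H, B);
  for (uword t = 0; t < T; ++t) {
    xin.rows(0, I - 1) = X.slice(t);
    xin.rows(I, I + H - 1) = h;
    mat z = W * xin;
    z.each_col() += b;
    mat gi = sigmoid(z.rows(0, H - 1));
    mat gf = sigmoid(z.rows(H, 2 * H - 1));
    mat gg = tanh(z.rows(2 * H, 3 * H - 1));
    mat go = sigmoid(z.rows(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    cc.gates.slice(t).rows(0, H - 1) = gi;
    cc.gates.slice(t).rows(H, 2 * H - 1) = gf;
    cc.gates.slice(t).rows(2 * H, 3 * H - 1) = gg;
    cc.gates.slice(t).rows(3 * H, 4 * H - 1) = go;
    cc.C.slice(t) = c;
    cc.H.slice(t) = h;
  }
  return cc;
}

// BPTT through one unidirectional LSTM. dH is the gradient w.r.t. the layer
// outputs. Returns gradient w.r.t. the inputs; accumulates dW, db.
cube lstm_backward(const mat& W, const cube& X, const LstmCache& cc,
                   const cube& dH, mat& dW, vec& db) {
  const uword I = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = W.n_rows / 4;
  dW.zeros(4 * H, I + H);
  db.zeros(4 * H);
  cube dX(I, B, T);
  mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  mat xin(I + H, B), dz(4 * H, B);
  for (uword t = T; t-- > 0;) {
    const mat gi = cc.gates.slice(t).rows(0, H - 1);
    const mat gf = cc.gates.slice(t).rows(H, 2 * H - 1);
    const mat gg = cc.gates.slice(t).rows(2 * H, 3 * H - 1);
    const mat go = cc.gates.slice(t).rows(3 * H, 4 * H - 1);
    const mat tc = tanh(cc.C.slice(t));
    mat c_prev = (t == 0) ? mat(H, B, fill::zeros) : mat(cc.C.slice(t - 1));
    mat h_prev = (t == 0) ? mat(H, B, fill::zeros) : mat(cc.H.slice(t - 1));

    mat dh = dH.slice(t) + dh_next;
    mat dc = dc_next + dh % go % (1.0 - tc % tc);
    mat d_go = dh % tc;
    mat d_gi = dc % gg;
    mat d_gg = dc % gi;
    mat d_gf = dc % c_prev;
    dc_next = dc % gf;

    dz.rows(0, H - 1) = d_gi % gi % (1.0 - gi);
    dz.rows(H, 2 * H - 1) = d_gf % gf % (1.0 - gf);
    dz.rows(2 * H, 3 * H - 1) = d_gg % (1.0 - gg % gg);
    dz.rows(3 * H, 4 * H - 1) = d_go % go % (1.0 - go);

    xin.rows(0, I - 1) = X.slice(t);
    xin.rows(I, I + H - 1) = h_prev;
    dW += dz * xin.t();
    db += sum(dz, 1);
    mat dxin = W.t() * dz;
    dX.slice(t) = dxin.rows(0, I - 1);
    dh_next = dxin.rows(I, I + H - 1);
  }
  return dX;
}

inline cube reverse_time(const cube& X) {
  cube out(X.n_rows, X.n_cols, X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t) out.slice(t) = X.slice(X.n_slices - 1 - t);
  return out;
}

struct LayerCache {
  std::string type;
  cube input;          // post-dropout input seen by the layer
  cube mask;           // dropout mask applied to this layer's input (or empty)
  LstmCache fwd, bwd;  // bwd used by blstm only
  cube output;
};

struct StackGrads {
  std::vector<Rcpp::List> layers;
};

cube apply_fc(const mat& W, const vec& b, const cube& X) {
  cube Y(W.n_rows, X.n_cols, X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t) {
    Y.slice(t) = W * X.slice(t);
    Y.slice(t).each_col() += b;
  }
  return Y;
}

// Forward through the whole stack. When training, dropout masks are drawn
// for the inputs of every layer after the first.
std::vector<LayerCache> stack_forward(const Rcpp::List& params,
                                      const std::vector<std::string>& types,
                                      const cube& X, double dropout_p,
                                      bool training, uint64_t seed) {
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<LayerCache> caches(types.size());
  cube cur = X;
  for (size_t l = 0; l < types.size(); ++l) {
    LayerCache& lc = caches[l];
    lc.type = types[l];
    if (training && dropout_p > 0.0 && l > 0) {
      lc.mask.set_size(cur.n_rows, cur.n_cols, cur.n_slices);
      const double keep = 1.0 - dropout_p;
      for (uword k = 0; k < lc.mask.n_elem; ++k) {
        lc.mask(k) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
      }
      cur = cur % lc.mask;
    }
    lc.input = cur;
    Rcpp::List pl = params[l];
    if (lc.type == "lstm") {
      mat W = pl["W"]; vec b = pl["b"];
      lc.fwd = lstm_forward(W, b, cur);
      lc.output = lc.fwd.H;
    } else if (lc.type == "blstm") {
      mat Wf = pl["Wf"]; vec bf = pl["bf"];
      mat Wb = pl["Wb"]; vec bb = pl["bb"];
      lc.fwd = lstm_forward(Wf, bf, cur);
      cube Xr = reverse_time(cur);
      lc.bwd = lstm_forward(Wb, bb, Xr);
      cube Hb = reverse_time(lc.bwd.H);
      const uword H = lc.fwd.H.n_rows;
      lc.output.set_size(2 * H, cur.n_cols, cur.n_slices);
      for (uword t = 0; t < cur.n_slices; ++t) {
        lc.output.slice(t).rows(0, H - 1) = lc.fwd.H.slice(t);
        lc.output.slice(t).rows(H, 2 * H - 1) = Hb.slice(t);
      }
    } else if (lc.type == "fc") {
      mat W = pl["W"]; vec b = pl["b"];
      lc.output = apply_fc(W, b, cur);
    } else {
      Rcpp::stop("unknown layer type '%s'", lc.type.c_str());
    }
    cur = lc.output;
  }
  return caches;
}

} // namespace

// [[Rcpp::export]]
arma::cube cpp_dann_forward(Rcpp::List params, std::vector<std::string> types,
                            arma::cube X) {
  std::vector<LayerCache> caches =
      stack_forward(params, types, X, 0.0, false, 0);
  return caches.back().output;
}

// Forward + BPTT backward pass with mean-squared-error loss over all
// components, sequences and timesteps. Returns the loss and per-layer
// gradients (same naming as the parameter list).
// [[Rcpp::export]]
Rcpp::List cpp_dann_grad(Rcpp::List params, std::vector<std::string> types,
                         arma::cube X, arma::cube Y, double dropout_p,
                         double seed) {
  std::vector<LayerCache> caches =
      stack_forward(params, types, X, dropout_p, true, (uint64_t) seed);
  const cube& Yhat = caches.back().output;
  const double n = (double) Yhat.n_elem;
  cube diff = Yhat - Y;
  double loss = accu(diff % diff) / n;
  if (!std::isfinite(loss)) {
    Rcpp::stop("non-finite training loss");
  }
  cube dOut = (2.0 / n) * diff;

  Rcpp::List grads(types.size());
  for (size_t li = types.size(); li-- > 0;) {
    LayerCache& lc = caches[li];
    Rcpp::List pl = params[li];
    cube dIn;
    if (lc.type == "fc") {
      mat W = pl["W"];
      mat dW(W.n_rows, W.n_cols, fill::zeros);
      vec db(W.n_rows, fill::zeros);
      dIn.set_size(lc.input.n_rows, lc.input.n_cols, lc.input.n_slices);
      for (uword t = 0; t < lc.input.n_slices; ++t) {
        dW += dOut.slice(t) * lc.input.slice(t).t();
        db += sum(dOut.slice(t), 1);
        dIn.slice(t) = W.t() * dOut.slice(t);
      }
      grads[li] = Rcpp::List::create(Rcpp::Named("W") = dW,
                                     Rcpp::Named("b") = db);
    } else if (lc.type == "lstm") {
      mat W = pl["W"];
      mat dW; vec db;
      dIn = lstm_backward(W, lc.input, lc.fwd, dOut, dW, db);
      grads[li] = Rcpp::List::create(Rcpp::Named("W") = dW,
                                     Rcpp::Named("b") = db);
    } else { // blstm
      mat Wf = pl["Wf"], Wb = pl["Wb"];
      const uword H = lc.fwd.H.n_rows;
      cube dHf(H, dOut.n_cols, dOut.n_slices);
      cube dHb(H, dOut.n_cols, dOut.n_slices);
      for (uword t = 0; t < dOut.n_slices; ++t) {
        dHf.slice(t) = dOut.slice(t).rows(0, H - 1);
        dHb.slice(t) = dOut.slice(t).rows(H, 2 * H - 1);
      }
      mat dWf; vec dbf;
      cube dIn_f = lstm_backward(Wf, lc.input, lc.fwd, dHf, dWf, dbf);
      cube Xr = reverse_time(lc.input);
      mat dWb; vec dbb;
      cube dIn_b = lstm_backward(Wb, Xr, lc.bwd, reverse_time(dHb), dWb, dbb);
      dIn = dIn_f + reverse_time(dIn_b);
      grads[li] = Rcpp::List::create(
          Rcpp::Named("Wf") = dWf, Rcpp::Named("bf") = dbf,
          Rcpp::Named("Wb") = dWb, Rcpp::Named("bb") = dbb);
    }
    if (!lc.mask.is_empty()) dIn %= lc.mask;
    dOut = dIn;
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}
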