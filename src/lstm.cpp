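// LSTM recurrent network core: forward pass over beat sequences, focal /
// cross-entropy loss, and exact backpropagation through time.
//
// Cell equations (peephole-style gate inputs; u_t = [a_{t-1}; x_t; c_{t-1}]):
//   f_t = sigmoid(W_f u_t + b_f)
//   i_t = sigmoid(W_i u_t + b_i)
//   c_in = tanh(W_c u_t + b_c)
//   c_t = f_t . c_{t-1} + i_t . c_in
//   o_t = sigmoid(W_o u_t + b_o)
//   a_t = o_t . tanh(c_t)
// With peephole = false the c_{t-1} block of u_t is zeroed (standard LSTM).
// Head: h = a_T (optionally masked by inverted dropout), FC1 + ReLU, FC2
// linear, softmax. Per-example loss on the true-class probability p:
//   CE = -log(p),  FL = -(1-p)^gamma log(p),  p clamped at 1e-12.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

static mat softmax_cols(const mat& z) {
  mat s = z.each_row() - max(z, 0);
  s = exp(s);
  s.each_row() /= sum(s, 0);
  return s;
}

// dL/dp for the per-example loss at true-class probability pt.
static double loss_dp(double pt, double gamma, bool focal) {
  double pc = std::max(pt, 1e-12);
  if (!focal || gamma == 0.0) return -1.0 / pc;
  if (pt >= 1.0) return 0.0;
  return gamma * std::pow(1.0 - pt, gamma - 1.0) * std::log(pc)
         - std::pow(1.0 - pt, gamma) / pc;
}

static double loss_value(double pt, double gamma, bool focal) {
  double pc = std::max(pt, 1e-12);
  double ce = -std::log(pc);
  if (!focal || gamma == 0.0) return ce;
  return std::pow(1.0 - pt, gamma) * ce;
}

// [[Rcpp::export(name = ".lstm_batch_cpp")]]
Rcpp::List lstm_batch_cpp(Rcpp::List params, const arma::mat& Xt,
                          const arma::ivec& y, double gamma, bool focal,
                          bool peephole, const arma::mat& drop_mask,
                          bool want_grad) {
  const mat Wf = params["W_f"], Wi = params["W_i"], Wc = params["W_c"],
            Wo = params["W_o"];
  const vec bf = params["b_f"], bi = params["b_i"], bc = params["b_c"],
            bo = params["b_o"];
  const mat W1 = params["W_fc1"], W2 = params["W_fc2"];
  const vec b1 = params["b_fc1"], b2 = params["b_fc2"];

  const uword T = Xt.n_rows, B = Xt.n_cols;
  const uword H = Wf.n_rows, H1 = W1.n_rows, C = W2.n_rows;
  if (Wf.n_cols != 2 * H + 1)
    Rcpp::stop("gate matrices must have 2H+1 columns (per-step input size 1)");
  const bool masked = drop_mask.n_elem > 0;
  const bool have_y = y.n_elem == B && B > 0;

  mat a(H, B, fill::zeros), c(H, B, fill::zeros);
  cube Fg, Ig, Gg, Og, Cs, Ap;
  if (want_grad) {
    Fg.set_size(H, B, T); Ig.set_size(H, B, T); Gg.set_size(H, B, T);
    Og.set_size(H, B, T); Cs.set_size(H, B, T); Ap.set_size(H, B, T);
  }

  mat u(2 * H + 1, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    u.rows(0, H - 1) = a;
    u.row(H) = Xt.row(t);
    if (peephole) u.rows(H + 1, 2 * H) = c; else u.rows(H + 1, 2 * H).zeros();
    mat f = sigmoid(Wf * u + repmat(bf, 1, B));
    mat i = sigmoid(Wi * u + repmat(bi, 1, B));
    mat g = tanh(Wc * u + repmat(bc, 1, B));
    mat o = sigmoid(Wo * u + repmat(bo, 1, B));
    if (want_grad) Ap.slice(t) = a;
    c = f % c + i % g;
    a = o % tanh(c);
    if (want_grad) {
      Fg.slice(t) = f; Ig.slice(t) = i; Gg.slice(t) = g; Og.slice(t) = o;
      Cs.slice(t) = c;
    }
  }

  mat h = a;
  if (masked) h %= drop_mask;
  mat z1 = W1 * h + repmat(b1, 1, B);
  mat r1 = clamp(z1, 0.0, datum::inf);               // ReLU
  mat z = W2 * r1 + repmat(b2, 1, B);
  mat p = softmax_cols(z);

  double loss = NA_REAL;
  if (have_y) {
    loss = 0.0;
    for (uword j = 0; j < B; ++j) loss += loss_value(p(y[j], j), gamma, focal);
    loss /= B;
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("prob") = p.t(), Rcpp::Named("logits") = z.t(),
    Rcpp::Named("loss") = loss, Rcpp::Named("hidden") = a.t());
  if (!want_grad) return out;
  if (!have_y) Rcpp::stop("gradients require labels");

  // ---- backward ----
  mat dZ(C, B, fill::zeros);
  for (uword j = 0; j < B; ++j) {
    double pt = p(y[j], j);
    double dldp = loss_dp(pt, gamma, focal);
    vec col = -pt * p.col(j);
    col(y[j]) += pt;
    dZ.col(j) = (dldp / double(B)) * col;
  }
  mat dW2 = dZ * r1.t();
  vec db2 = sum(dZ, 1);
  mat dr1 = W2.t() * dZ;
  dr1 %= conv_to<mat>::from(z1 > 0.0);
  mat dW1 = dr1 * h.t();
  vec db1 = sum(dr1, 1);
  mat dh = W1.t() * dr1;
  if (masked) dh %= drop_mask;

  mat da = dh, dc(H, B, fill::zeros);
  mat dWf(size(Wf), fill::zeros), dWi(size(Wi), fill::zeros),
      dWc(size(Wc), fill::zeros), dWo(size(Wo), fill::zeros);
  vec dbf(H, fill::zeros), dbi(H, fill::zeros), dbc(H, fill::zeros),
      dbo(H, fill::zeros);

  for (uword t = T; t-- > 0;) {
    const mat& f = Fg.slice(t); const mat& i = Ig.slice(t);
    const mat& g = Gg.slice(t); const mat& o = Og.slice(t);
    mat c_prev = (t > 0) ? Cs.slice(t - 1) : mat(H, B, fill::zeros);
    mat tc = tanh(Cs.slice(t));

    mat dzo = (da % tc) % o % (1.0 - o);
    dc += da % o % (1.0 - tc % tc);
    mat dzf = (dc % c_prev) % f % (1.0 - f);
    mat dzi = (dc % g) % i % (1.0 - i);
    mat dzc = (dc % i) % (1.0 - g % g);

    u.rows(0, H - 1) = Ap.slice(t);
    u.row(H) = Xt.row(t);
    if (peephole) u.rows(H + 1, 2 * H) = c_prev;
    else u.rows(H + 1, 2 * H).zeros();

    dWf += dzf * u.t(); dbf += sum(dzf, 1);
    dWi += dzi * u.t(); dbi += sum(dzi, 1);
    dWc += dzc * u.t(); dbc += sum(dzc, 1);
    dWo += dzo * u.t(); dbo += sum(dzo, 1);

    mat du = Wf.t() * dzf + Wi.t() * dzi + Wc.t() * dzc + Wo.t() * dzo;
    da = du.rows(0, H - 1);
    dc %= f;
    if (peephole) dc += du.rows(H + 1, 2 * H);
  }

  out["grads"] = Rcpp::List::create(
    Rcpp::Named("W_f") = dWf, Rcpp::Named("W_i") = dWi,
    Rcpp::Named("W_c") = dWc, Rcpp::Named("W_o") = dWo,
    Rcpp::Named("b_f") = dbf, Rcpp::Named("b_i") = dbi,
    Rcpp::Named("b_c") = dbc, Rcpp::Named("b_o") = dbo,
    Rcpp::Named("W_fc1") = dW1, Rcpp::Named("b_fc1") = db1,
    Rcpp::Named("W_fc2") = dW2, Rcpp::Named("b_fc2") = db2);
  return out;
}
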