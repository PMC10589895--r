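// Recurrent path-integration network: forward pass and one BPTT/Adam
// training step. Layout conventions (column-major, batch in columns):
//   p0:     Np x B   initial place-cell activity
//   v:      cube (B, T, 2)  Cartesian velocities (as passed from R)
//   labels: cube (Np, B, T) target place-cell activity
//   g:      cube (Ng, B, T) recurrent states, phat: cube (Np, B, T)
// The model has no bias terms anywhere.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// column-wise softmax with log-sum-exp stabilisation
static mat softmax_cols(const mat& u, mat* logp = nullptr) {
  rowvec m = max(u, 0);
  mat e = exp(u.each_row() - m);
  rowvec s = sum(e, 0);
  if (logp) {
    rowvec lse = m + log(s);
    *logp = u.each_row() - lse;
  }
  return e.each_row() / s;
}

struct ForwardPass {
  cube g;     // Ng x B x T
  cube phat;  // Np x B x T
  cube logp;  // Np x B x T
  mat g0;     // Ng x B
};

static ForwardPass run_forward(const mat& We, const mat& Wg, const mat& Wv,
                               const mat& Wd, const mat& p0, const cube& v) {
  const uword Ng = Wg.n_rows, Np = Wd.n_rows;
  const uword B = p0.n_cols, T = v.n_cols;
  ForwardPass fp;
  fp.g.set_size(Ng, B, T);
  fp.phat.set_size(Np, B, T);
  fp.logp.set_size(Np, B, T);
  fp.g0 = We * p0;  // linear initial state (no ReLU)
  mat gprev = fp.g0;
  const mat vx = v.slice(0);  // B x T
  const mat vy = v.slice(1);
  for (uword t = 0; t < T; ++t) {
    mat a = Wg * gprev;
    a += Wv.col(0) * vx.col(t).t();
    a += Wv.col(1) * vy.col(t).t();
    mat g = clamp(a, 0.0, datum::inf);  // ReLU
    mat lp;
    fp.phat.slice(t) = softmax_cols(Wd * g, &lp);
    fp.logp.slice(t) = lp;
    fp.g.slice(t) = g;
    gprev = g;
  }
  return fp;
}

// [[Rcpp::export]]
Rcpp::List cpp_rnn_forward(const arma::mat& We, const arma::mat& Wg,
                           const arma::mat& Wv, const arma::mat& Wd,
                           const arma::mat& p0, const arma::cube& v,
                           bool return_states = true) {
  ForwardPass fp = run_forward(We, Wg, Wv, Wd, p0, v);
  if (!fp.g.is_finite())
    Rcpp::stop("non-finite recurrent state encountered during forward pass");
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("p_hat") = fp.phat,
                                      Rcpp::Named("g0") = fp.g0);
  if (return_states) out["g"] = fp.g;
  return out;
}

// One minibatch of training: forward, backprop through all T steps, Adam
// update. Returns updated parameters, optimizer state and metrics.
// [[Rcpp::export]]
Rcpp::List cpp_train_step(Rcpp::List params, Rcpp::List adam,
                          const arma::mat& p0, const arma::cube& v,
                          const arma::cube& labels, double lr, double lambda,
                          int step, double beta1 = 0.9, double beta2 = 0.999,
                          double eps = 1e-8) {
  mat We = params["We"], Wg = params["Wg"], Wv = params["Wv"],
      Wd = params["Wd"];
  const uword B = p0.n_cols, T = v.n_cols;

  ForwardPass fp = run_forward(We, Wg, Wv, Wd, p0, v);
  if (!fp.g.is_finite())
    Rcpp::stop("training diverged: non-finite state at step %d", step);

  const double scale = 1.0 / double(B * T);
  double ce = 0.0, ent = 0.0;
  mat gWe(size(We), fill::zeros), gWg(size(Wg), fill::zeros),
      gWv(size(Wv), fill::zeros), gWd(size(Wd), fill::zeros);
  const mat vx = v.slice(0), vy = v.slice(1);

  mat da_next;  // da_{t+1}, empty at t = T-1
  for (uword t = T; t-- > 0;) {
    const mat& p = labels.slice(t);
    const mat& lp = fp.logp.slice(t);
    ce -= accu(p % lp) * scale;
    ent -= accu(p % log(clamp(p, 1e-12, datum::inf))) * scale;
    mat dU = (fp.phat.slice(t) - p) * scale;
    gWd += dU * fp.g.slice(t).t();
    mat dg = Wd.t() * dU;
    if (!da_next.is_empty()) dg += Wg.t() * da_next;
    mat da = dg % conv_to<mat>::from(fp.g.slice(t) > 0);
    const mat& gprev = (t == 0) ? fp.g0 : fp.g.slice(t - 1);
    gWg += da * gprev.t();
    gWv.col(0) += da * vx.col(t);
    gWv.col(1) += da * vy.col(t);
    da_next = da;
  }
  gWe = (Wg.t() * da_next) * p0.t();  // da_next now holds da_1
  gWg += 2.0 * lambda * Wg;

  const double l2 = accu(square(Wg));
  const double kl = ce - ent;

  // Adam
  const char* names[4] = {"We", "Wg", "Wv", "Wd"};
  mat* Ws[4] = {&We, &Wg, &Wv, &Wd};
  mat* Gs[4] = {&gWe, &gWg, &gWv, &gWd};
  const double c1 = 1.0 - std::pow(beta1, step);
  const double c2 = 1.0 - std::pow(beta2, step);
  for (int k = 0; k < 4; ++k) {
    std::string mn = std::string("m") + names[k];
    std::string vn = std::string("v") + names[k];
    mat m = adam[mn], vv = adam[vn];
    m = beta1 * m + (1 - beta1) * (*Gs[k]);
    vv = beta2 * vv + (1 - beta2) * square(*Gs[k]);
    *Ws[k] -= lr * (m / c1) / (sqrt(vv / c2) + eps);
    adam[mn] = m;
    adam[vn] = vv;
  }
  params["We"] = We; params["Wg"] = Wg; params["Wv"] = Wv; params["Wd"] = Wd;

  return Rcpp::List::create(
      Rcpp::Named("params") = params, Rcpp::Named("adam") = adam,
      Rcpp::Named("cross_entropy") = ce, Rcpp::Named("kl") = kl,
      Rcpp::Named("l2") = l2, Rcpp::Named("loss") = ce + lambda * l2);
}
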