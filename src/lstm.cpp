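// Batched network engine.
//
// Layout: document batches are cubes with rows = documents (B), columns =
// feature width, slices = sentence positions (n), so slice(t) is the
// contiguous B x d input matrix of position t. Gate blocks in W and b are
// ordered f, i, o, c and act on the concatenation [h_{t-1}, x_t].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct LstmCache {
  cube H, F, I, O, Ct, C, Cprev, Hprev;
  bool reverse;
};

static LstmCache lstm_fw(const cube& X, const mat& W, const vec& b,
                         bool reverse) {
  const uword B = X.n_rows, d = X.n_cols, n = X.n_slices;
  const uword H = W.n_cols / 4;
  LstmCache cc;
  cc.H = cube(B, H, n);
  cc.F = cube(B, H, n);
  cc.I = cube(B, H, n);
  cc.O = cube(B, H, n);
  cc.Ct = cube(B, H, n);
  cc.C = cube(B, H, n);
  cc.Cprev = cube(B, H, n);
  cc.Hprev = cube(B, H, n);
  cc.reverse = reverse;
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  const mat Wh = W.rows(0, H - 1);
  const mat Wx = W.rows(H, H + d - 1);
  const rowvec bt = b.t();
  for (uword s = 0; s < n; ++s) {
    const uword t = reverse ? n - 1 - s : s;
    cc.Hprev.slice(t) = h;
    cc.Cprev.slice(t) = c;
    mat z = h * Wh + X.slice(t) * Wx;
    z.each_row() += bt;
    const mat f = 1.0 / (1.0 + exp(-z.cols(0, H - 1)));
    const mat i = 1.0 / (1.0 + exp(-z.cols(H, 2 * H - 1)));
    const mat o = 1.0 / (1.0 + exp(-z.cols(2 * H, 3 * H - 1)));
    const mat ct = tanh(z.cols(3 * H, 4 * H - 1));
    c = f % c + i % ct;
    h = o % tanh(c);
    cc.F.slice(t) = f;
    cc.I.slice(t) = i;
    cc.O.slice(t) = o;
    cc.Ct.slice(t) = ct;
    cc.C.slice(t) = c;
    cc.H.slice(t) = h;
  }
  return cc;
}

// Unwind the recurrence in the opposite order of the forward pass.
static void lstm_bw(const cube& dHout, const cube& X, const mat& W,
                    const LstmCache& cc, mat& dW, rowvec& db) {
  const uword B = X.n_rows, d = X.n_cols, n = X.n_slices;
  const uword H = W.n_cols / 4;
  dW.zeros(H + d, 4 * H);
  db.zeros(4 * H);
  mat dh_carry(B, H, fill::zeros), dc_carry(B, H, fill::zeros);
  const mat Wh = W.rows(0, H - 1);
  for (uword s = 0; s < n; ++s) {
    const uword t = cc.reverse ? s : n - 1 - s;
    const mat& f = cc.F.slice(t);
    const mat& i = cc.I.slice(t);
    const mat& o = cc.O.slice(t);
    const mat& ct = cc.Ct.slice(t);
    const mat tc = tanh(cc.C.slice(t));
    const mat dh = dHout.slice(t) + dh_carry;
    const mat do_ = dh % tc;
    const mat dc = dc_carry + dh % o % (1.0 - tc % tc);
    mat dz(B, 4 * H);
    dz.cols(0, H - 1) = (dc % cc.Cprev.slice(t)) % f % (1.0 - f);
    dz.cols(H, 2 * H - 1) = (dc % ct) % i % (1.0 - i);
    dz.cols(2 * H, 3 * H - 1) = do_ % o % (1.0 - o);
    dz.cols(3 * H, 4 * H - 1) = (dc % i) % (1.0 - ct % ct);
    dW.rows(0, H - 1) += cc.Hprev.slice(t).t() * dz;
    dW.rows(H, H + d - 1) += X.slice(t).t() * dz;
    db += sum(dz, 0);
    dh_carry = dz * Wh.t();
    dc_carry = dc % f;
  }
}

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::cube& X, const arma::mat& W,
                            const arma::vec& b, bool reverse) {
  LstmCache cc = lstm_fw(X, W, b, reverse);
  return Rcpp::List::create(
      Rcpp::Named("H") = cc.H, Rcpp::Named("f") = cc.F,
      Rcpp::Named("i") = cc.I, Rcpp::Named("o") = cc.O,
      Rcpp::Named("ctilde") = cc.Ct, Rcpp::Named("C") = cc.C,
      Rcpp::Named("Cprev") = cc.Cprev, Rcpp::Named("Hprev") = cc.Hprev,
      Rcpp::Named("reverse") = reverse);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::cube& dHout, const arma::cube& X,
                             const arma::mat& W, const Rcpp::List& fw) {
  LstmCache cc;
  cc.F = Rcpp::as<cube>(fw["f"]);
  cc.I = Rcpp::as<cube>(fw["i"]);
  cc.O = Rcpp::as<cube>(fw["o"]);
  cc.Ct = Rcpp::as<cube>(fw["ctilde"]);
  cc.C = Rcpp::as<cube>(fw["C"]);
  cc.Cprev = Rcpp::as<cube>(fw["Cprev"]);
  cc.Hprev = Rcpp::as<cube>(fw["Hprev"]);
  cc.reverse = Rcpp::as<bool>(fw["reverse"]);
  mat dW;
  rowvec db;
  lstm_bw(dHout, X, W, cc, dW, db);
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
}

struct NetForward {
  LstmCache fwd, bwd;
  std::vector<mat> Hmats, As, Aqs, Aks;
  mat R;
};

// Shared forward pass: BiLSTM -> self-attention -> masked mean of contexts.
static NetForward net_fw(const cube& X, const umat& mask, const mat& Wf,
                         const vec& bf, const mat& Wb, const vec& bb,
                         const mat& WQ, const mat& WK) {
  const uword B = X.n_rows, n = X.n_slices;
  const uword H = Wf.n_cols / 4;
  const double sdk = std::sqrt((double)WQ.n_cols);
  NetForward nf;
  nf.fwd = lstm_fw(X, Wf, bf, false);
  nf.bwd = lstm_fw(X, Wb, bb, true);
  nf.Hmats.resize(B);
  nf.As.resize(B);
  nf.Aqs.resize(B);
  nf.Aks.resize(B);
  nf.R = mat(B, 2 * H, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    mat Hm(n, 2 * H);
    for (uword t = 0; t < n; ++t) {
      Hm(t, span(0, H - 1)) = nf.fwd.H.slice(t).row(b);
      Hm(t, span(H, 2 * H - 1)) = nf.bwd.H.slice(t).row(b);
    }
    mat Aq = Hm * WQ, Ak = Hm * WK;
    mat E = (Aq * Ak.t()) / sdk;
    uvec unmasked = find(mask.row(b).t() != 0);
    if (unmasked.n_elem == 0) Rcpp::stop("document with zero unmasked sentences");
    for (uword j = 0; j < n; ++j) {
      if (mask(b, j) == 0) E.col(j).fill(-datum::inf);
    }
    vec mx = max(E, 1);
    mat A = exp(E.each_col() - mx);
    vec rs = sum(A, 1);
    A.each_col() /= rs;
    for (uword i2 = 0; i2 < n; ++i2) {
      if (mask(b, i2) == 0) A.row(i2).zeros();
    }
    mat C = A * Hm;
    nf.R.row(b) = mean(C.rows(unmasked), 0);
    nf.Hmats[b] = std::move(Hm);
    nf.As[b] = std::move(A);
    nf.Aqs[b] = std::move(Aq);
    nf.Aks[b] = std::move(Ak);
  }
  return nf;
}

// Forward-only pass; with `collect` also returns the per-document sentence
// weight vectors (mean attention received over unmasked queries) and the
// masked mean of the BiLSTM hidden states.
// [[Rcpp::export]]
Rcpp::List network_forward_cpp(const arma::cube& X, const arma::umat& mask,
                               const arma::mat& Wf, const arma::vec& bf,
                               const arma::mat& Wb, const arma::vec& bb,
                               const arma::mat& WQ, const arma::mat& WK,
                               const arma::vec& w, double b0, bool collect) {
  const uword B = X.n_rows, n = X.n_slices;
  const uword H = Wf.n_cols / 4;
  NetForward nf = net_fw(X, mask, Wf, bf, Wb, bb, WQ, WK);
  vec z = nf.R * w + b0;
  vec p = 1.0 / (1.0 + exp(-z));
  mat W_sent, H_pool;
  if (collect) {
    W_sent = mat(B, n);
    H_pool = mat(B, 2 * H);
    for (uword b = 0; b < B; ++b) {
      uvec unmasked = find(mask.row(b).t() != 0);
      W_sent.row(b) = mean(nf.As[b].rows(unmasked), 0);
      H_pool.row(b) = mean(nf.Hmats[b].rows(unmasked), 0);
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("p") = p, Rcpp::Named("R") = nf.R,
      Rcpp::Named("sentence_weights") = W_sent,
      Rcpp::Named("bilstm_pooled") = H_pool);
}

// One full training step: forward (BiLSTM -> self-attention -> masked mean
// of contexts -> dropout -> affine head -> sigmoid), mean binary
// cross-entropy, and the gradients of every parameter. `drop_mask` is the
// B x 2H Bernoulli mask drawn by the caller (ignored when dropout = 0).
// [[Rcpp::export]]
Rcpp::List network_grad_cpp(const arma::cube& X, const arma::umat& mask,
                            const arma::mat& Wf, const arma::vec& bf,
                            const arma::mat& Wb, const arma::vec& bb,
                            const arma::mat& WQ, const arma::mat& WK,
                            const arma::vec& w, double b0,
                            const arma::vec& y, double dropout,
                            const arma::mat& drop_mask) {
  const uword B = X.n_rows, n = X.n_slices;
  const uword H = Wf.n_cols / 4;
  const double sdk = std::sqrt((double)WQ.n_cols);
  NetForward nf = net_fw(X, mask, Wf, bf, Wb, bb, WQ, WK);
  LstmCache& fwd = nf.fwd;
  LstmCache& bwd = nf.bwd;
  std::vector<mat>& Hmats = nf.Hmats;
  std::vector<mat>& As = nf.As;
  std::vector<mat>& Aqs = nf.Aqs;
  std::vector<mat>& Aks = nf.Aks;
  mat& R = nf.R;

  mat R_drop = R;
  if (dropout > 0) R_drop = (R % drop_mask) / (1.0 - dropout);
  vec z = R_drop * w + b0;
  vec p = 1.0 / (1.0 + exp(-z));
  vec pc = clamp(p, 1e-12, 1.0 - 1e-12);
  double loss = -mean(y % log(pc) + (1.0 - y) % log(1.0 - pc));

  // backward
  vec dz = (p - y) / (double)B;
  vec dw = R_drop.t() * dz;
  double db0 = accu(dz);
  mat dR = dz * w.t();
  if (dropout > 0) dR = (dR % drop_mask) / (1.0 - dropout);

  mat dWQ(WQ.n_rows, WQ.n_cols, fill::zeros);
  mat dWK(WK.n_rows, WK.n_cols, fill::zeros);
  cube dHf(B, H, n, fill::zeros), dHb(B, H, n, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    uvec unmasked = find(mask.row(b).t() != 0);
    mat dC(n, 2 * H, fill::zeros);
    rowvec share = dR.row(b) / (double)unmasked.n_elem;
    for (uword u = 0; u < unmasked.n_elem; ++u) dC.row(unmasked(u)) = share;
    const mat& Hm = Hmats[b];
    const mat& A = As[b];
    mat dA = dC * Hm.t();
    mat dHm = A.t() * dC;
    vec srow = sum(dA % A, 1);
    mat dE = A % (dA.each_col() - srow);
    mat dAq = (dE * Aks[b]) / sdk;
    mat dAk = (dE.t() * Aqs[b]) / sdk;
    dWQ += Hm.t() * dAq;
    dWK += Hm.t() * dAk;
    dHm += dAq * WQ.t() + dAk * WK.t();
    for (uword t = 0; t < n; ++t) {
      dHf.slice(t).row(b) = dHm(t, span(0, H - 1));
      dHb.slice(t).row(b) = dHm(t, span(H, 2 * H - 1));
    }
  }
  mat dWf, dWb;
  rowvec dbf, dbb;
  lstm_bw(dHf, X, Wf, fwd, dWf, dbf);
  lstm_bw(dHb, X, Wb, bwd, dWb, dbb);

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("p") = p,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("fwd") = Rcpp::List::create(Rcpp::Named("W") = dWf,
                                                  Rcpp::Named("b") = dbf.t()),
          Rcpp::Named("bwd") = Rcpp::List::create(Rcpp::Named("W") = dWb,
                                                  Rcpp::Named("b") = dbb.t()),
          Rcpp::Named("WQ") = dWQ, Rcpp::Named("WK") = dWK,
          Rcpp::Named("w") = dw, Rcpp::Named("b0") = db0));
}
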