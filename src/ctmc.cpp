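// Epoch-stratified CTMC pruning core.
//
// Transition probabilities use an eigendecomposition fast path per epoch
// (one decomposition per likelihood evaluation, reused across branch
// segments) with a dense scaling-and-squaring matrix exponential fallback
// when the generator is defective or ill-conditioned.  Partial likelihoods
// are rescaled per edge so 100+-tip trees do not underflow.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct EpochDecomp {
  bool ok;
  cx_mat V, Vinv;
  cx_vec ev;
  mat Q;
};

static EpochDecomp decompose(const mat& Q) {
  EpochDecomp d;
  d.Q = Q;
  d.ok = false;
  cx_vec ev;
  cx_mat V;
  if (eig_gen(ev, V, Q)) {
    cx_mat Vinv;
    if (inv(Vinv, V)) {
      cx_mat recon = V * diagmat(ev) * Vinv;
      double err = norm(real(recon) - Q, "fro") + norm(imag(recon), "fro");
      if (err <= 1e-9 * (1.0 + norm(Q, "fro"))) {
        d.ok = true;
        d.V = V;
        d.Vinv = Vinv;
        d.ev = ev;
      }
    }
  }
  return d;
}

static mat seg_prob(const EpochDecomp& d, double dt) {
  const uword k = d.Q.n_rows;
  if (dt <= 0.0) return eye(k, k);
  mat P;
  if (d.ok) {
    P = real(d.V * diagmat(exp(d.ev * dt)) * d.Vinv);
  } else {
    P = expmat(d.Q * dt);
  }
  P.for_each([](double& x) { if (x < 0.0) x = 0.0; });
  return P;
}

// Dense matrix exponential (scaling-and-squaring); exposed for
// transition-probability computations at the R level.
// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& M) {
  return expmat(M);
}

// Felsenstein pruning over an epoch-stratified CTMC.
//
// edge:      m x 2 (parent, child), 1-based, in postorder
// nseg:      number of segments per edge (same order)
// seg_epoch: flattened per-segment epoch index (1-based), oldest first
// seg_dt:    flattened per-segment duration (Ma)
// Qs:        k x k x n_epoch cube of generators
// init:      (ntip + nnode) x k partial-likelihood initialisation
// root:      root node index, 1-based
// pi:        root state prior
// want:      0 = loglik only; 1 = + partials; 2 = + per-edge P matrices
// [[Rcpp::export]]
Rcpp::List cpp_ctmc(const arma::umat& edge,
                    const arma::uvec& nseg,
                    const arma::uvec& seg_epoch,
                    const arma::vec& seg_dt,
                    const arma::cube& Qs,
                    const arma::mat& init,
                    const int root,
                    const arma::vec& pi,
                    const int want) {
  const uword m = edge.n_rows;
  const uword k = Qs.n_rows;
  const uword nep = Qs.n_slices;

  std::vector<EpochDecomp> dec(nep);
  for (uword e = 0; e < nep; ++e) dec[e] = decompose(Qs.slice(e));

  mat part = init;
  double logscale = 0.0;
  bool dead = false;

  cube edgeP;
  if (want >= 2) edgeP.set_size(k, k, m);

  uword pos = 0;
  for (uword e = 0; e < m; ++e) {
    const uword u = edge(e, 0) - 1;
    const uword v = edge(e, 1) - 1;
    const uword ns = nseg(e);
    mat P = eye(k, k);
    for (uword s = 0; s < ns; ++s) {
      const uword ep = seg_epoch(pos + s) - 1;
      P = P * seg_prob(dec[ep], seg_dt(pos + s));
    }
    pos += ns;
    if (want >= 2) edgeP.slice(e) = P;
    if (dead) continue;
    vec contrib = P * part.row(v).t();
    double mx = contrib.max();
    if (!(mx > 0.0)) {
      dead = true;
      continue;
    }
    contrib /= mx;
    logscale += std::log(mx);
    part.row(u) %= contrib.t();
  }

  double loglik;
  if (dead) {
    loglik = R_NegInf;
  } else {
    double tot = dot(pi, part.row(root - 1).t());
    loglik = tot > 0.0 ? std::log(tot) + logscale : R_NegInf;
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loglik") = loglik);
  if (want >= 1) out["partials"] = part;
  if (want >= 2) out["edgeP"] = edgeP;
  return out;
}
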