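// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Transition kernels and the pruning (Felsenstein) likelihood over the
// expanded state space (observed states x hidden rate categories).
//
// P(t) = exp(Qt) is computed once per branch. The fast path shares a single
// eigendecomposition of Q across all branches; when Q is defective or the
// eigenbasis is ill-conditioned the code falls back to scaling-and-squaring
// (arma::expmat) per branch.

static arma::mat clean_P(arma::mat P) {
  // clamp tiny negative entries produced by roundoff, then renormalise rows
  P.elem(arma::find(P < 0.0)).zeros();
  arma::vec rs = arma::sum(P, 1);
  for (arma::uword i = 0; i < P.n_rows; ++i) {
    if (rs(i) > 0.0) P.row(i) /= rs(i);
  }
  return P;
}

static bool P_plausible(const arma::mat& P) {
  if (!P.is_finite()) return false;
  if (P.min() < -1e-8) return false;
  arma::vec rs = arma::sum(P, 1);
  return arma::abs(rs - 1.0).max() < 1e-8;
}

// [[Rcpp::export]]
arma::cube cpp_branch_P(const arma::mat& Q, const arma::vec& lens) {
  const arma::uword m = Q.n_rows, E = lens.n_elem;
  arma::cube P(m, m, E);
  arma::cx_vec lam;
  arma::cx_mat V, Vinv;
  bool spectral = arma::eig_gen(lam, V, Q);
  if (spectral) spectral = arma::rcond(V) > 1e-12 && arma::inv(Vinv, V);
  for (arma::uword e = 0; e < E; ++e) {
    if (lens(e) == 0.0) { // zero-length branch: exactly the identity
      P.slice(e) = arma::eye(m, m);
      continue;
    }
    arma::mat Pe;
    bool ok = false;
    if (spectral) {
      arma::cx_mat cP = V * arma::diagmat(arma::exp(lam * lens(e))) * Vinv;
      Pe = arma::real(cP);
      ok = P_plausible(Pe);
    }
    if (!ok) Pe = arma::expmat(Q * lens(e));
    P.slice(e) = clean_P(Pe);
  }
  return P;
}

// Post-order accumulation of partial likelihoods with per-edge rescaling.
// `edge` must be in postorder (every child edge before its parent's edge);
// `partials` holds one row per node: tip rows carry the observation vector,
// internal rows carry the clamp mask (all ones when unclamped).
static double prune_impl(const arma::imat& edge, const arma::cube& P,
                         arma::mat L, const arma::vec& root_pi,
                         const int root) {
  double logscale = 0.0;
  const arma::uword E = edge.n_rows;
  for (arma::uword e = 0; e < E; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    arma::vec v = P.slice(e) * L.row(c).t();
    const double mx = v.max();
    if (!(mx > 0.0)) return -arma::datum::inf;
    logscale += std::log(mx);
    L.row(p) %= (v / mx).t();
  }
  const double s = arma::dot(L.row(root - 1).t(), root_pi);
  if (!(s > 0.0)) return -arma::datum::inf;
  return std::log(s) + logscale;
}

// [[Rcpp::export]]
double cpp_prune(const arma::imat& edge, const arma::cube& P,
                 const arma::mat& partials, const arma::vec& root_pi,
                 const int root) {
  return prune_impl(edge, P, partials, root_pi, root);
}

// Log-likelihood with one node at a time clamped to each observed state.
// `state_masks` has one 0/1 row per observed state over the expanded states;
// normalising each output row yields the marginal ancestral reconstruction.
// [[Rcpp::export]]
arma::mat cpp_clamped_logliks(const arma::imat& edge, const arma::cube& P,
                              const arma::mat& partials,
                              const arma::vec& root_pi, const int root,
                              const arma::ivec& nodes,
                              const arma::mat& state_masks) {
  arma::mat out(nodes.n_elem, state_masks.n_rows);
  for (arma::uword i = 0; i < nodes.n_elem; ++i) {
    for (arma::uword s = 0; s < state_masks.n_rows; ++s) {
      arma::mat L = partials;
      L.row(nodes(i) - 1) %= state_masks.row(s);
      out(i, s) = prune_impl(edge, P, L, root_pi, root);
    }
  }
  return out;
}
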