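// Pruning likelihood for a CTMC on a rooted phylogeny.
// Node indexing follows ape: tips 1..ntip, internals ntip+1..ntip+nnode.
// Edges must arrive in postorder (children before parents).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double t) {
  return arma::expmat(Q * t);
}

// P(t) for each length, caching identical lengths. When Q has a
// well-conditioned eigendecomposition, P(t) = V exp(Dt) V^-1 costs
// O(S^2) per distinct length after one O(S^3) factorization; otherwise
// fall back to a Pade matrix exponential per length.
static std::vector<arma::mat> expm_cache(const arma::mat& Q,
                                         const arma::vec& lens) {
  const arma::uword S = Q.n_rows;
  std::vector<arma::mat> out(lens.n_elem);
  std::map<double, int> seen;

  arma::cx_vec eigval;
  arma::cx_mat V, Vinv;
  bool use_eig = false;
  if (S > 8 && lens.n_elem > 3) {
    if (arma::eig_gen(eigval, V, Q)) {
      double rc = arma::rcond(V);
      if (rc > 1e-9 && arma::inv(Vinv, V)) use_eig = true;
    }
  }
  for (arma::uword i = 0; i < lens.n_elem; ++i) {
    auto hit = seen.find(lens[i]);
    if (hit != seen.end()) {
      out[i] = out[hit->second];
      continue;
    }
    arma::mat P;
    bool ok = false;
    if (use_eig) {
      arma::cx_mat Pc = V * arma::diagmat(arma::exp(eigval * lens[i])) * Vinv;
      P = arma::real(Pc);
      // sanity: rows of a stochastic matrix sum to one
      arma::vec rs = arma::sum(P, 1);
      if (arma::all(arma::abs(rs - 1.0) < 1e-8)) {
        P.clamp(0.0, 1.0);
        ok = true;
      }
    }
    if (!ok) P = arma::expmat(Q * lens[i]);
    out[i] = P;
    seen[lens[i]] = i;
  }
  return out;
}

// Downpass conditional likelihoods. Returns the log-likelihood together
// with per-node partials and per-node log scaling factors so that the
// true partial at node v is partials.col(v-1) * exp(logscale[v-1]).
// root_mode: 0 = obs_weighted (FitzJohn root weighting), 1 = flat.
// [[Rcpp::export]]
List cpp_prune(const arma::imat& edge, const arma::vec& edge_len,
               int ntip, int nnode, const arma::ivec& tip_state,
               const arma::mat& Q, int root_mode) {
  const int S = Q.n_rows;
  const int ntot = ntip + nnode;
  arma::mat part(S, ntot, arma::fill::ones);
  arma::vec logscale(ntot, arma::fill::zeros);
  for (int i = 0; i < ntip; ++i) {
    part.col(i).zeros();
    part(tip_state[i] - 1, i) = 1.0;
  }
  std::vector<arma::mat> P = expm_cache(Q, edge_len);
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int par = edge(e, 0) - 1;
    const int chi = edge(e, 1) - 1;
    arma::vec v = P[e] * part.col(chi);
    part.col(par) %= v;
    logscale[par] += logscale[chi];
    double s = arma::accu(part.col(par));
    if (!(s > 0.0) || !std::isfinite(s)) {
      return List::create(_["loglik"] = R_NegInf, _["partials"] = part,
                          _["logscale"] = logscale);
    }
    part.col(par) /= s;
    logscale[par] += std::log(s);
  }
  // the root is the one parent that never appears as a child
  std::vector<bool> is_child(ntot, false);
  for (arma::uword e = 0; e < edge.n_rows; ++e) is_child[edge(e, 1) - 1] = true;
  int root = ntip;  // ape convention; fall back to scan
  if (is_child[root]) {
    for (int i = ntip; i < ntot; ++i) if (!is_child[i]) { root = i; break; }
  }
  const arma::vec D = part.col(root);
  double rootval;
  if (root_mode == 0) {
    rootval = arma::dot(D, D) / arma::accu(D);
  } else {
    rootval = arma::accu(D) / S;
  }
  double ll = (rootval > 0.0) ? logscale[root] + std::log(rootval) : R_NegInf;
  return List::create(_["loglik"] = ll, _["partials"] = part,
                      _["logscale"] = logscale, _["root"] = root + 1);
}

// [[Rcpp::export]]
double cpp_prune_loglik(const arma::imat& edge, const arma::vec& edge_len,
                        int ntip, int nnode, const arma::ivec& tip_state,
                        const arma::mat& Q, int root_mode) {
  const int S = Q.n_rows;
  const int ntot = ntip + nnode;
  arma::mat part(S, ntot, arma::fill::ones);
  double logscale = 0.0;
  for (int i = 0; i < ntip; ++i) {
    part.col(i).zeros();
    part(tip_state[i] - 1, i) = 1.0;
  }
  std::vector<arma::mat> P = expm_cache(Q, edge_len);
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int par = edge(e, 0) - 1;
    const int chi = edge(e, 1) - 1;
    part.col(par) %= P[e] * part.col(chi);
    double s = arma::accu(part.col(par));
    if (!(s > 0.0) || !std::isfinite(s)) return R_NegInf;
    part.col(par) /= s;
    logscale += std::log(s);
  }
  std::vector<bool> is_child(ntot, false);
  for (arma::uword e = 0; e < edge.n_rows; ++e) is_child[edge(e, 1) - 1] = true;
  int root = ntip;
  if (is_child[root]) {
    for (int i = ntip; i < ntot; ++i) if (!is_child[i]) { root = i; break; }
  }
  const arma::vec D = part.col(root);
  double rootval = (root_mode == 0) ? arma::dot(D, D) / arma::accu(D)
                                    : arma::accu(D) / S;
  return (rootval > 0.0) ? logscale + std::log(rootval) : R_NegInf;
}
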