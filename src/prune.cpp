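#include <RcppArmadillo.h>
#include <map>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Felsenstein pruning log-likelihood for tip states under a finite-state
// CTMC with generator Q on a rooted tree.
//
// edge     : E x 2 integer matrix (parent, child), 1-based ape node ids with
//            tips 1..n_tip; rows must be in postorder so every node appears
//            as a child before it appears as a parent.
// elen     : branch length per edge row (>= 0).
// tip_state: observed 0-based state index per tip (length n_tip).
// prior    : root state distribution (length m).
// n_node   : total number of nodes (tips + internal).
// log_pi   : if length m, the chain is reversible with stationary
//            log-probabilities log_pi and the symmetrized eigendecomposition
//            diag(sqrt(pi)) Q diag(1/sqrt(pi)) is used; otherwise a general
//            eigendecomposition with a scaling-and-squaring fallback.
//
// Transition matrices are never formed: each branch applies
// P(b) v = V exp(Lambda b) V^{-1} v as three matrix-vector products.
// Partial likelihoods are rescaled per node with accumulated log scalers so
// trees with many hundreds of tips do not underflow.
// [[Rcpp::export]]
double prune_loglik_cpp(const arma::mat& Q,
                        const arma::imat& edge,
                        const arma::vec& elen,
                        const arma::ivec& tip_state,
                        const arma::vec& prior,
                        const int n_node,
                        const arma::vec& log_pi) {
  const uword m = Q.n_rows;
  const uword E = edge.n_rows;
  const uword n_tip = tip_state.n_elem;
  const double neg_inf = -std::numeric_limits<double>::infinity();

  if (!Q.is_finite()) return neg_inf;

  mat L(m, (uword)n_node, fill::ones);
  for (uword i = 0; i < n_tip; ++i) {
    L.col(i).zeros();
    L((uword)tip_state(i), i) = 1.0;
  }
  double logscale = 0.0;

  const bool sym = (log_pi.n_elem == m);

  // reversible path: real symmetric eigendecomposition
  vec ev;
  mat A, B;
  // general path: complex eigendecomposition
  bool gen_eig_ok = false;
  cx_vec cev;
  cx_mat V, Vi;
  std::map<double, mat> pcache;  // expmat fallback, keyed by branch length

  if (sym) {
    vec d = 0.5 * log_pi;
    mat M(m, m);
    for (uword j = 0; j < m; ++j)
      for (uword i = 0; i < m; ++i)
        M(i, j) = Q(i, j) * std::exp(d(i) - d(j));
    M = 0.5 * (M + M.t());
    mat U;
    if (!eig_sym(ev, U, M)) return neg_inf;
    A = U;
    A.each_col() %= exp(-d);      // A(i,.) = exp(-d_i) U(i,.)
    B = U.t();
    B.each_row() %= exp(d).t();   // B(.,j) = U(j,.)' exp(d_j)
  } else {
    gen_eig_ok = eig_gen(cev, V, Q);
    if (gen_eig_ok) gen_eig_ok = inv(Vi, V);
    if (gen_eig_ok) {
      mat R = real(V * diagmat(cev) * Vi);
      double err = norm(R - Q, "inf") / (1.0 + norm(Q, "inf"));
      if (!std::isfinite(err) || err > 1e-8) gen_eig_ok = false;
    }
  }

  vec v(m), w(m);
  cx_vec cw(m);
  for (uword e = 0; e < E; ++e) {
    const uword p = (uword)edge(e, 0) - 1;
    const uword c = (uword)edge(e, 1) - 1;
    const double b = elen(e);

    if (sym) {
      w = B * L.col(c);
      w %= exp(ev * b);
      v = A * w;
    } else if (gen_eig_ok) {
      cw = Vi * conv_to<cx_vec>::from(L.col(c));
      cw %= exp(cev * b);
      v = real(V * cw);
    } else {
      std::map<double, mat>::iterator it = pcache.find(b);
      if (it == pcache.end())
        it = pcache.insert(std::make_pair(b, expmat(Q * b))).first;
      v = it->second * L.col(c);
    }

    v.transform([](double x) { return x > 0.0 ? x : 0.0; });
    const double mx = v.max();
    if (!(mx > 0.0) || !std::isfinite(mx)) return neg_inf;
    L.col(p) %= v / mx;
    logscale += std::log(mx);
  }

  const uword root = (uword)edge(E - 1, 0) - 1;
  const double s = dot(prior, L.col(root));
  if (!(s > 0.0) || !std::isfinite(s)) return neg_inf;
  return std::log(s) + logscale;
}
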