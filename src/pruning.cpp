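// Felsenstein pruning and marginal ancestral posteriors.
//
// Two engines share the same tree conventions as ape's "phylo":
// nodes 1..n_tips are leaves, n_tips+1..n_nodes internal, edges supplied in
// postorder (every child edge precedes its parent's edge).  States are
// 0-based integers; -1 marks missing data (gap/ambiguity), which contributes
// a flat partial likelihood.  Partial likelihoods are rescaled per column to
// avoid underflow on 20- and 61-state alphabets.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Column-rescale a partial-likelihood matrix in place; adds log scale to ls.
static void rescale_cols(arma::mat &L, arma::rowvec &ls) {
  arma::rowvec mx = arma::max(L, 0);
  for (arma::uword s = 0; s < L.n_cols; ++s) {
    double m = mx(s);
    if (m > 0 && (m < 1e-200 || m > 1e200)) {
      L.col(s) /= m;
      ls(s) += std::log(m);
    }
  }
}

// Pruning with one precomputed P matrix per edge, vectorised across sites.
// edge: nE x 2 (1-based parent, child), postorder.  P: k x k x nE.
// tip_states: n_tips x S.  root_pi: k.
// [[Rcpp::export]]
List prune_edge_P(const arma::imat &edge, const arma::cube &P,
                  const arma::imat &tip_states, const arma::vec &root_pi,
                  int n_tips, bool posterior) {
  const arma::uword k = P.n_rows, S = tip_states.n_cols,
                    nE = edge.n_rows;
  const arma::uword n_nodes = (arma::uword)edge.max();
  arma::field<arma::mat> L(n_nodes), M(nE);
  arma::mat logsc(n_nodes, S, arma::fill::zeros);
  std::vector<bool> seen(n_nodes, false);
  std::vector<std::vector<arma::uword>> child_edges(n_nodes);

  // tip partials
  for (arma::uword i = 0; i < (arma::uword)n_tips; ++i) {
    arma::mat Li(k, S, arma::fill::zeros);
    for (arma::uword s = 0; s < S; ++s) {
      int st = tip_states(i, s);
      if (st < 0) Li.col(s).ones();
      else Li((arma::uword)st, s) = 1.0;
    }
    L(i) = Li;
    seen[i] = true;
  }

  for (arma::uword e = 0; e < nE; ++e) {
    arma::uword p = (arma::uword)edge(e, 0) - 1, c = (arma::uword)edge(e, 1) - 1;
    child_edges[p].push_back(e);
    arma::mat Me = P.slice(e) * L(c);
    if (posterior) M(e) = Me;
    if (!seen[p]) {
      L(p) = Me;
      logsc.row(p) = logsc.row(c);
      seen[p] = true;
    } else {
      L(p) %= Me;
      logsc.row(p) += logsc.row(c);
    }
    arma::rowvec ls = logsc.row(p);
    rescale_cols(L(p), ls);
    logsc.row(p) = ls;
  }

  arma::uword root = (arma::uword)edge(nE - 1, 0) - 1;
  arma::rowvec lik = root_pi.t() * L(root);
  arma::rowvec loglik = arma::log(lik) + logsc.row(root);

  List out = List::create(_["loglik"] = NumericVector(loglik.begin(), loglik.end()));
  if (!posterior) return out;

  // Outside pass: O(v) for internal nodes, columns kept normalised.
  arma::uword n_int = n_nodes - (arma::uword)n_tips;
  arma::field<arma::mat> O(n_nodes);
  O(root) = arma::repmat(root_pi, 1, S);
  arma::cube post(k, S, n_int, arma::fill::zeros);
  // posterior at root
  {
    arma::mat pr = O(root) % L(root);
    pr.each_row() /= arma::sum(pr, 0);
    post.slice(root - n_tips) = pr;
  }
  // edges in reverse postorder: parents before children
  for (arma::uword e2 = nE; e2-- > 0;) {
    arma::uword p = (arma::uword)edge(e2, 0) - 1, c = (arma::uword)edge(e2, 1) - 1;
    if (c < (arma::uword)n_tips) continue;
    arma::mat T = O(p);
    for (arma::uword j : child_edges[p])
      if (j != e2) T %= M(j);
    arma::mat Oc = P.slice(e2).t() * T;
    arma::rowvec cs = arma::sum(Oc, 0);
    cs.replace(0.0, 1.0);
    Oc.each_row() /= cs;
    O(c) = Oc;
    arma::mat pr = Oc % L(c);
    arma::rowvec ps = arma::sum(pr, 0);
    ps.replace(0.0, 1.0);
    pr.each_row() /= ps;
    post.slice(c - n_tips) = pr;
  }
  out["posterior"] = post;
  return out;
}

// Build P(t) = exp(Qt) for a reversible Q given its symmetric decomposition.
static arma::mat p_matrix(const arma::vec &eval, const arma::mat &evec,
                          const arma::vec &sqp, double t) {
  arma::mat E = evec;
  E.each_row() %= arma::exp(eval.t() * t);
  arma::mat P = E * evec.t();          // exp(At) in symmetric basis
  P.each_col() /= sqp;                 // D^{ -1/2 } exp(At) D^{ 1/2 }
  P.each_row() %= sqp.t();
  P.clamp(0.0, arma::datum::inf);
  return P;
}

// Pruning under site-specific equilibrium frequencies ("fsite"):
// Q_s is rebuilt for every site from shared exchangeabilities and pi_s,
// normalised to one expected substitution per unit branch length.
// P(t) is never formed during the passes; it is applied through the
// symmetric eigendecomposition (two mat-vecs per edge), which dominates the
// speed on 20-state problems.  pis: k x S (or k x 1 for a global model).
// want_edges: 1-based edge rows whose per-site P matrices are returned
// (k x k x S cubes, used by the expected-convergence computation).
// [[Rcpp::export]]
List prune_fsite(const arma::imat &edge, const arma::vec &edge_len,
                 const arma::imat &tip_states, const arma::mat &exch,
                 const arma::mat &pis, int n_tips, bool posterior,
                 const arma::uvec &want_edges, bool keep_P = true,
                 bool map_w = false) {
  const arma::uword k = exch.n_rows, S = tip_states.n_cols,
                    nE = edge.n_rows;
  const arma::uword n_nodes = (arma::uword)edge.max();
  const arma::uword n_int = n_nodes - (arma::uword)n_tips;
  const bool per_site = pis.n_cols > 1;
  arma::uword root = (arma::uword)edge(nE - 1, 0) - 1;

  std::vector<std::vector<arma::uword>> child_edges(n_nodes);
  for (arma::uword e = 0; e < nE; ++e)
    child_edges[(arma::uword)edge(e, 0) - 1].push_back(e);

  arma::vec loglik(S);
  arma::cube post;
  if (posterior) post.zeros(k, S, n_int);
  arma::field<arma::cube> edgeP(keep_P ? want_edges.n_elem : 0);
  if (keep_P)
    for (arma::uword w = 0; w < want_edges.n_elem; ++w)
      edgeP(w).zeros(k, k, S);
  // W(w)[d,s]: P(parent state ends in d having changed) on the edge,
  // integrated over the parent's marginal posterior, or (map_w) conditioned
  // on the parent's MAP state - the same conditioning as observed events
  arma::field<arma::mat> edgeW(want_edges.n_elem);
  if (posterior)
    for (arma::uword w = 0; w < want_edges.n_elem; ++w)
      edgeW(w).zeros(k, S);

  arma::vec eval, sqp, pi;
  arma::mat evec, evecT;
  arma::mat expE(k, nE);                 // exp(eval * t_e) per edge
  arma::mat Lmat(k, n_nodes), Mmat(k, nE), Omat(k, n_nodes);
  std::vector<bool> seen(n_nodes);

  // P v   = D^{-1/2} U E U^T D^{1/2} v   (applied without forming P)
  auto apply_P = [&](arma::uword e, const arma::vec &v) {
    arma::vec u = evecT * (sqp % v);
    u %= expE.col(e);
    arma::vec w = (evec * u) / sqp;
    w.clamp(0.0, arma::datum::inf);
    return w;
  };
  // P^T v = D^{1/2} U E U^T D^{-1/2} v
  auto apply_Pt = [&](arma::uword e, const arma::vec &v) {
    arma::vec u = evecT * (v / sqp);
    u %= expE.col(e);
    arma::vec w = (evec * u) % sqp;
    w.clamp(0.0, arma::datum::inf);
    return w;
  };

  for (arma::uword s = 0; s < S; ++s) {
    if (per_site || s == 0) {
      pi = per_site ? pis.col(s) : pis.col(0);
      arma::mat Q = exch;
      Q.each_row() %= pi.t();
      Q.diag().zeros();
      Q.diag() = -arma::sum(Q, 1);
      double mu = -arma::dot(pi, Q.diag());
      Q /= mu;
      sqp = arma::sqrt(pi);
      arma::mat A = Q;
      A.each_col() %= sqp;
      A.each_row() /= sqp.t();
      A = 0.5 * (A + A.t());
      arma::eig_sym(eval, evec, A);
      evecT = evec.t();
      for (arma::uword e = 0; e < nE; ++e)
        expE.col(e) = arma::exp(eval * edge_len(e));
    }
    if (keep_P)
      for (arma::uword w = 0; w < want_edges.n_elem; ++w)
        edgeP(w).slice(s) =
            p_matrix(eval, evec, sqp, edge_len(want_edges(w) - 1));

    // inside pass for this site
    std::fill(seen.begin(), seen.end(), false);
    double lsc = 0.0;
    for (arma::uword i = 0; i < (arma::uword)n_tips; ++i) {
      int st = tip_states(i, s);
      Lmat.col(i).zeros();
      if (st < 0) Lmat.col(i).ones();
      else Lmat((arma::uword)st, i) = 1.0;
    }
    for (arma::uword e = 0; e < nE; ++e) {
      arma::uword p = (arma::uword)edge(e, 0) - 1,
                  c = (arma::uword)edge(e, 1) - 1;
      arma::vec Me = apply_P(e, Lmat.col(c));
      Mmat.col(e) = Me;
      if (!seen[p]) { Lmat.col(p) = Me; seen[p] = true; }
      else Lmat.col(p) %= Me;
      double m = Lmat.col(p).max();
      if (m > 0 && m < 1e-200) { Lmat.col(p) /= m; lsc += std::log(m); }
    }
    loglik(s) = std::log(arma::dot(pi, Lmat.col(root))) + lsc;

    if (posterior) {
      Omat.col(root) = pi;
      arma::vec pr = Omat.col(root) % Lmat.col(root);
      post.slice(root - n_tips).col(s) = pr / arma::accu(pr);
      for (arma::uword e2 = nE; e2-- > 0;) {
        arma::uword p = (arma::uword)edge(e2, 0) - 1,
                    c = (arma::uword)edge(e2, 1) - 1;
        if (c < (arma::uword)n_tips) continue;
        arma::vec T = Omat.col(p);
        for (arma::uword j : child_edges[p])
          if (j != e2) T %= Mmat.col(j);
        arma::vec Oc = apply_Pt(e2, T);
        double cs = arma::accu(Oc);
        if (cs > 0) Oc /= cs;
        Omat.col(c) = Oc;
        arma::vec pc = Oc % Lmat.col(c);
        double ps = arma::accu(pc);
        if (ps > 0) pc /= ps;
        post.slice(c - n_tips).col(s) = pc;
      }
      for (arma::uword w = 0; w < want_edges.n_elem; ++w) {
        arma::uword e = want_edges(w) - 1;
        arma::uword p = (arma::uword)edge(e, 0) - 1;
        arma::vec q = post.slice(p - n_tips).col(s);
        arma::vec wv;
        if (map_w) {
          arma::uword astar = q.index_max();
          arma::vec ea(k, arma::fill::zeros);
          ea(astar) = 1.0;
          wv = apply_Pt(e, ea);        // row astar of P
          wv(astar) = 0.0;             // require a change
        } else {
          arma::vec diagP = (evec % evec) * expE.col(e);
          wv = apply_Pt(e, q) - q % diagP;
        }
        wv.clamp(0.0, arma::datum::inf);
        edgeW(w).col(s) = wv;
      }
    }
  }

  List out = List::create(
      _["loglik"] = NumericVector(loglik.begin(), loglik.end()));
  if (posterior) out["posterior"] = post;
  if (want_edges.n_elem > 0) {
    if (keep_P) {
      List eP(want_edges.n_elem);
      for (arma::uword w = 0; w < want_edges.n_elem; ++w)
        eP[w] = edgeP(w);
      out["edge_P"] = eP;
    }
    if (posterior) {
      List eW(want_edges.n_elem);
      for (arma::uword w = 0; w < want_edges.n_elem; ++w)
        eW[w] = edgeW(w);
      out["edge_W"] = eW;
    }
  }
  return out;
}
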