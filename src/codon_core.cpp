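// Core 61-state codon machinery: GY94 generator, mixture pruning likelihood,
// expected labeled substitution counts (uniformization-free eigen integral),
// and CTMC path simulation.  All stochastic draws use R's RNG so set.seed()
// governs reproducibility.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int NSTATE = 61;

// pairtype codes (built in R from the genetic code):
//   0 = not a single-nucleotide change; 1 = syn transition; 2 = syn transversion;
//   3 = nonsyn transition; 4 = nonsyn transversion
static arma::mat gy94_unnorm(const arma::imat& pairtype, const arma::vec& pi,
                             double kappa, double omega) {
  arma::mat Q(NSTATE, NSTATE, arma::fill::zeros);
  for (int i = 0; i < NSTATE; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < NSTATE; ++j) {
      if (i == j) continue;
      double r = 0.0;
      switch (pairtype(i, j)) {
      case 1: r = kappa * pi(j); break;
      case 2: r = pi(j); break;
      case 3: r = omega * kappa * pi(j); break;
      case 4: r = omega * pi(j); break;
      default: r = 0.0;
      }
      Q(i, j) = r;
      rowsum += r;
    }
    Q(i, i) = -rowsum;
  }
  return Q;
}

static double mean_rate(const arma::mat& Q, const arma::vec& pi) {
  return -arma::dot(pi, Q.diag());
}

// [[Rcpp::export]]
Rcpp::List cpp_gy94_Q(const arma::imat& pairtype, const arma::vec& pi,
                      double kappa, double omega) {
  arma::mat Q = gy94_unnorm(pairtype, pi, kappa, omega);
  double mu = mean_rate(Q, pi);
  return Rcpp::List::create(Rcpp::Named("Q") = Q, Rcpp::Named("mu") = mu);
}

struct EigQ {
  // Q = A diag(lambda) Ainv, via symmetrization with D = diag(pi)
  arma::vec lambda;
  arma::mat A;
  arma::mat Ainv;
};

static EigQ eigen_q(const arma::mat& Q, const arma::vec& pi) {
  arma::vec s = arma::sqrt(pi);
  arma::mat B = Q;
  for (int i = 0; i < NSTATE; ++i)
    for (int j = 0; j < NSTATE; ++j)
      B(i, j) *= s(i) / s(j);
  B = 0.5 * (B + B.t());  // symmetric up to round-off
  EigQ e;
  arma::mat U;
  arma::eig_sym(e.lambda, U, B);
  e.A = U;
  e.A.each_col() /= s;            // A = D^{-1/2} U
  e.Ainv = U.t();
  e.Ainv.each_row() %= s.t();     // Ainv = U' D^{1/2}
  return e;
}

static arma::mat pmat(const EigQ& e, double t) {
  arma::mat P = e.A * arma::diagmat(arma::exp(e.lambda * t)) * e.Ainv;
  P.clamp(0.0, arma::datum::inf);
  return P;
}

// Build, per site class, the normalized generator (mixture mean rate 1) and
// its eigendecomposition.
static std::vector<EigQ> class_eigs(const arma::imat& pairtype, const arma::vec& pi,
                                    double kappa, const arma::vec& omegas,
                                    const arma::vec& probs,
                                    std::vector<arma::mat>* Qs_out = nullptr) {
  const int K = omegas.n_elem;
  std::vector<arma::mat> Qs(K);
  double c = 0.0;
  for (int k = 0; k < K; ++k) {
    Qs[k] = gy94_unnorm(pairtype, pi, kappa, omegas(k));
    c += probs(k) * mean_rate(Qs[k], pi);
  }
  if (c <= 0) Rcpp::stop("degenerate codon model: zero mean substitution rate");
  std::vector<EigQ> eigs(K);
  for (int k = 0; k < K; ++k) {
    Qs[k] /= c;
    eigs[k] = eigen_q(Qs[k], pi);
  }
  if (Qs_out) *Qs_out = Qs;
  return eigs;
}

// Postorder pruning for one class; returns per-pattern site likelihoods and,
// if keep != nullptr, the per-node partials and per-branch P matrices.
struct TreeData {
  arma::imat edge;     // nedge x 2, 1-based ape codes (tips 1..ntip)
  arma::vec blen;      // branch lengths (already scaled)
  int ntip;
  int nnode;           // total nodes = max code
  std::vector<int> postorder_edges;  // edge indices in postorder (child before parent use)
};

static TreeData make_tree(const arma::imat& edge, const arma::vec& blen, int ntip) {
  TreeData td;
  td.edge = edge;
  td.blen = blen;
  td.ntip = ntip;
  td.nnode = std::max((int)edge.max(), ntip);
  // postorder: repeatedly emit edges whose child subtree is complete
  int nedge = edge.n_rows;
  std::vector<int> nchild(td.nnode + 1, 0), done(td.nnode + 1, 0);
  for (int e = 0; e < nedge; ++e) nchild[edge(e, 0)]++;
  for (int i = 1; i <= td.ntip; ++i) done[i] = 1;
  std::vector<bool> used(nedge, false);
  td.postorder_edges.reserve(nedge);
  bool progress = true;
  while ((int)td.postorder_edges.size() < nedge && progress) {
    progress = false;
    for (int e = 0; e < nedge; ++e) {
      if (used[e]) continue;
      int child = edge(e, 1);
      if (done[child]) {
        used[e] = true;
        td.postorder_edges.push_back(e);
        int par = edge(e, 0);
        if (--nchild[par] == 0) done[par] = 1;
        progress = true;
      }
    }
  }
  if ((int)td.postorder_edges.size() < nedge)
    Rcpp::stop("edge matrix does not describe a rooted tree");
  return td;
}

// partials: (nnode+1) matrices NSTATE x npat; scalers accumulated per pattern.
static void prune_class(const TreeData& td, const arma::imat& tipstates,
                        const arma::mat& /*unused*/, const EigQ& eig,
                        const arma::vec& pi,
                        arma::vec& sitelik_log,           // out: log lik per pattern
                        std::vector<arma::mat>* keep_up,  // optional per-node partials
                        std::vector<arma::mat>* keep_P) { // optional per-edge P
  const int npat = tipstates.n_cols;
  const int nedge = td.edge.n_rows;
  std::vector<arma::mat> up(td.nnode + 1);
  arma::rowvec logscale(npat, arma::fill::zeros);
  // tip partials
  for (int i = 1; i <= td.ntip; ++i) {
    up[i] = arma::mat(NSTATE, npat, arma::fill::zeros);
    for (int s = 0; s < npat; ++s) {
      int st = tipstates(i - 1, s);
      if (st < 0) up[i].col(s).ones();   // missing data
      else up[i](st, s) = 1.0;
    }
  }
  if (keep_P) keep_P->assign(nedge, arma::mat());
  for (int idx = 0; idx < nedge; ++idx) {
    int e = td.postorder_edges[idx];
    int par = td.edge(e, 0), child = td.edge(e, 1);
    arma::mat P = pmat(eig, td.blen(e));
    if (keep_P) (*keep_P)[e] = P;
    arma::mat contrib = P * up[child];
    if (up[par].n_elem == 0) up[par] = contrib;
    else up[par] %= contrib;
    // rescale at the parent when all children so far processed could underflow
    arma::rowvec mx = arma::max(up[par], 0);
    mx.transform([](double v) { return v > 0 && v < 1e-280 ? v : 1.0; });
    if (arma::any(mx != 1.0)) {
      up[par].each_row() /= mx;
      logscale += arma::log(mx);
    }
  }
  int root = td.edge(td.postorder_edges[nedge - 1], 0);
  arma::rowvec lik = pi.t() * up[root];
  sitelik_log = (arma::log(lik) + logscale).t();
  if (keep_up) *keep_up = up;
}

// [[Rcpp::export]]
Rcpp::List cpp_mix_loglik(const arma::imat& tipstates, const arma::vec& weights,
                          const arma::imat& edge, const arma::vec& blen,
                          const arma::imat& pairtype, const arma::vec& pi,
                          double kappa, const arma::vec& omegas,
                          const arma::vec& probs, double scale,
                          bool want_sitelik) {
  const int ntip = tipstates.n_rows, npat = tipstates.n_cols;
  const int K = omegas.n_elem;
  TreeData td = make_tree(edge, blen * scale, ntip);
  std::vector<EigQ> eigs = class_eigs(pairtype, pi, kappa, omegas, probs);
  arma::mat loglik_k(K, npat);
  for (int k = 0; k < K; ++k) {
    arma::vec sl;
    prune_class(td, tipstates, arma::mat(), eigs[k], pi, sl, nullptr, nullptr);
    loglik_k.row(k) = sl.t();
  }
  // log-sum-exp over classes with weights probs
  arma::rowvec m = arma::max(loglik_k, 0);
  arma::rowvec mix(npat, arma::fill::zeros);
  for (int k = 0; k < K; ++k)
    mix += probs(k) * arma::exp(loglik_k.row(k) - m);
  arma::rowvec site_log = m + arma::log(mix);
  double ll = arma::dot(site_log.t(), weights);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loglik") = ll);
  if (want_sitelik) {
    out["site_loglik"] = arma::vec(site_log.t());
    out["class_loglik"] = loglik_k;  // K x npat, conditional log-likelihoods
  }
  return out;
}

// Expected number of labeled substitutions on a branch of length t:
//   M_L(t) = A ( (Ainv (Q o L) A) o J(t) ) Ainv,
//   J_ij = (exp(l_i t) - exp(l_j t)) / (l_i - l_j)   (t exp(l_i t) if equal)
static arma::mat count_integral(const EigQ& e, const arma::mat& QL, double t) {
  arma::mat G = e.Ainv * QL * e.A;
  arma::vec el = arma::exp(e.lambda * t);
  arma::mat J(NSTATE, NSTATE);
  for (int i = 0; i < NSTATE; ++i)
    for (int j = 0; j < NSTATE; ++j) {
      double d = e.lambda(i) - e.lambda(j);
      J(i, j) = (std::fabs(d) < 1e-12) ? t * el(i)
        : (el(i) - el(j)) / d;
    }
  return e.A * (G % J) * e.Ainv;
}

// Per-branch expected synonymous / nonsynonymous substitution counts, summed
// over sites, classes weighted by their posterior probability at each site.
// labels: 1 if pairtype in {1,2} (syn), 2 if in {3,4} (nonsyn).
// [[Rcpp::export]]
Rcpp::List cpp_expected_counts(const arma::imat& tipstates, const arma::vec& weights,
                               const arma::imat& edge, const arma::vec& blen,
                               const arma::imat& pairtype, const arma::vec& pi,
                               double kappa, const arma::vec& omegas,
                               const arma::vec& probs, double scale) {
  const int ntip = tipstates.n_rows, npat = tipstates.n_cols;
  const int K = omegas.n_elem;
  const int nedge = edge.n_rows;
  TreeData td = make_tree(edge, blen * scale, ntip);
  std::vector<arma::mat> Qs;
  std::vector<EigQ> eigs = class_eigs(pairtype, pi, kappa, omegas, probs, &Qs);

  // site class posteriors need class likelihoods first
  arma::mat loglik_k(K, npat);
  std::vector<std::vector<arma::mat>> ups(K);
  std::vector<std::vector<arma::mat>> Ps(K);
  for (int k = 0; k < K; ++k) {
    arma::vec sl;
    prune_class(td, tipstates, arma::mat(), eigs[k], pi, sl, &ups[k], &Ps[k]);
    loglik_k.row(k) = sl.t();
  }
  arma::rowvec m = arma::max(loglik_k, 0);
  arma::mat post(K, npat);
  for (int k = 0; k < K; ++k)
    post.row(k) = probs(k) * arma::exp(loglik_k.row(k) - m);
  post.each_row() /= arma::sum(post, 0);

  arma::mat nbS(nedge, 1, arma::fill::zeros), nbNS(nedge, 1, arma::fill::zeros);

  for (int k = 0; k < K; ++k) {
    // outside pass: H[e] = outside at parent restricted through other children
    // O[node]: outside partial (NSTATE x npat)
    std::vector<arma::mat> O(td.nnode + 1);
    int root = td.edge(td.postorder_edges[nedge - 1], 0);
    O[root] = arma::mat(NSTATE, npat);
    O[root].each_col() = pi;
    // children lists
    std::vector<std::vector<int>> child_edges(td.nnode + 1);
    for (int e = 0; e < nedge; ++e) child_edges[td.edge(e, 0)].push_back(e);
    // site likelihood per pattern for this class (unscaled ratios handled via
    // normalized quantities: use lik = pi' up[root], but partials were rescaled;
    // ratios H' M up / (pi' up) stay valid because scalers cancel per pattern
    // only if O carries the same scalers.  We therefore recompute likelihood
    // contributions pattern-wise using the scaled partials consistently.)
    arma::rowvec lik_root = arma::sum(ups[k][root].each_col() % pi, 0);
    // preorder over edges (reverse postorder)
    arma::mat QS = Qs[k], QN = Qs[k];
    for (int i = 0; i < NSTATE; ++i)
      for (int j = 0; j < NSTATE; ++j) {
        int pt = pairtype(i, j);
        QS(i, j) = (pt == 1 || pt == 2) ? Qs[k](i, j) : 0.0;
        QN(i, j) = (pt == 3 || pt == 4) ? Qs[k](i, j) : 0.0;
      }
    for (int idx = nedge - 1; idx >= 0; --idx) {
      int e = td.postorder_edges[idx];
      int par = td.edge(e, 0), child = td.edge(e, 1);
      // H = O[par] * prod_{sibling edges} P_sib up_sib
      arma::mat H = O[par];
      for (int se : child_edges[par]) {
        if (se == e) continue;
        H %= (Ps[k][se] * ups[k][td.edge(se, 1)]);
      }
      // expected counts on this branch for class k:
      //   count(s) = H(.,s)' M up_child(.,s) / lik(s)
      arma::mat MS = count_integral(eigs[k], QS, td.blen(e));
      arma::mat MN = count_integral(eigs[k], QN, td.blen(e));
      arma::rowvec lik = arma::sum((Ps[k][e] * ups[k][child]) % H, 0);
      arma::rowvec cS = arma::sum((MS * ups[k][child]) % H, 0) / lik;
      arma::rowvec cN = arma::sum((MN * ups[k][child]) % H, 0) / lik;
      nbS(e, 0) += arma::dot(cS.t() % post.row(k).t(), weights);
      nbNS(e, 0) += arma::dot(cN.t() % post.row(k).t(), weights);
      // outside for the child node
      O[child] = Ps[k][e].t() * H;
      // rescale to avoid under/overflow drifting across deep trees
      arma::rowvec mx = arma::max(O[child], 0);
      mx.transform([](double v) { return v > 0 && (v < 1e-280 || v > 1e280) ? v : 1.0; });
      if (arma::any(mx != 1.0)) O[child].each_row() /= mx;
    }
    (void)lik_root;
  }
  return Rcpp::List::create(Rcpp::Named("nbS") = arma::vec(nbS.col(0)),
                            Rcpp::Named("nbNS") = arma::vec(nbNS.col(0)),
                            Rcpp::Named("class_posterior") = post);
}

// Simulate one CTMC path per replicate from a fixed start state.
// Returns n x 3 matrix: end state (0-based), n_syn, n_nonsyn.
// [[Rcpp::export]]
arma::imat cpp_simulate_branch_paths(int start, const arma::mat& Q,
                                     const arma::imat& pairtype,
                                     double t, int n) {
  RNGScope scope;
  arma::imat out(n, 3);
  for (int r = 0; r < n; ++r) {
    int state = start;
    double time = 0.0;
    int ns = 0, nn = 0;
    while (true) {
      double rate = -Q(state, state);
      if (rate <= 0) break;
      time += R::exp_rand() / rate;
      if (time >= t) break;
      // draw destination
      double u = R::unif_rand() * rate, acc = 0.0;
      int dest = -1;
      for (int j = 0; j < NSTATE; ++j) {
        if (j == state) continue;
        acc += Q(state, j);
        if (u <= acc) { dest = j; break; }
      }
      if (dest < 0) dest = state == NSTATE - 1 ? NSTATE - 2 : NSTATE - 1;
      int pt = pairtype(state, dest);
      if (pt == 1 || pt == 2) ++ns; else ++nn;
      state = dest;
    }
    out(r, 0) = state; out(r, 1) = ns; out(r, 2) = nn;
  }
  return out;
}

// Evolve an alignment along a rooted tree.  site_class (0-based, length nsite)
// selects the generator for each site from Qlist.  Root states 0-based.
// Returns tip states plus realized per-branch syn/nonsyn counts and per-branch
// per-site counts.
// [[Rcpp::export]]
Rcpp::List cpp_simulate_alignment(const arma::imat& edge, const arma::vec& blen,
                                  int ntip, const arma::ivec& root_states,
                                  const arma::ivec& site_class,
                                  const Rcpp::List& Qlist,
                                  const arma::imat& pairtype) {
  RNGScope scope;
  const int nsite = root_states.n_elem;
  const int nedge = edge.n_rows;
  TreeData td = make_tree(edge, blen, ntip);
  std::vector<arma::mat> Qs(Qlist.size());
  for (int k = 0; k < (int)Qlist.size(); ++k) Qs[k] = Rcpp::as<arma::mat>(Qlist[k]);
  std::vector<arma::ivec> node_states(td.nnode + 1);
  int root = td.edge(td.postorder_edges[nedge - 1], 0);
  node_states[root] = root_states;
  arma::imat brS(nedge, nsite, arma::fill::zeros), brN(nedge, nsite, arma::fill::zeros);
  // preorder
  for (int idx = nedge - 1; idx >= 0; --idx) {
    int e = td.postorder_edges[idx];
    int par = td.edge(e, 0), child = td.edge(e, 1);
    double t = td.blen(e);
    arma::ivec st = node_states[par];
    for (int s = 0; s < nsite; ++s) {
      const arma::mat& Q = Qs[site_class(s)];
      int state = st(s);
      double time = 0.0;
      while (true) {
        double rate = -Q(state, state);
        if (rate <= 0) break;
        time += R::exp_rand() / rate;
        if (time >= t) break;
        double u = R::unif_rand() * rate, acc = 0.0;
        int dest = -1;
        for (int j = 0; j < NSTATE; ++j) {
          if (j == state) continue;
          acc += Q(state, j);
          if (u <= acc) { dest = j; break; }
        }
        if (dest < 0) dest = state == NSTATE - 1 ? NSTATE - 2 : NSTATE - 1;
        int pt = pairtype(state, dest);
        if (pt == 1 || pt == 2) brS(e, s)++; else brN(e, s)++;
        state = dest;
      }
      st(s) = state;
    }
    node_states[child] = st;
  }
  arma::imat tips(ntip, nsite);
  for (int i = 1; i <= ntip; ++i) tips.row(i - 1) = node_states[i].t();
  return Rcpp::List::create(Rcpp::Named("tipstates") = tips,
                            Rcpp::Named("branch_syn") = brS,
                            Rcpp::Named("branch_nonsyn") = brN);
}

// EM for mixture weights given per-class site likelihood ratios.
// L: K x npat (already exp-shifted), wpat: pattern counts.
// Returns the weight vector after EM (tol on lnL improvement).
// [[Rcpp::export]]
arma::vec cpp_profile_weights_em(const arma::mat& L, const arma::vec& wpat,
                                 const arma::vec& init, double tol,
                                 int max_iter) {
  const int K = L.n_rows;
  const double W = arma::accu(wpat);
  arma::vec p = init / arma::accu(init);
  arma::rowvec wt = wpat.t();
  double last = -arma::datum::inf;
  for (int it = 0; it < max_iter; ++it) {
    arma::rowvec mix = p.t() * L;
    double lnl = arma::dot(wt, arma::log(mix));
    if (lnl - last < tol && it > 0) break;
    last = lnl;
    p %= L * (wpat / mix.t());
    p /= W;
  }
  return p;
}
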