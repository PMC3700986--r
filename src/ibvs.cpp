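// MCMC core for integrative Bayesian variable selection with a probit link.
//
// The latent vector Z is marginally N(0, Sigma) with
//   Sigma = h * 1 1' + I_n + c * P_T,
// where P_T is the orthogonal projector onto the column space of the design T
// (one first-PLS-component column per selected pathway for iBVS; the raw
// selected gene columns for the YS baseline).  All likelihood evaluations use
// the low-rank structure: with Q an orthonormal basis of col(T),
//   A      = I + c Q Q',          A^{-1} = I - c/(1+c) Q Q',
//   u      = A^{-1} 1,            s      = 1 + h 1'u,
//   Sigma^{-1} = A^{-1} - (h/s) u u',   log|Sigma| = k log(1+c) + log(s).
// All randomness flows through R's RNG so chains are reproducible via set.seed.

#include <RcppArmadillo.h>
using namespace Rcpp;

// ---------------------------------------------------------------- truncated normal

// Standard normal truncated to (a, Inf); Robert (1995) tail rejection.
static double rtn_pos_std(double a) {
  if (a < 0.4) {
    double z;
    do { z = norm_rand(); } while (z <= a);
    return z;
  }
  const double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a + exp_rand() / alpha;
    double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
    if (unif_rand() <= rho) return z;
  }
}

// N(mu, sd^2) truncated to (0, Inf) if pos, else to (-Inf, 0].
static double rtn(double mu, double sd, bool pos) {
  if (pos) return mu + sd * rtn_pos_std(-mu / sd);
  return -(-mu + sd * rtn_pos_std(mu / sd));
}

// ---------------------------------------------------------------- marginal of Z

struct MargCache {
  arma::mat Q;     // n x k orthonormal basis of col(T)
  arma::vec u;     // A^{-1} 1
  double s;        // 1 + h 1'u
  double logdet;   // log|Sigma|
  int n;
  double c, h;
};

static void marg_update(MargCache& M, const arma::mat& Q) {
  M.Q = Q;
  const double cc = M.c / (1.0 + M.c);
  arma::vec ones(M.n, arma::fill::ones);
  if (Q.n_cols > 0) {
    arma::vec q1 = Q.t() * ones;
    M.u = ones - cc * (Q * q1);
  } else {
    M.u = ones;
  }
  M.s = 1.0 + M.h * arma::accu(M.u);
  M.logdet = (double)Q.n_cols * std::log1p(M.c) + std::log(M.s);
}

static double marg_logpdf(const MargCache& M, const arma::vec& Z) {
  const double cc = M.c / (1.0 + M.c);
  double quad = arma::dot(Z, Z);
  if (M.Q.n_cols > 0) {
    arma::vec qz = M.Q.t() * Z;
    quad -= cc * arma::dot(qz, qz);
  }
  const double uz = arma::dot(M.u, Z);
  quad -= (M.h / M.s) * uz * uz;
  return -0.5 * ((double)M.n * std::log(2.0 * M_PI) + M.logdet + quad);
}

static arma::mat marg_omega(const MargCache& M) {
  const double cc = M.c / (1.0 + M.c);
  arma::mat Om = arma::eye(M.n, M.n);
  if (M.Q.n_cols > 0) Om -= cc * (M.Q * M.Q.t());
  Om -= (M.h / M.s) * (M.u * M.u.t());
  return Om;
}

// One full Gibbs sweep of Z | theta, gamma, y (univariate truncated normals).
static void z_sweep(arma::vec& Z, const arma::ivec& y, const arma::mat& Om) {
  const int n = Z.n_elem;
  for (int i = 0; i < n; ++i) {
    const double oii = Om(i, i);
    const double dv = arma::dot(Om.col(i), Z) - oii * Z(i);
    const double mu = -dv / oii;
    const double sd = 1.0 / std::sqrt(oii);
    Z(i) = rtn(mu, sd, y(i) == 1);
  }
}

// ---------------------------------------------------------------- structure

struct Struct {
  std::vector<arma::uvec> pw;           // pathway -> member genes (sorted, 0-based)
  std::vector<std::vector<int>> memb;   // gene -> pathways
  std::vector<std::vector<int>> nbr;    // gene -> network neighbours
  int p, K;
};

static Struct make_struct(int p, const List& pathways, const List& neighbors) {
  Struct S;
  S.p = p;
  S.K = pathways.size();
  S.pw.resize(S.K);
  S.memb.assign(p, {});
  S.nbr.assign(p, {});
  for (int k = 0; k < S.K; ++k) {
    IntegerVector g = pathways[k];
    arma::uvec u(g.size());
    for (int i = 0; i < g.size(); ++i) u(i) = (arma::uword)(g[i] - 1);
    u = arma::sort(u);
    S.pw[k] = u;
    for (arma::uword i = 0; i < u.n_elem; ++i) S.memb[u(i)].push_back(k);
  }
  for (int j = 0; j < p; ++j) {
    IntegerVector nb = neighbors[j];
    for (int i = 0; i < nb.size(); ++i) S.nbr[j].push_back(nb[i] - 1);
  }
  return S;
}

// gene j and l share at least one *selected* pathway?
static bool share_selected(const Struct& S, const std::vector<int>& theta, int j, int l) {
  for (int k : S.memb[j]) {
    if (!theta[k]) continue;
    for (int k2 : S.memb[l]) if (k2 == k) return true;
  }
  return false;
}

// 0 = valid, 1/2/3 = constraint (a)/(b)/(c) violated.
static int validity_code(const Struct& S, const std::vector<int>& theta,
                         const std::vector<int>& gamma) {
  std::vector<std::vector<int>> selsets;
  for (int k = 0; k < S.K; ++k) {
    if (!theta[k]) continue;
    std::vector<int> ss;
    for (arma::uword i = 0; i < S.pw[k].n_elem; ++i) {
      int g = (int)S.pw[k](i);
      if (gamma[g]) ss.push_back(g);
    }
    if (ss.empty()) return 1;
    selsets.push_back(ss);
  }
  for (int j = 0; j < S.p; ++j) {
    if (!gamma[j]) continue;
    bool ok = false;
    for (int k : S.memb[j]) if (theta[k]) { ok = true; break; }
    if (!ok) return 2;
  }
  for (size_t i = 0; i < selsets.size(); ++i)
    for (size_t j = i + 1; j < selsets.size(); ++j)
      if (selsets[i] == selsets[j]) return 3;
  return 0;
}

// Joint log prior: independent Bernoulli(pi) on theta plus the unnormalised
// Ising/MRF mass on gamma restricted to members of selected pathways.
static double log_prior_state(const Struct& S, const std::vector<int>& theta,
                              const std::vector<int>& gamma,
                              double d, double f, double pi) {
  double lp = 0.0;
  for (int k = 0; k < S.K; ++k) lp += theta[k] ? std::log(pi) : std::log(1.0 - pi);
  int nsel = 0;
  double edges = 0.0;
  for (int j = 0; j < S.p; ++j) {
    if (!gamma[j]) continue;
    ++nsel;
    for (int l : S.nbr[j])
      if (l > j && gamma[l] && share_selected(S, theta, j, l)) edges += 1.0;
  }
  return lp + d * nsel + f * edges;
}

// ---------------------------------------------------------------- MH proposals

// genes of pathway k that are unselected and belong to no *other* selected pathway
static void free_excl(const Struct& S, const std::vector<int>& theta,
                      const std::vector<int>& gamma, int k, std::vector<int>& out) {
  out.clear();
  for (arma::uword i = 0; i < S.pw[k].n_elem; ++i) {
    int g = (int)S.pw[k](i);
    if (gamma[g]) continue;
    bool other = false;
    for (int kk : S.memb[g]) if (kk != k && theta[kk]) { other = true; break; }
    if (!other) out.push_back(g);
  }
}

// selected genes of selected pathway k that belong to no other selected pathway
static void excl_sel(const Struct& S, const std::vector<int>& theta,
                     const std::vector<int>& gamma, int k, std::vector<int>& out) {
  out.clear();
  for (arma::uword i = 0; i < S.pw[k].n_elem; ++i) {
    int g = (int)S.pw[k](i);
    if (!gamma[g]) continue;
    bool other = false;
    for (int kk : S.memb[g]) if (kk != k && theta[kk]) { other = true; break; }
    if (!other) out.push_back(g);
  }
}

static int count_C1(const Struct& S, const std::vector<int>& theta,
                    const std::vector<int>& gamma) {
  std::vector<int> tmp;
  int c = 0;
  for (int k = 0; k < S.K; ++k) {
    if (theta[k]) continue;
    free_excl(S, theta, gamma, k, tmp);
    if (!tmp.empty()) ++c;
  }
  return c;
}

static int count_C2(const Struct& S, const std::vector<int>& theta,
                    const std::vector<int>& gamma) {
  std::vector<int> tmp;
  int c = 0;
  for (int k = 0; k < S.K; ++k) {
    if (!theta[k]) continue;
    excl_sel(S, theta, gamma, k, tmp);
    if (!tmp.empty()) ++c;
  }
  return c;
}

// selected / unselected member counts of pathway k
static void sel_counts(const Struct& S, const std::vector<int>& gamma, int k,
                       int& nsel, int& nuns) {
  nsel = 0; nuns = 0;
  for (arma::uword i = 0; i < S.pw[k].n_elem; ++i) {
    if (gamma[S.pw[k](i)]) ++nsel; else ++nuns;
  }
}

static int count_C4(const Struct& S, const std::vector<int>& theta,
                    const std::vector<int>& gamma) {
  int c = 0, a, b;
  for (int k = 0; k < S.K; ++k) {
    if (!theta[k]) continue;
    sel_counts(S, gamma, k, a, b);
    if (a >= 1 && b >= 1) ++c;
  }
  return c;
}

// Total forward density of an M4 swap (j1 out, j2 in) summed over every
// selected pathway through which the same swap could have been proposed.
static double m4_density(const Struct& S, const std::vector<int>& theta,
                         const std::vector<int>& gamma, int j1, int j2) {
  const int C4 = count_C4(S, theta, gamma);
  if (C4 == 0) return 0.0;
  double q = 0.0;
  int a, b;
  for (int k = 0; k < S.K; ++k) {
    if (!theta[k]) continue;
    bool has1 = false, has2 = false;
    for (arma::uword i = 0; i < S.pw[k].n_elem; ++i) {
      int g = (int)S.pw[k](i);
      if (g == j1) has1 = true;
      if (g == j2) has2 = true;
    }
    if (!(has1 && has2)) continue;
    sel_counts(S, gamma, k, a, b);
    if (gamma[j1] == 1 && gamma[j2] == 0 && a >= 1 && b >= 1)
      q += 1.0 / ((double)C4 * a * b);
  }
  return q;
}

// Subset proposal for pathway addition: each free gene enters independently
// with a small probability q (conditioned on a nonempty pick), so new
// pathways arrive with a few seed genes that toggle/swap moves then refine.
static double subset_q(int m) { return std::min(0.5, 2.0 / (double)m); }

static double log_subset_prob(int m, int s) {
  const double q = subset_q(m);
  return s * std::log(q) + (m - s) * std::log1p(-q)
         - std::log1p(-std::pow(1.0 - q, m));
}

struct Prop {
  bool stuck = false;
  bool invalid = false;
  int type = 0;                 // 1..4
  std::vector<int> th, ga;
  double lqf = 0.0, lqr = 0.0;  // log forward / reverse proposal densities
};

static int sample_index(int n) { return (int)std::floor(unif_rand() * n) % n; }

static Prop propose_state(const Struct& S, const std::vector<int>& theta,
                          const std::vector<int>& gamma, const arma::vec& mp) {
  Prop P;
  double u = unif_rand();
  int type = 1;
  double acc = 0.0;
  for (int t = 0; t < 4; ++t) {
    acc += mp(t);
    if (u <= acc) { type = t + 1; break; }
    if (t == 3) type = 4;
  }
  P.type = type;
  P.th = theta;
  P.ga = gamma;
  std::vector<int> tmp;

  if (type == 1) {                       // add pathway + nonempty exclusive subset
    std::vector<int> C1;
    for (int k = 0; k < S.K; ++k) {
      if (theta[k]) continue;
      free_excl(S, theta, gamma, k, tmp);
      if (!tmp.empty()) C1.push_back(k);
    }
    if (C1.empty()) { P.stuck = true; return P; }
    int k = C1[sample_index((int)C1.size())];
    std::vector<int> F;
    free_excl(S, theta, gamma, k, F);
    const int m = (int)F.size();
    const double q = subset_q(m);
    std::vector<char> pick(m);
    int cnt = 0;
    do {
      cnt = 0;
      for (int i = 0; i < m; ++i) { pick[i] = unif_rand() < q; cnt += pick[i]; }
    } while (cnt == 0);
    P.th[k] = 1;
    for (int i = 0; i < m; ++i) if (pick[i]) P.ga[F[i]] = 1;
    P.lqf = std::log(mp(0)) - std::log((double)C1.size()) + log_subset_prob(m, cnt);
    P.lqr = std::log(mp(1)) - std::log((double)count_C2(S, P.th, P.ga));
  } else if (type == 2) {                // remove pathway + its exclusive genes
    std::vector<int> C2;
    for (int k = 0; k < S.K; ++k) {
      if (!theta[k]) continue;
      excl_sel(S, theta, gamma, k, tmp);
      if (!tmp.empty()) C2.push_back(k);
    }
    if (C2.empty()) { P.stuck = true; return P; }
    int k = C2[sample_index((int)C2.size())];
    std::vector<int> E;
    excl_sel(S, theta, gamma, k, E);
    P.th[k] = 0;
    for (int g : E) P.ga[g] = 0;
    P.lqf = std::log(mp(1)) - std::log((double)C2.size());
    std::vector<int> Fr;
    free_excl(S, P.th, P.ga, k, Fr);
    P.lqr = std::log(mp(0)) - std::log((double)count_C1(S, P.th, P.ga))
            + log_subset_prob((int)Fr.size(), (int)E.size());
  } else if (type == 3) {                // toggle one gene inside selected pathways
    std::vector<int> M;
    for (int j = 0; j < S.p; ++j) {
      bool in = false;
      for (int k : S.memb[j]) if (theta[k]) { in = true; break; }
      if (in) M.push_back(j);
    }
    if (M.empty()) { P.stuck = true; return P; }
    int j = M[sample_index((int)M.size())];
    P.ga[j] = 1 - P.ga[j];
    if (validity_code(S, P.th, P.ga) != 0) { P.invalid = true; return P; }
    P.lqf = std::log(mp(2)) - std::log((double)M.size());
    P.lqr = P.lqf;                       // member set unchanged by a gamma toggle
  } else {                               // swap within a selected pathway
    std::vector<int> C4;
    int a, b;
    for (int k = 0; k < S.K; ++k) {
      if (!theta[k]) continue;
      sel_counts(S, gamma, k, a, b);
      if (a >= 1 && b >= 1) C4.push_back(k);
    }
    if (C4.empty()) { P.stuck = true; return P; }
    int k = C4[sample_index((int)C4.size())];
    std::vector<int> selg, unsg;
    for (arma::uword i = 0; i < S.pw[k].n_elem; ++i) {
      int g = (int)S.pw[k](i);
      if (gamma[g]) selg.push_back(g); else unsg.push_back(g);
    }
    int j1 = selg[sample_index((int)selg.size())];
    int j2 = unsg[sample_index((int)unsg.size())];
    P.ga[j1] = 0;
    P.ga[j2] = 1;
    if (validity_code(S, P.th, P.ga) != 0) { P.invalid = true; return P; }
    P.lqf = std::log(mp(3)) + std::log(m4_density(S, theta, gamma, j1, j2));
    P.lqr = std::log(mp(3)) + std::log(m4_density(S, P.th, P.ga, j2, j1));
  }
  return P;
}

// ---------------------------------------------------------------- design builders

static arma::mat orth_basis(const arma::mat& T) {
  if (T.n_cols == 0) return arma::mat(T.n_rows, 0);
  return arma::orth(T);
}

// iBVS design: one first-PLS-component column per selected pathway.
static arma::mat build_T_ibvs(const arma::mat& X, const arma::vec& r, const Struct& S,
                              const std::vector<int>& theta, const std::vector<int>& gamma) {
  const int n = X.n_rows;
  std::vector<arma::vec> cols;
  for (int k = 0; k < S.K; ++k) {
    if (!theta[k]) continue;
    std::vector<arma::uword> idx;
    for (arma::uword i = 0; i < S.pw[k].n_elem; ++i)
      if (gamma[S.pw[k](i)]) idx.push_back(S.pw[k](i));
    arma::uvec ui(idx);
    arma::mat sub = X.cols(ui);
    arma::vec w = sub.t() * r;
    double nw = arma::norm(w);
    arma::vec t;
    if (nw < 1e-12) {               // degenerate PLS direction: first PC fallback
      arma::mat U, V;
      arma::vec sv;
      arma::svd_econ(U, sv, V, sub);
      t = sub * V.col(0);
    } else {
      t = sub * (w / nw);
    }
    cols.push_back(t);
  }
  arma::mat T(n, (int)cols.size());
  for (size_t j = 0; j < cols.size(); ++j) T.col((arma::uword)j) = cols[j];
  return T;
}

// ---------------------------------------------------------------- exported pieces

// [[Rcpp::export]]
NumericVector cpp_z_sweep(NumericVector Z0, IntegerVector y, const arma::mat& Omega) {
  arma::vec Z(Z0.begin(), Z0.size());
  arma::ivec yy(y.size());
  for (int i = 0; i < y.size(); ++i) yy(i) = y[i];
  z_sweep(Z, yy, Omega);
  return NumericVector(Z.begin(), Z.end());
}

// [[Rcpp::export]]
double cpp_logmarg_Z(const arma::vec& Z, const arma::mat& T, double c, double h) {
  MargCache M;
  M.n = Z.n_elem; M.c = c; M.h = h;
  marg_update(M, orth_basis(T));
  return marg_logpdf(M, Z);
}

// [[Rcpp::export]]
List cpp_propose(IntegerVector theta, IntegerVector gamma, List pathways,
                 List neighbors, NumericVector move_probs) {
  Struct S = make_struct(gamma.size(), pathways, neighbors);
  std::vector<int> th(theta.begin(), theta.end()), ga(gamma.begin(), gamma.end());
  arma::vec mp(move_probs.begin(), move_probs.size());
  Prop P = propose_state(S, th, ga, mp);
  return List::create(
    _["theta"] = IntegerVector(P.th.begin(), P.th.end()),
    _["gamma"] = IntegerVector(P.ga.begin(), P.ga.end()),
    _["type"] = P.type, _["stuck"] = P.stuck, _["invalid"] = P.invalid,
    _["log_q_fwd"] = P.lqf, _["log_q_rev"] = P.lqr);
}

// ---------------------------------------------------------------- full chains

// [[Rcpp::export]]
List cpp_run_ibvs(const arma::mat& X, IntegerVector y, List pathways, List neighbors,
                  double c, double h, double d, double f, double pi_theta,
                  NumericVector move_probs, int burn, int kept, int store_every,
                  int mh_per_sweep = 1) {
  const int n = X.n_rows, p = X.n_cols;
  Struct S = make_struct(p, pathways, neighbors);
  arma::ivec yy(n);
  arma::vec r(n);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) { yy(i) = y[i]; ybar += y[i]; }
  ybar /= n;
  for (int i = 0; i < n; ++i) r(i) = y[i] - ybar;
  arma::vec mp(move_probs.begin(), move_probs.size());

  std::vector<int> theta(S.K, 0), gamma(p, 0);
  MargCache M;
  M.n = n; M.c = c; M.h = h;
  marg_update(M, arma::mat(n, 0));
  arma::mat Om = marg_omega(M);
  double lp_cur = log_prior_state(S, theta, gamma, d, f, pi_theta);

  arma::vec Z(n);
  for (int i = 0; i < n; ++i) Z(i) = rtn(0.0, 1.0, yy(i) == 1);

  arma::vec gene_cnt(p, arma::fill::zeros), pw_cnt(S.K, arma::fill::zeros);
  NumericVector logpost(kept), model_size(kept);
  IntegerVector acc(4), prop_cnt(4);
  int stuck = 0, invalid = 0;
  const int n_store = store_every > 0 ? kept / store_every : 0;
  IntegerMatrix store_g(n_store, p), store_t(n_store, S.K);
  int srow = 0;

  const int total = burn + kept;
  for (int it = 0; it < total; ++it) {
    z_sweep(Z, yy, Om);
    double lm_cur = marg_logpdf(M, Z);

    bool changed = false;
    for (int s_it = 0; s_it < mh_per_sweep; ++s_it) {
      Prop P = propose_state(S, theta, gamma, mp);
      if (P.stuck) {
        ++stuck;
        continue;
      }
      prop_cnt[P.type - 1]++;
      if (P.invalid) {
        ++invalid;
        continue;
      }
      arma::mat Tn = build_T_ibvs(X, r, S, P.th, P.ga);
      MargCache Mn;
      Mn.n = n; Mn.c = c; Mn.h = h;
      marg_update(Mn, orth_basis(Tn));
      double lm_new = marg_logpdf(Mn, Z);
      double lp_new = log_prior_state(S, P.th, P.ga, d, f, pi_theta);
      double la = (lm_new + lp_new) - (lm_cur + lp_cur) + (P.lqr - P.lqf);
      if (la >= 0.0 || std::log(unif_rand()) < la) {
        theta = P.th; gamma = P.ga;
        M = Mn;
        lp_cur = lp_new; lm_cur = lm_new;
        acc[P.type - 1]++;
        changed = true;
      }
    }
    if (changed) Om = marg_omega(M);

    if (it >= burn) {
      const int j = it - burn;
      int ms = 0;
      for (int g = 0; g < p; ++g) if (gamma[g]) { gene_cnt(g) += 1.0; ++ms; }
      for (int k = 0; k < S.K; ++k) if (theta[k]) pw_cnt(k) += 1.0;
      logpost[j] = lm_cur + lp_cur;
      model_size[j] = ms;
      if (store_every > 0 && (j % store_every) == 0 && srow < n_store) {
        for (int g = 0; g < p; ++g) store_g(srow, g) = gamma[g];
        for (int k = 0; k < S.K; ++k) store_t(srow, k) = theta[k];
        ++srow;
      }
    }
  }

  return List::create(
    _["gene_freq"] = NumericVector(gene_cnt.begin(), gene_cnt.end()) / (double)kept,
    _["pathway_freq"] = NumericVector(pw_cnt.begin(), pw_cnt.end()) / (double)kept,
    _["logpost"] = logpost, _["model_size"] = model_size,
    _["accepted"] = acc, _["proposed"] = prop_cnt,
    _["stuck"] = stuck, _["invalid"] = invalid,
    _["draws_gamma"] = store_g, _["draws_theta"] = store_t);
}

// YS-BVS baseline: gene-only probit BVS, prior N(0, c (X_g' X_g)^+) on the raw
// selected columns, independent Bernoulli(rate) on gamma, add/remove/swap moves.
// [[Rcpp::export]]
List cpp_run_ys(const arma::mat& X, IntegerVector y, double c, double h, double rate,
                NumericVector move_probs, int burn, int kept, int store_every) {
  const int n = X.n_rows, p = X.n_cols;
  arma::ivec yy(n);
  for (int i = 0; i < n; ++i) yy(i) = y[i];
  arma::vec mp(move_probs.begin(), move_probs.size());
  const double lr1 = std::log(rate), lr0 = std::log(1.0 - rate);

  std::vector<int> gamma(p, 0);
  int ns = 0;
  MargCache M;
  M.n = n; M.c = c; M.h = h;
  marg_update(M, arma::mat(n, 0));
  arma::mat Om = marg_omega(M);
  double lp_cur = p * lr0;

  arma::vec Z(n);
  for (int i = 0; i < n; ++i) Z(i) = rtn(0.0, 1.0, yy(i) == 1);

  arma::vec gene_cnt(p, arma::fill::zeros);
  NumericVector logpost(kept), model_size(kept);
  IntegerVector acc(3), prop_cnt(3);
  int stuck = 0;
  const int n_store = store_every > 0 ? kept / store_every : 0;
  IntegerMatrix store_g(n_store, p);
  int srow = 0;

  auto design_Q = [&](const std::vector<int>& g, int nsel) {
    if (nsel == 0) return arma::mat(n, 0);
    arma::uvec idx(nsel);
    int j = 0;
    for (int i = 0; i < p; ++i) if (g[i]) idx(j++) = (arma::uword)i;
    return orth_basis(X.cols(idx));
  };

  const int total = burn + kept;
  for (int it = 0; it < total; ++it) {
    z_sweep(Z, yy, Om);
    double lm_cur = marg_logpdf(M, Z);

    // choose move: 0 add, 1 remove, 2 swap
    double u = unif_rand();
    int type = (u <= mp(0)) ? 0 : (u <= mp(0) + mp(1) ? 1 : 2);
    std::vector<int> gn = gamma;
    double lqf = 0.0, lqr = 0.0;
    bool ok = true;
    if (type == 0) {
      if (ns == p) ok = false;
      else {
        int pick = sample_index(p - ns), seen = 0, j = -1;
        for (int i = 0; i < p; ++i) if (!gamma[i]) { if (seen++ == pick) { j = i; break; } }
        gn[j] = 1;
        lqf = std::log(mp(0)) - std::log((double)(p - ns));
        lqr = std::log(mp(1)) - std::log((double)(ns + 1));
      }
    } else if (type == 1) {
      if (ns == 0) ok = false;
      else {
        int pick = sample_index(ns), seen = 0, j = -1;
        for (int i = 0; i < p; ++i) if (gamma[i]) { if (seen++ == pick) { j = i; break; } }
        gn[j] = 0;
        lqf = std::log(mp(1)) - std::log((double)ns);
        lqr = std::log(mp(0)) - std::log((double)(p - ns + 1));
      }
    } else {
      if (ns == 0 || ns == p) ok = false;
      else {
        int p1 = sample_index(ns), p2 = sample_index(p - ns), seen = 0;
        int j1 = -1, j2 = -1;
        for (int i = 0; i < p; ++i) if (gamma[i]) { if (seen++ == p1) { j1 = i; break; } }
        seen = 0;
        for (int i = 0; i < p; ++i) if (!gamma[i]) { if (seen++ == p2) { j2 = i; break; } }
        gn[j1] = 0; gn[j2] = 1;
        lqf = lqr = 0.0;                // symmetric: same counts after swap
      }
    }

    if (!ok) {
      ++stuck;
    } else {
      prop_cnt[type]++;
      int ns_new = ns + (type == 0 ? 1 : (type == 1 ? -1 : 0));
      MargCache Mn;
      Mn.n = n; Mn.c = c; Mn.h = h;
      marg_update(Mn, design_Q(gn, ns_new));
      double lm_new = marg_logpdf(Mn, Z);
      double lp_new = ns_new * lr1 + (p - ns_new) * lr0;
      double la = (lm_new + lp_new) - (lm_cur + lp_cur) + (lqr - lqf);
      if (la >= 0.0 || std::log(unif_rand()) < la) {
        gamma = gn; ns = ns_new;
        M = Mn; Om = marg_omega(M);
        lp_cur = lp_new; lm_cur = lm_new;
        acc[type]++;
      }
    }

    if (it >= burn) {
      const int j = it - burn;
      for (int g = 0; g < p; ++g) if (gamma[g]) gene_cnt(g) += 1.0;
      logpost[j] = lm_cur + lp_cur;
      model_size[j] = ns;
      if (store_every > 0 && (j % store_every) == 0 && srow < n_store) {
        for (int g = 0; g < p; ++g) store_g(srow, g) = gamma[g];
        ++srow;
      }
    }
  }

  return List::create(
    _["gene_freq"] = NumericVector(gene_cnt.begin(), gene_cnt.end()) / (double)kept,
    _["logpost"] = logpost, _["model_size"] = model_size,
    _["accepted"] = acc, _["proposed"] = prop_cnt, _["stuck"] = stuck,
    _["draws_gamma"] = store_g);
}

// [[Rcpp::export]]
int cpp_validity_code(IntegerVector theta, IntegerVector gamma, List pathways,
                      List neighbors) {
  Struct S = make_struct(gamma.size(), pathways, neighbors);
  std::vector<int> th(theta.begin(), theta.end()), ga(gamma.begin(), gamma.end());
  return validity_code(S, th, ga);
}
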