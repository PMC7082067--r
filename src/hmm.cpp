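// Pairwise SMC' hidden Markov model over discretized tMRCA.
//
// Hidden state: the time interval containing the local pairwise tMRCA.
// Transitions across a window of the sequence follow the SMC' process: a
// recombination falls on the local tree (two branches of length t) with
// probability 1 - exp(-2 rho t); the cut point u is uniform on (0, t); the
// floating lineage then re-coalesces, at rate 2*lambda below t (half of
// which rejoins its own branch, restoring t) and rate lambda above t.
// For piecewise-constant lambda all integrals have closed forms; the
// matrix is built in O(K^2) from prefix quantities.
//
// Emissions: a window (bin) of n called sites with j heterozygous sites
// has probability (1-p)^(n-j) p^j with p = 1 - exp(-2 t_k mu) at the
// interval's representative time t_k; phase-ambiguous sites contribute a
// constant factor 1/2 (average of the het and hom phasings).

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// (1 - exp(-x)) / x, stable for small x
static inline double em1x(double x) {
  if (std::fabs(x) < 1e-8) return 1.0 - 0.5 * x;
  return -std::expm1(-x) / x;
}

// SMC' transition matrix for one window.
// tau: K left boundaries (tau[0] = 0, generations); lambda: K hazards
// (per generation, > 0); trep: K representative times (tau[k] < trep[k] <
// tau[k+1]); rho2: twice the per-window per-generation recombination rate
// (so the recombination probability from state k is 1 - exp(-rho2 *
// trep[k])).
// [[Rcpp::export(name = ".cpp_smc_transition")]]
NumericMatrix cpp_smc_transition(NumericVector tau, NumericVector lambda,
                                 NumericVector trep, double rho2) {
  const int K = tau.size();
  // G(s) = Int_0^s exp(-2 (Lambda(s) - Lambda(u))) du, the density kernel
  // of the recombination point; computed at boundaries by the stable
  // recursion G(tau_{i+1}) = e^{-2 lam_i w} G(tau_i) + (1-e^{-2 lam_i w})
  // / (2 lam_i). Bounded by min(s, 1/(2 lambda)).
  std::vector<double> Gb(K);
  Gb[0] = 0.0;
  for (int i = 0; i + 1 < K; ++i) {
    const double w = tau[i + 1] - tau[i];
    const double g = 2.0 * lambda[i] * w;
    Gb[i + 1] = std::exp(-g) * Gb[i] + w * em1x(g);
  }
  // G at a point x inside interval l, measured from tau[l]
  auto G_at = [&](int l, double x) {
    const double g = 2.0 * lambda[l] * x;
    return std::exp(-g) * Gb[l] + x * em1x(g);
  };

  NumericMatrix A(K, K);
  for (int j = 0; j < K; ++j) {
    const double t = trep[j];
    const double r = -std::expm1(-rho2 * t);
    const double nr = 1.0 - r;
    const double lamj = lambda[j];
    const double Gt = G_at(j, t - tau[j]);
    // partner re-coalescence mass below t falling in [a, b] of interval l:
    // (lambda_l / t) Int_a^b G(s) ds, with G(s) = e^{-2 lam x} G(a)
    // + (1 - e^{-2 lam x})/(2 lam), x = s - a
    auto below_piece = [&](int l, double a, double b) {
      const double w = b - a;
      if (w <= 0) return 0.0;
      const double lam = lambda[l];
      const double Ga = G_at(l, a - tau[l]);
      const double g = 2.0 * lam * w;
      const double wem = w * em1x(g);
      const double i1 = Ga * wem;                 // Int G(a) e^{-2 lam x}
      const double i2 = (w - wem) / (2.0 * lam);  // Int (1-e^{-2 lam x})/(2 lam)
      return (lam / t) * (i1 + i2);
    };
    double t_below = 0.0;
    for (int l = 0; l < j; ++l) {
      const double m = below_piece(l, tau[l], tau[l + 1]);
      A(j, l) += r * m;
      t_below += m;
    }
    const double mj = below_piece(j, tau[j], t);
    A(j, j) += r * mj;
    t_below += mj;
    // own-branch re-coalescence (restores t) has the same total mass
    A(j, j) += nr + r * t_below;
    // mass above t: survive to t with weight J, then coalesce at rate lambda
    const double J = Gt / t;
    // within interval j, (t, tau[j+1])
    double surv = 1.0;  // exp(-Lambda(t, s)) running from s = t
    if (j + 1 < K) {
      const double rest = tau[j + 1] - t;
      const double dec = std::exp(-lamj * rest);
      A(j, j) += r * J * (surv - dec);
      surv *= dec;
      for (int l = j + 1; l < K; ++l) {
        double dec2 = (l + 1 < K)
          ? std::exp(-lambda[l] * (tau[l + 1] - tau[l])) : 0.0;
        A(j, l) += r * J * (surv - surv * dec2);
        surv *= dec2;
      }
    } else {
      A(j, j) += r * J * surv;  // open-ended last interval
    }
    // guard round-off: renormalize row
    double s = 0.0;
    for (int l = 0; l < K; ++l) s += A(j, l);
    for (int l = 0; l < K; ++l) A(j, l) /= s;
  }
  return A;
}

// marginal interval probabilities of the tMRCA under piecewise lambda
// [[Rcpp::export(name = ".cpp_tmrca_marginal")]]
NumericVector cpp_tmrca_marginal(NumericVector tau, NumericVector lambda) {
  const int K = tau.size();
  NumericVector pi(K);
  double cum = 0.0, Sprev = 1.0;
  for (int i = 0; i + 1 < K; ++i) {
    cum += lambda[i] * (tau[i + 1] - tau[i]);
    const double S = std::exp(-cum);
    pi[i] = Sprev - S;
    Sprev = S;
  }
  pi[K - 1] = Sprev;
  return pi;
}

// emission cache: bins share few distinct (hom, het, amb) patterns, so
// emission vectors are built once per pattern (hom rounded to the nearest
// called site) and the passes below use plain loops over K states.
struct EmissionCache {
  std::unordered_map<long long, int> index;
  std::vector<double> cols;  // column-major K x n_classes
  int K;
  const double *lp, *l1p;
  double lhalf;
  EmissionCache(int K_, const double* lp_, const double* l1p_)
    : K(K_), lp(lp_), l1p(l1p_), lhalf(std::log(0.5)) {}
  // class id; pointers into cols are only stable once no more ids are
  // created, so callers collect ids first and fetch columns afterwards
  int id(double hom, int het, int amb) {
    const long long h = (long long)(hom + 0.5);
    const long long key = (h * 1000 + het) * 1000 + std::min(amb, 999);
    auto it = index.find(key);
    if (it != index.end()) return it->second;
    const int id = index.size();
    index.emplace(key, id);
    cols.resize((size_t)(id + 1) * K);
    double* c = &cols[(size_t)id * K];
    for (int k = 0; k < K; ++k)
      c[k] = std::exp(h * l1p[k] + het * lp[k] + amb * lhalf);
    return id;
  }
  const double* col(int id) const { return &cols[(size_t)id * K]; }
};

// forward-backward over one binned observation sequence.
// hom: (possibly fractional) homozygous called sites per bin; het, amb:
// counts of heterozygous / phase-ambiguous sites per bin.
// Returns log-likelihood, expected transition counts (K x K), and the
// posterior of the first bin's state.
// [[Rcpp::export(name = ".cpp_hmm_estep")]]
List cpp_hmm_estep(NumericVector hom, IntegerVector het, IntegerVector amb,
                   NumericVector pi, NumericMatrix A, NumericVector p_het) {
  const int T = hom.size(), K = pi.size();
  if (T == 0) stop("empty observation sequence");
  std::vector<double> lp(K), l1p(K);
  for (int k = 0; k < K; ++k) {
    lp[k] = std::log(p_het[k]);
    l1p[k] = std::log1p(-p_het[k]);
  }
  EmissionCache em(K, lp.data(), l1p.data());
  std::vector<int> Eid(T);
  for (int t = 0; t < T; ++t) Eid[t] = em.id(hom[t], het[t], amb[t]);
  std::vector<const double*> E(T);
  for (int t = 0; t < T; ++t) E[t] = em.col(Eid[t]);
  // row-major copy of A: a[j*K + l] = A(j, l)
  std::vector<double> a((size_t)K * K);
  for (int j = 0; j < K; ++j)
    for (int l = 0; l < K; ++l) a[(size_t)j * K + l] = A(j, l);
  std::vector<double> alpha((size_t)T * K);
  std::vector<double> cscale(T);
  double loglik = 0.0;
  {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha[k] = pi[k] * E[0][k];
      s += alpha[k];
    }
    cscale[0] = s;
    for (int k = 0; k < K; ++k) alpha[k] /= s;
    loglik += std::log(s);
  }
  std::vector<double> pred(K);
  for (int t = 1; t < T; ++t) {
    double* at = &alpha[(size_t)t * K];
    const double* ap = &alpha[(size_t)(t - 1) * K];
    std::fill(pred.begin(), pred.end(), 0.0);
    for (int j = 0; j < K; ++j) {
      const double aj = ap[j];
      if (aj == 0.0) continue;
      const double* arow = &a[(size_t)j * K];
      for (int l = 0; l < K; ++l) pred[l] += aj * arow[l];
    }
    double s = 0.0;
    const double* e = E[t];
    for (int l = 0; l < K; ++l) {
      at[l] = pred[l] * e[l];
      s += at[l];
    }
    cscale[t] = s;
    for (int l = 0; l < K; ++l) at[l] /= s;
    loglik += std::log(s);
  }
  // backward with transition-count accumulation
  std::vector<double> beta(K, 1.0), eb(K), nbeta(K);
  std::vector<double> C((size_t)K * K, 0.0);
  for (int t = T - 2; t >= 0; --t) {
    const double* e = E[t + 1];
    const double invc = 1.0 / cscale[t + 1];
    for (int l = 0; l < K; ++l) eb[l] = e[l] * beta[l] * invc;
    const double* ap = &alpha[(size_t)t * K];
    for (int j = 0; j < K; ++j) {
      const double aj = ap[j];
      const double* arow = &a[(size_t)j * K];
      double* crow = &C[(size_t)j * K];
      double bj = 0.0;
      for (int l = 0; l < K; ++l) {
        const double x = arow[l] * eb[l];
        crow[l] += aj * x;
        bj += x;
      }
      nbeta[j] = bj;
    }
    beta.swap(nbeta);
  }
  NumericVector gamma0(K);
  double g0s = 0.0;
  for (int k = 0; k < K; ++k) {
    gamma0[k] = alpha[k] * beta[k];
    g0s += gamma0[k];
  }
  for (int k = 0; k < K; ++k) gamma0[k] /= g0s;
  NumericMatrix Cout(K, K);
  for (int j = 0; j < K; ++j)
    for (int l = 0; l < K; ++l) Cout(j, l) = C[(size_t)j * K + l];
  return List::create(_["loglik"] = loglik,
                      _["counts"] = Cout,
                      _["gamma0"] = gamma0);
}

// posterior state probabilities for every bin (diagnostics / tests)
// [[Rcpp::export(name = ".cpp_hmm_posterior")]]
NumericMatrix cpp_hmm_posterior(NumericVector hom, IntegerVector het,
                                IntegerVector amb, NumericVector pi,
                                NumericMatrix A, NumericVector p_het) {
  const int T = hom.size(), K = pi.size();
  std::vector<double> lp(K), l1p(K);
  for (int k = 0; k < K; ++k) {
    lp[k] = std::log(p_het[k]);
    l1p[k] = std::log1p(-p_het[k]);
  }
  EmissionCache em(K, lp.data(), l1p.data());
  std::vector<int> Eid(T);
  for (int t = 0; t < T; ++t) Eid[t] = em.id(hom[t], het[t], amb[t]);
  std::vector<const double*> E(T);
  for (int t = 0; t < T; ++t) E[t] = em.col(Eid[t]);
  arma::mat At(K, K);
  for (int j = 0; j < K; ++j)
    for (int l = 0; l < K; ++l) At(j, l) = A(j, l);
  arma::mat alpha(K, T), gamma(K, T);
  std::vector<double> cscale(T);
  for (int k = 0; k < K; ++k) alpha(k, 0) = pi[k] * E[0][k];
  cscale[0] = arma::accu(alpha.col(0)); alpha.col(0) /= cscale[0];
  for (int t = 1; t < T; ++t) {
    arma::vec e(const_cast<double*>(E[t]), K, false, true);
    alpha.col(t) = (At.t() * alpha.col(t - 1)) % e;
    cscale[t] = arma::accu(alpha.col(t));
    alpha.col(t) /= cscale[t];
  }
  arma::vec beta(K, arma::fill::ones);
  gamma.col(T - 1) = alpha.col(T - 1);
  for (int t = T - 2; t >= 0; --t) {
    arma::vec e(const_cast<double*>(E[t + 1]), K, false, true);
    beta = (At * (e % beta)) / cscale[t + 1];
    gamma.col(t) = alpha.col(t) % beta;
    gamma.col(t) /= arma::accu(gamma.col(t));
  }
  return wrap(gamma.t().eval());
}

// backward-pass total likelihood, for the forward/backward agreement check
// [[Rcpp::export(name = ".cpp_hmm_loglik_backward")]]
double cpp_hmm_loglik_backward(NumericVector hom, IntegerVector het,
                               IntegerVector amb, NumericVector pi,
                               NumericMatrix A, NumericVector p_het) {
  const int T = hom.size(), K = pi.size();
  std::vector<double> lp(K), l1p(K);
  for (int k = 0; k < K; ++k) {
    lp[k] = std::log(p_het[k]);
    l1p[k] = std::log1p(-p_het[k]);
  }
  EmissionCache em(K, lp.data(), l1p.data());
  std::vector<int> Eid(T);
  for (int t = 0; t < T; ++t) Eid[t] = em.id(hom[t], het[t], amb[t]);
  arma::mat At(K, K);
  for (int j = 0; j < K; ++j)
    for (int l = 0; l < K; ++l) At(j, l) = A(j, l);
  arma::vec beta(K, arma::fill::ones);
  double loglik = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    const double* e1 = em.col(Eid[t + 1]);
    arma::vec eb(K);
    for (int k = 0; k < K; ++k) eb[k] = e1[k] * beta[k];
    beta = At * eb;
    const double s = arma::accu(beta) / K;
    beta /= s;
    loglik += std::log(s);
  }
  const double* e0 = em.col(Eid[0]);
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += pi[k] * e0[k] * beta[k];
  return loglik + std::log(tot);
}

// expected complete-data objective for the M-step:
// sum_j gamma0[j] log pi_j(lambda) + sum_jl C[j][l] log A[j][l](lambda, rho)
// [[Rcpp::export(name = ".cpp_hmm_q")]]
double cpp_hmm_q(NumericVector tau, NumericVector lambda, NumericVector trep,
                 double rho2, NumericMatrix C, NumericVector gamma0) {
  const int K = tau.size();
  NumericMatrix A = cpp_smc_transition(tau, lambda, trep, rho2);
  NumericVector pi = cpp_tmrca_marginal(tau, lambda);
  double q = 0.0;
  for (int j = 0; j < K; ++j) {
    if (gamma0[j] > 0) q += gamma0[j] * std::log(std::max(pi[j], 1e-300));
    for (int l = 0; l < K; ++l)
      if (C(j, l) > 0) q += C(j, l) * std::log(std::max(A(j, l), 1e-300));
  }
  return q;
}

// bin the (position, called, het-code) stream of one chromosome/pair:
// het codes: 0 = site homozygous for the pair, 1 = heterozygous,
// 2 = phase-ambiguous. Called sites between records are allocated to bins
// proportionally to overlap.
// [[Rcpp::export(name = ".cpp_bin_observations")]]
List cpp_bin_observations(IntegerVector pos, IntegerVector called,
                          IntegerVector hetcode, int bin, int n_bins) {
  const int n = pos.size();
  NumericVector hom(n_bins);
  IntegerVector het(n_bins), amb(n_bins);
  int prev = 0;
  for (int i = 0; i < n; ++i) {
    const int p = pos[i];
    int b = (p - 1) / bin;
    if (b >= n_bins) b = n_bins - 1;
    if (hetcode[i] == 1) het[b] += 1;
    else if (hetcode[i] == 2) amb[b] += 1;
    else hom[b] += 1.0;
    // remaining called - 1 homozygous sites spread over (prev, p - 1]
    const double extra = called[i] - 1;
    const int lo = prev + 1, hi = p - 1;
    if (extra > 0 && hi >= lo) {
      const double dens = extra / double(hi - lo + 1);
      int b0 = (lo - 1) / bin, b1 = (hi - 1) / bin;
      if (b1 >= n_bins) b1 = n_bins - 1;
      for (int bb = b0; bb <= b1; ++bb) {
        const int blo = bb * bin + 1, bhi = (bb + 1) * bin;
        const int olo = std::max(lo, blo), ohi = std::min(hi, bhi);
        if (ohi >= olo) hom[bb] += dens * (ohi - olo + 1);
      }
    }
    prev = p;
  }
  return List::create(_["hom"] = hom, _["het"] = het, _["amb"] = amb);
}
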