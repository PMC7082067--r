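// Two-island isolation-migration forward model.
//
// The pair of lineages lives on a 4-state continuous-time Markov chain with
// states ordered (S11, S12, S22, C): both lineages in island 1, one in each,
// both in island 2, coalesced (absorbing). Per-generation rates:
//   S12 -> S11: m/2     S12 -> S22: m/2
//   S11 -> C: 1/(2 N1)  S22 -> C: 1/(2 N2)
// Migration acts on separated pairs only: a cross pair merges into a
// common island at total rate m(t), so the cumulative migration
// probability M(t) = 1 - exp(-Int m) is exactly the probability that a
// cross pair has merged by t, and the within-island states map one-to-one
// onto the within-population coalescence rates (sizes remain close to
// inverse rates). Parameters are piecewise constant on the time grid; the
// occupancy vector is propagated across segments by chained dense matrix
// exponentials.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat generator(double m, double N1, double N2) {
  arma::mat Q(4, 4, arma::fill::zeros);
  const double c1 = 1.0 / (2.0 * N1), c2 = 1.0 / (2.0 * N2);
  Q(0, 3) = c1;
  Q(1, 0) = 0.5 * m;  Q(1, 2) = 0.5 * m;
  Q(2, 3) = c2;
  Q(0, 0) = -Q(0, 3);
  Q(1, 1) = -(Q(1, 0) + Q(1, 2));
  Q(2, 2) = -Q(2, 3);
  return Q;
}

// [[Rcpp::export(name = ".cpp_im_generator")]]
NumericMatrix cpp_im_generator(double m, double N1, double N2) {
  if (!std::isfinite(m) || !std::isfinite(N1) || !std::isfinite(N2))
    stop("non-finite generator parameters");
  return wrap(generator(m, N1, N2));
}

// generic dense matrix exponential (used by the scenario CTMC engine too)
// [[Rcpp::export(name = ".cpp_expm")]]
NumericMatrix cpp_expm(NumericMatrix A) {
  arma::mat M = as<arma::mat>(A);
  return wrap(arma::expmat(M).eval());
}

// occupancy vectors for the three start states at every segment left
// boundary: returns a cube flattened as list of three K x 4 matrices
// b: K left boundaries (generations, b[0] = 0); N1, N2, m: per segment
static void boundary_states(const arma::vec& b, const arma::vec& N1,
                            const arma::vec& N2, const arma::vec& m,
                            arma::cube& P) {
  const arma::uword K = b.n_elem;
  P.set_size(3, 4, K);
  arma::mat cur(3, 4, arma::fill::zeros);
  cur(0, 0) = 1.0; cur(1, 1) = 1.0; cur(2, 2) = 1.0;
  P.slice(0) = cur;
  for (arma::uword i = 0; i + 1 < K; ++i) {
    const double dt = b(i + 1) - b(i);
    arma::mat T = arma::expmat(generator(m(i), N1(i), N2(i)) * dt);
    cur = cur * T;
    P.slice(i + 1) = cur;
  }
}

// [[Rcpp::export(name = ".cpp_im_boundary_states")]]
List cpp_im_boundary_states(NumericVector b, NumericVector N1,
                            NumericVector N2, NumericVector m) {
  arma::vec bb = as<arma::vec>(b);
  arma::cube P;
  boundary_states(bb, as<arma::vec>(N1), as<arma::vec>(N2), as<arma::vec>(m), P);
  List out(3);
  for (int s = 0; s < 3; ++s) {
    arma::mat M(P.n_slices, 4);
    for (arma::uword i = 0; i < P.n_slices; ++i)
      M.row(i) = P.slice(i).row(s);
    out[s] = wrap(M);
  }
  return out;
}

// densities (per generation) and survival at arbitrary times for the three
// start states; returns 3 x n matrix (rows S11, S12, S22)
// [[Rcpp::export(name = ".cpp_im_density")]]
NumericMatrix cpp_im_density(NumericVector times, NumericVector b,
                             NumericVector N1, NumericVector N2,
                             NumericVector m, bool survival = false) {
  arma::vec t = as<arma::vec>(times), bb = as<arma::vec>(b);
  arma::vec n1 = as<arma::vec>(N1), n2 = as<arma::vec>(N2), mm = as<arma::vec>(m);
  const arma::uword K = bb.n_elem;
  arma::cube P;
  boundary_states(bb, n1, n2, mm, P);
  arma::mat out(3, t.n_elem);
  for (arma::uword j = 0; j < t.n_elem; ++j) {
    if (t(j) < 0) stop("evaluation times must be >= 0");
    // segment containing t(j): last i with b(i) <= t
    arma::uword i = K - 1;
    while (i > 0 && bb(i) > t(j)) --i;
    arma::mat cur = P.slice(i);
    const double dt = t(j) - bb(i);
    if (dt > 0)
      cur = cur * arma::expmat(generator(mm(i), n1(i), n2(i)) * dt);
    for (int s = 0; s < 3; ++s) {
      if (survival)
        out(s, j) = cur(s, 0) + cur(s, 1) + cur(s, 2);
      else
        out(s, j) = cur(s, 0) / (2.0 * n1(i)) + cur(s, 2) / (2.0 * n2(i));
    }
  }
  return wrap(out);
}

// per-segment coalescence masses of the IM model for the three start
// states: mass(i, s0) = S(t_i | s0) - S(t_{i+1} | s0), with the final
// open-ended segment taking the remaining mass S(t_{K-1} | s0).
// [[Rcpp::export(name = ".cpp_im_masses")]]
NumericMatrix cpp_im_masses(NumericVector b, NumericVector N1,
                            NumericVector N2, NumericVector m) {
  arma::vec bb = as<arma::vec>(b);
  const int K = bb.n_elem;
  arma::cube P;
  boundary_states(bb, as<arma::vec>(N1), as<arma::vec>(N2), as<arma::vec>(m),
                  P);
  NumericMatrix out(K, 3);
  for (int s = 0; s < 3; ++s) {
    double Sprev = 1.0;
    for (int i = 1; i < K; ++i) {
      const arma::mat& cur = P.slice(i);
      const double S = cur(s, 0) + cur(s, 1) + cur(s, 2);
      out(i - 1, s) = Sprev - S;
      Sprev = S;
    }
    out(K - 1, s) = Sprev;
  }
  return out;
}

// tail chi-square: residual mass terms for segments i..K given the
// occupancy rows (3 start states x 4 states) at the left boundary of the
// first tail segment, plus the regularization terms of those segments.
// b: tail left boundaries; N1, N2, m, dt, Pmsmc: tail segment vectors.
// use_density = true compares instantaneous coalescence densities at the
// segment right boundaries, evaluated with the segment's own hazards
// (left-continuous; the final open-ended segment is evaluated one
// last-segment span past its left boundary); false compares per-segment
// coalescence masses.
// [[Rcpp::export(name = ".cpp_im_tail_chisq")]]
double cpp_im_tail_chisq(NumericMatrix occ, NumericVector b,
                         NumericVector N1, NumericVector N2, NumericVector m,
                         NumericMatrix Pmsmc, NumericVector dt,
                         double beta1, double beta2, double dens_floor,
                         bool use_density) {
  const int K = b.size();
  arma::mat cur = as<arma::mat>(occ);
  double chisq = 0.0;
  arma::vec Sprev = arma::sum(cur.cols(0, 2), 1);
  for (int i = 0; i < K; ++i) {
    const double w = (i + 1 < K) ? (b[i + 1] - b[i]) : dt[i];
    arma::vec Snew(3);
    if (use_density || i + 1 < K) {
      cur = cur * arma::expmat(generator(m[i], N1[i], N2[i]) * w);
      Snew = arma::sum(cur.cols(0, 2), 1);
    }
    if (i + 1 >= K && !use_density) Snew.zeros();
    if (use_density) {
      for (int s = 0; s < 3; ++s) {
        const double pim = cur(s, 0) / (2.0 * N1[i]) +
                           cur(s, 2) / (2.0 * N2[i]);
        const double pm = Pmsmc(i, s);
        const double d = pim - pm;
        chisq += d * d / std::max(pm, dens_floor);
      }
    } else {
      for (int s = 0; s < 3; ++s) {
        const double pim = Sprev(s) - Snew(s);
        const double pm = Pmsmc(i, s);
        const double d = pim - pm;
        chisq += d * d / std::max(pm, dens_floor);
      }
    }
    Sprev = Snew;
    chisq += beta1 * m[i] * dt[i];
    const double nd = (N1[i] - N2[i]) / (N1[i] + N2[i]);
    chisq += beta2 * nd * nd;
  }
  return chisq;
}

// propagate occupancy rows across one segment
// [[Rcpp::export(name = ".cpp_im_propagate")]]
NumericMatrix cpp_im_propagate(NumericMatrix occ, double w, double N1,
                               double N2, double m) {
  arma::mat cur = as<arma::mat>(occ);
  cur = cur * arma::expmat(generator(m, N1, N2) * w);
  return wrap(cur);
}

// chi-square objective for the fit, fast path for the optimizer.
// x = c(log N1, log N2, log(m + eps)) of length 3K.
// Pmsmc: K x 3 matrix of target per-segment coalescence masses (columns
// S11, S12, S22); dt: per-segment widths for the migration penalty;
// floor: denominator floor below which residual terms are skipped.
// [[Rcpp::export(name = ".cpp_im_chisq")]]
double cpp_im_chisq(NumericVector x, NumericVector b, NumericMatrix Pmsmc,
                    NumericVector dt, double beta1, double beta2,
                    double dens_floor, double eps, bool use_density) {
  const int K = b.size();
  NumericVector n1(K), n2(K), mm(K);
  for (int i = 0; i < K; ++i) {
    n1[i] = std::exp(x[i]);
    n2[i] = std::exp(x[K + i]);
    mm[i] = std::max(0.0, std::exp(x[2 * K + i]) - eps);
  }
  NumericMatrix occ(3, 4);
  occ(0, 0) = 1.0; occ(1, 1) = 1.0; occ(2, 2) = 1.0;
  return cpp_im_tail_chisq(occ, b, n1, n2, mm, Pmsmc, dt, beta1, beta2,
                           dens_floor, use_density);
}
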