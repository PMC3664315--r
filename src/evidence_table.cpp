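// Fast inner loops for Bayesian binning: the upper-triangular table of
// per-segment log marginal likelihoods under the conjugate polynomial-mean
// Gauss-Wishart observation model, and the posterior-weighted expected
// trajectory. Per segment start, raw time-power moments are accumulated
// incrementally over segment ends; the per-segment rescaling of elapsed
// time to [0,1] is a diagonal congruence of the moment matrices, and the
// change to the orthonormal segment basis (Cmat: rows = coefficients of
// the normalized shifted Legendre polynomials in powers of the rescaled
// time) is a fixed congruence applied per cell.
//
// Wishart convention: W(P; nu, V) ~ |P|^((nu-L-1)/2) exp(-tr(V^-1 P)/2);
// Vinv denotes V^-1. The R-level quadrature oracle in the test suite is the
// authority for this convention.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double lmvgamma(double a, int L) {
  double r = 0.25 * L * (L - 1) * std::log(M_PI);
  for (int i = 1; i <= L; ++i) r += std::lgamma(a + 0.5 * (1 - i));
  return r;
}

static double ldet_chol(const mat& M) {
  mat R = chol(M);
  return 2.0 * accu(log(R.diag()));
}

// bin_first[j] (0-based, length T+1): index of first sample in bin j+1;
// samples are assumed sorted by time, hence contiguous per bin.
static void bin_offsets(const ivec& bins, int T, ivec& bin_first) {
  const int n = bins.n_elem;
  bin_first.set_size(T + 1);
  int s = 0;
  for (int j = 1; j <= T; ++j) {
    bin_first[j - 1] = s;
    while (s < n && bins[s] == j) ++s;
  }
  bin_first[T] = n;
}

// [[Rcpp::export]]
arma::mat evidence_table_cpp(const arma::vec& times, const arma::mat& X,
                             const arma::ivec& bins, int T, int order,
                             const arma::mat& A0, const arma::mat& B,
                             const arma::mat& Vinv, double nu,
                             double t_min, double dt,
                             const arma::mat& Cmat) {
  const int L = X.n_cols, S1 = order + 1;
  ivec bf;
  bin_offsets(bins, T, bf);

  const mat BA0 = B * A0;
  const mat A0BA0 = A0.t() * BA0;
  const double ldetB = ldet_chol(B);
  const double ldetVinv = ldet_chol(Vinv);
  const double lmvg_prior = lmvgamma(0.5 * nu, L);
  const double l2pi = std::log(2.0 * M_PI);

  mat E(T, T);
  E.fill(datum::nan);
  vec phi(S1), dsc(S1);

  for (int i = 1; i <= T; ++i) {
    const double t_start = t_min + (i - 1) * dt;
    mat Mpp(S1, S1, fill::zeros), MpX(S1, L, fill::zeros),
        MXX(L, L, fill::zeros);
    int n = 0;
    for (int j = i; j <= T; ++j) {
      for (int s = bf[j - 1]; s < bf[j]; ++s) {
        const double u = times[s] - t_start;
        phi[0] = 1.0;
        for (int k = 1; k < S1; ++k) phi[k] = phi[k - 1] * u;
        Mpp += phi * phi.t();
        MpX += phi * X.row(s);
        MXX += X.row(s).t() * X.row(s);
        ++n;
      }
      // rescale elapsed time by the segment duration
      const double d = (j - i + 1) * dt;
      dsc[0] = 1.0;
      for (int k = 1; k < S1; ++k) dsc[k] = dsc[k - 1] / d;
      mat Mu = Mpp % (dsc * dsc.t());      // moments of rescaled time
      mat Bp = B + Cmat * Mu * Cmat.t();
      mat RHS = BA0 + Cmat * (MpX.each_col() % dsc);
      mat Ap = solve(Bp, RHS, solve_opts::likely_sympd);
      mat R = MXX + A0BA0 - Ap.t() * Bp * Ap;
      mat Vinvp = Vinv + 0.5 * (R + R.t());
      const double nup = nu + n;
      const double lev = -0.5 * n * L * l2pi
        + 0.5 * L * (ldetB - ldet_chol(Bp))
        + lmvgamma(0.5 * nup, L) - lmvg_prior
        + 0.5 * n * L * std::log(2.0)
        - 0.5 * nup * ldet_chol(Vinvp) + 0.5 * nu * ldetVinv;
      E(i - 1, j - 1) = lev;
    }
  }
  return E;
}

// Posterior-weighted expected trajectory: W(i-1, j-1) is the posterior
// probability that bins i..j form one segment; each sample accumulates the
// weighted posterior-mean polynomial of every segment containing it.
// Weights below `threshold` are skipped.
// [[Rcpp::export]]
arma::mat expected_trajectory_cpp(const arma::vec& times, const arma::mat& X,
                                  const arma::ivec& bins, int T, int order,
                                  const arma::mat& A0, const arma::mat& B,
                                  const arma::mat& W, double t_min, double dt,
                                  double threshold, const arma::mat& Cmat) {
  const int L = X.n_cols, S1 = order + 1;
  const int nsamp = X.n_rows;
  ivec bf;
  bin_offsets(bins, T, bf);
  const mat BA0 = B * A0;

  mat out(nsamp, L, fill::zeros);
  vec wsum(nsamp, fill::zeros);
  vec phi(S1), dsc(S1);

  for (int i = 1; i <= T; ++i) {
    const double t_start = t_min + (i - 1) * dt;
    mat Mpp(S1, S1, fill::zeros), MpX(S1, L, fill::zeros);
    for (int j = i; j <= T; ++j) {
      for (int s = bf[j - 1]; s < bf[j]; ++s) {
        const double u = times[s] - t_start;
        phi[0] = 1.0;
        for (int k = 1; k < S1; ++k) phi[k] = phi[k - 1] * u;
        Mpp += phi * phi.t();
        MpX += phi * X.row(s);
      }
      const double w = W(i - 1, j - 1);
      if (!(w > threshold)) continue;
      const double d = (j - i + 1) * dt;
      dsc[0] = 1.0;
      for (int k = 1; k < S1; ++k) dsc[k] = dsc[k - 1] / d;
      mat Bp = B + Cmat * (Mpp % (dsc * dsc.t())) * Cmat.t();
      mat Ap = solve(Bp, BA0 + Cmat * (MpX.each_col() % dsc),
                     solve_opts::likely_sympd);
      const mat CA = Cmat.t() * Ap;   // coefficients in rescaled powers
      for (int s = bf[i - 1]; s < bf[j]; ++s) {
        const double u = (times[s] - t_start) / d;
        double uk = 1.0;
        rowvec pred(L, fill::zeros);
        for (int k = 0; k < S1; ++k) {
          pred += uk * CA.row(k);
          uk *= u;
        }
        out.row(s) += w * pred;
        wsum[s] += w;
      }
    }
  }
  // guard against tiny weight loss from thresholding
  for (int s = 0; s < nsamp; ++s)
    if (wsum[s] > 0) out.row(s) /= wsum[s];
  return out;
}
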