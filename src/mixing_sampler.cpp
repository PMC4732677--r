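#include <Rcpp.h>
using namespace Rcpp;

// SD floor: a source/TEF SD of 0 is replaced by 0.01 permil inside the
// likelihood so the posterior stays proper for degenerate inputs.
static inline double floor_sd(double s) { return s <= 0.0 ? 0.01 : s; }

// Log-density of the single-consumer mixing model on the natural scale:
// for each isotope j, Normal(x_j | sum_k p_k (s_jk + c_jk),
// sum_k p_k^2 (sig_jk^2 + tau_jk^2) + r_j^2), plus Dirichlet(alpha) on p and
// independent uniform(0, resid_upper) on each residual SD.
static double natural_log_post(const NumericVector& x, const NumericMatrix& s,
                               const NumericMatrix& sig, const NumericMatrix& cc,
                               const NumericMatrix& tau, const NumericVector& alpha,
                               double resid_upper, const std::vector<double>& p,
                               const std::vector<double>& r, bool prior_only) {
  const int J = s.nrow(), K = s.ncol();
  double lp = 0.0;
  double asum = 0.0;
  for (int k = 0; k < K; k++) {
    asum += alpha[k];
    lp -= R::lgammafn(alpha[k]);
    if (alpha[k] != 1.0) lp += (alpha[k] - 1.0) * std::log(p[k]);
  }
  lp += R::lgammafn(asum);
  for (int j = 0; j < J; j++) {
    if (r[j] < 0.0 || r[j] > resid_upper) return R_NegInf;
    lp += -std::log(resid_upper);
  }
  if (!prior_only) {
    for (int j = 0; j < J; j++) {
      double mu = 0.0, v = r[j] * r[j];
      for (int k = 0; k < K; k++) {
        double sg = floor_sd(sig(j, k)), tu = floor_sd(tau(j, k));
        mu += p[k] * (s(j, k) + cc(j, k));
        v += p[k] * p[k] * (sg * sg + tu * tu);
      }
      lp += -0.5 * std::log(2.0 * M_PI * v) -
            (x[j] - mu) * (x[j] - mu) / (2.0 * v);
    }
  }
  return lp;
}

static void alr_to_p(const std::vector<double>& z, std::vector<double>& p) {
  const int K = (int)p.size();
  double denom = 1.0;
  for (int k = 0; k < K - 1; k++) denom += std::exp(z[k]);
  for (int k = 0; k < K - 1; k++) p[k] = std::exp(z[k]) / denom;
  p[K - 1] = 1.0 / denom;
}

// Log-posterior in sampling coordinates (additive-log-ratio z for p, log u
// for residual SDs), including the change-of-variable Jacobians
// (sum_k log p_k for ALR, u_j for each log-SD).
static double working_log_post(const NumericVector& x, const NumericMatrix& s,
                               const NumericMatrix& sig, const NumericMatrix& cc,
                               const NumericMatrix& tau, const NumericVector& alpha,
                               double resid_upper, const std::vector<double>& z,
                               const std::vector<double>& u, bool prior_only,
                               std::vector<double>& p, std::vector<double>& r) {
  const int J = s.nrow(), K = s.ncol();
  alr_to_p(z, p);
  for (int j = 0; j < J; j++) r[j] = std::exp(u[j]);
  double lp = natural_log_post(x, s, sig, cc, tau, alpha, resid_upper, p, r,
                               prior_only);
  if (!R_finite(lp)) return lp;
  for (int k = 0; k < K; k++) lp += std::log(p[k]);
  for (int j = 0; j < J; j++) lp += u[j];
  return lp;
}

// [[Rcpp::export]]
double cpp_log_posterior(NumericVector p, NumericVector resid_sd,
                         NumericVector x, NumericMatrix s, NumericMatrix sig,
                         NumericMatrix cc, NumericMatrix tau,
                         NumericVector alpha, double resid_upper,
                         bool prior_only) {
  std::vector<double> pp(p.begin(), p.end()), rr(resid_sd.begin(), resid_sd.end());
  return natural_log_post(x, s, sig, cc, tau, alpha, resid_upper, pp, rr,
                          prior_only);
}

// Component-wise random-walk Metropolis over (z, u) with per-component
// proposal-scale adaptation during burn-in targeting ~35% acceptance.
// [[Rcpp::export]]
List cpp_sample_mixing(NumericVector x, NumericMatrix s, NumericMatrix sig,
                       NumericMatrix cc, NumericMatrix tau, NumericVector alpha,
                       double resid_upper, int iterations, int burn_in, int thin,
                       double init_scale, bool adapt, bool prior_only,
                       NumericVector fix_resid, double init_resid) {
  const int J = s.nrow(), K = s.ncol(), nz = K - 1;
  const bool fixed = fix_resid.size() == J;
  std::vector<double> z(nz, 0.0), u(J);
  for (int j = 0; j < J; j++)
    u[j] = std::log(fixed ? fix_resid[j] : init_resid);
  const int npar = nz + (fixed ? 0 : J);
  std::vector<double> scales(npar, init_scale);
  std::vector<long> acc(npar, 0), tries(npar, 0), accAll(npar, 0), triesAll(npar, 0);
  std::vector<double> p(K), r(J);

  double cur = working_log_post(x, s, sig, cc, tau, alpha, resid_upper, z, u,
                                prior_only, p, r);
  if (!R_finite(cur))
    stop("non-finite posterior at initialization; check inputs (SD floors may be needed)");

  const int nkeep = (iterations - burn_in) / thin;
  NumericMatrix pdraws(std::max(nkeep, 0), K), rdraws(std::max(nkeep, 0), J);
  int kept = 0;

  for (int it = 1; it <= iterations; it++) {
    for (int k = 0; k < nz; k++) {
      double old = z[k];
      z[k] = old + scales[k] * R::norm_rand();
      double lp = working_log_post(x, s, sig, cc, tau, alpha, resid_upper, z, u,
                                   prior_only, p, r);
      tries[k]++; triesAll[k]++;
      if (R_finite(lp) && std::log(R::unif_rand()) < lp - cur) {
        cur = lp; acc[k]++; accAll[k]++;
      } else {
        z[k] = old;
      }
    }
    if (!fixed) {
      for (int j = 0; j < J; j++) {
        int idx = nz + j;
        double old = u[j];
        u[j] = old + scales[idx] * R::norm_rand();
        double lp = working_log_post(x, s, sig, cc, tau, alpha, resid_upper, z, u,
                                     prior_only, p, r);
        tries[idx]++; triesAll[idx]++;
        if (R_finite(lp) && std::log(R::unif_rand()) < lp - cur) {
          cur = lp; acc[idx]++; accAll[idx]++;
        } else {
          u[j] = old;
        }
      }
    }
    if (adapt && it <= burn_in && it % 50 == 0) {
      for (int i = 0; i < npar; i++) {
        if (tries[i] > 0) {
          double rate = (double)acc[i] / (double)tries[i];
          scales[i] *= std::exp(0.6 * (rate - 0.35));
          if (scales[i] < 1e-3) scales[i] = 1e-3;
          if (scales[i] > 20.0) scales[i] = 20.0;
        }
        acc[i] = 0; tries[i] = 0;
      }
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < nkeep) {
      alr_to_p(z, p);
      for (int k = 0; k < K; k++) pdraws(kept, k) = p[k];
      for (int j = 0; j < J; j++) rdraws(kept, j) = std::exp(u[j]);
      kept++;
    }
  }

  NumericVector rates(npar), sc(npar);
  for (int i = 0; i < npar; i++) {
    rates[i] = triesAll[i] > 0 ? (double)accAll[i] / (double)triesAll[i] : NA_REAL;
    sc[i] = scales[i];
  }
  return List::create(_["p"] = pdraws, _["resid"] = rdraws,
                      _["accept"] = rates, _["scales"] = sc,
                      _["n_retained"] = kept);
}
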