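// Multi-attribute drift-diffusion model: Wiener first-passage density,
// diffusion simulator, and hierarchical Metropolis-within-Gibbs sampler.
//
// Conventions (fixed throughout the package):
//   * diffusion coefficient sigma = 1 (scale convention; drift weights are in
//     sigma units),
//   * upper boundary = option with more shocks and more money ("high"),
//   * relative starting point w in (0,1); absolute start = w * a,
//   * observed RT = decision time + non-decision time t0.

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

static const double LOG_ZERO = -1e10; // soft -Inf: keeps the sampler movable

// Log density of the first passage through the LOWER boundary at decision
// time tau (> 0), for drift v (positive = towards upper), boundary
// separation a, relative start w. Dual small-time / large-time series with
// automatic selection; truncation error below `eps` per evaluation.
static double wfpt_log(double tau, double v, double a, double w,
                       double eps = 1e-10) {
  if (!(tau > 0.0) || !(a > 0.0) || !(w > 0.0) || !(w < 1.0)) return LOG_ZERO;
  double u = tau / (a * a); // time in boundary-normalised units

  // number of terms needed by each expansion
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double f; // drift-free density on the unit-boundary time scale
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    int kmin = -(int)std::floor((K - 1) / 2.0);
    int kmax = (int)std::ceil((K - 1) / 2.0);
    double s = 0.0;
    for (int k = kmin; k <= kmax; ++k) {
      double x = w + 2.0 * k;
      s += x * std::exp(-x * x / (2.0 * u));
    }
    f = s / std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k)
      s += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    f = s * M_PI;
  }
  if (!(f > 0.0) || !R_finite(f)) return LOG_ZERO; // far-tail round-off
  return std::log(f) - v * a * w - v * v * tau / 2.0 - 2.0 * std::log(a);
}

// Vectorised log first-passage density of observed responses.
// upper[i] = 1 if the response hit the upper (high-harm/high-money) boundary.
// [[Rcpp::export]]
NumericVector wiener_logdens_cpp(NumericVector rt, IntegerVector upper,
                                 NumericVector v, double a, double w,
                                 double t0) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double tau = rt[i] - t0;
    if (upper[i] == 1)
      out[i] = wfpt_log(tau, -v[i], a, 1.0 - w);
    else
      out[i] = wfpt_log(tau, v[i], a, w);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Simulation.
//
// Increments of a constant-drift diffusion are exactly Gaussian, so endpoints
// are sampled exactly at any step size; a Brownian-bridge test catches
// within-step boundary crossings, removing the usual O(sqrt(dt)) crossing
// bias. The only discretisation left is the O(dt) resolution of the recorded
// crossing time (mid-step imputation) and double crossings within one step
// (probability ~ exp(-2 a^2 / dt), negligible).
// ---------------------------------------------------------------------------

// Simulate one decision; returns +1 (upper) or -1 (lower), writes decision
// time. Trajectories whose total RT would exceed `window` are redrawn
// (mirrors a response deadline with re-presentation of missed trials).
template <class NormFun, class UnifFun>
static int sim_one(double v, double a, double w, double t0, double dt,
                   double window, double &dtime, NormFun rnorm1,
                   UnifFun runif1) {
  double sqdt = std::sqrt(dt);
  double tmax = window - t0; // decision-time budget
  for (int redraw = 0; redraw < 100000; ++redraw) {
    double x = w * a, t = 0.0;
    while (tmax <= 0.0 || t < tmax) {
      double xn = x + v * dt + sqdt * rnorm1();
      if (xn >= a) { dtime = t + dt / 2.0; return +1; }
      if (xn <= 0.0) { dtime = t + dt / 2.0; return -1; }
      // Brownian-bridge within-step crossing probabilities
      double eu = 2.0 * (a - x) * (a - xn) / dt;
      double el = 2.0 * x * xn / dt;
      double pu = (eu < 30.0) ? std::exp(-eu) : 0.0;
      double pl = (el < 30.0) ? std::exp(-el) : 0.0;
      if (pu > 0.0 || pl > 0.0) {
        double uu = runif1();
        if (uu < pu) { dtime = t + dt / 2.0; return +1; }
        if (uu < pu + pl) { dtime = t + dt / 2.0; return -1; }
      }
      x = xn;
      t += dt;
      if (tmax > 0.0 && t + t0 > window) break; // exceeded deadline: redraw
    }
    if (tmax <= 0.0) break; // no window: should have returned
  }
  // pathological parameters: report a censored response at the deadline
  dtime = (tmax > 0.0) ? tmax : 6.0;
  return (runif1() < 0.5) ? +1 : -1;
}

// n paths from a single parameter set. window = Inf disables the deadline.
// Uses R's RNG (deterministic under set.seed()).
// [[Rcpp::export]]
List simulate_paths_cpp(int n, double v, double a, double w, double t0,
                        double dt, double window) {
  IntegerVector upper(n);
  NumericVector rt(n);
  auto rn = []() { return norm_rand(); };
  auto ru = []() { return unif_rand(); };
  double dtime;
  for (int i = 0; i < n; ++i) {
    int b = sim_one(v, a, w, t0, dt, window, dtime, rn, ru);
    upper[i] = (b > 0) ? 1 : 0;
    rt[i] = dtime + t0;
  }
  return List::create(_["upper"] = upper, _["rt"] = rt);
}

// One response per record, each with its own parameters (posterior-predictive
// and synthetic-study workhorse).
// [[Rcpp::export]]
List sim_dataset_cpp(NumericVector v, NumericVector a, NumericVector w,
                     NumericVector t0, double dt, double window) {
  int n = v.size();
  IntegerVector upper(n);
  NumericVector rt(n);
  auto rn = []() { return norm_rand(); };
  auto ru = []() { return unif_rand(); };
  double dtime;
  for (int i = 0; i < n; ++i) {
    int b = sim_one(v[i], a[i], w[i], t0[i], dt, window, dtime, rn, ru);
    upper[i] = (b > 0) ? 1 : 0;
    rt[i] = dtime + t0[i];
  }
  return List::create(_["upper"] = upper, _["rt"] = rt);
}

// ---------------------------------------------------------------------------
// Hierarchical sampler.
//
// Subject-level parameter matrix theta (nsub x K); each column k is one
// parameter label (a, t0, z cell, beta_m cell, beta_s cell) with support
// [lo_k, hi_k]. Subjects are drawn from Normal(mu_k, sg_k) truncated to the
// support; mu_k has a uniform prior over the support and sg_k a uniform
// prior over [sg_lo, sg_hi]. Metropolis-within-Gibbs with random-walk
// proposals, batch-adapted during burn-in only.
// ---------------------------------------------------------------------------

struct HData {
  IntegerVector sub_start, sub_end;          // record ranges per subject
  NumericVector dm, ds, rt;                  // per record
  IntegerVector resp;                        // 1 = upper
  IntegerVector mcol, scol, zcol;            // per-record column maps
  int col_a, col_t0;
  bool use_lik;
};

static double subj_loglik(const HData &d, int i, const double *th) {
  if (!d.use_lik) return 0.0;
  double a = th[d.col_a];
  double t0 = th[d.col_t0];
  double ll = 0.0;
  for (int r = d.sub_start[i]; r <= d.sub_end[i]; ++r) {
    double w = (d.zcol[r] < 0) ? 0.5 : th[d.zcol[r]];
    double v = th[d.mcol[r]] * d.dm[r] + th[d.scol[r]] * d.ds[r];
    double tau = d.rt[r] - t0;
    ll += (d.resp[r] == 1) ? wfpt_log(tau, -v, a, 1.0 - w)
                           : wfpt_log(tau, v, a, w);
  }
  return ll;
}

// log truncated-normal density (normalisation matters: mu, sg are sampled)
static double ltn(double x, double m, double s, double lo, double hi) {
  if (x < lo || x > hi) return R_NegInf;
  double z = R::pnorm(hi, m, s, 1, 0) - R::pnorm(lo, m, s, 1, 0);
  if (z <= 0.0) return R_NegInf;
  return R::dnorm(x, m, s, 1) - std::log(z);
}

// [[Rcpp::export]]
List hddm_mcmc_cpp(IntegerVector sub_start, IntegerVector sub_end,
                   NumericVector dm, NumericVector ds, NumericVector rt,
                   IntegerVector resp, IntegerVector mcol, IntegerVector scol,
                   IntegerVector zcol, int col_a, int col_t0,
                   NumericMatrix support, NumericVector mu_init,
                   NumericVector sg_init, NumericMatrix theta_init,
                   int n_iter, int n_burn, double sg_lo, double sg_hi,
                   bool use_lik) {
  HData d{sub_start, sub_end, dm, ds, rt, resp, mcol, scol, zcol,
          col_a, col_t0, use_lik};
  int nsub = sub_start.size();
  int K = support.nrow();

  std::vector<double> mu(mu_init.begin(), mu_init.end());
  std::vector<double> sg(sg_init.begin(), sg_init.end());
  // theta stored subject-major for cache-friendly likelihoods
  std::vector<double> th((size_t)nsub * K);
  for (int i = 0; i < nsub; ++i)
    for (int k = 0; k < K; ++k) th[(size_t)i * K + k] = theta_init(i, k);

  std::vector<double> llcur(nsub);
  for (int i = 0; i < nsub; ++i) llcur[i] = subj_loglik(d, i, &th[(size_t)i * K]);

  // proposal scales + adaptation bookkeeping
  std::vector<double> s_mu(K), s_sg(K), s_th((size_t)nsub * K);
  std::vector<int> a_mu(K, 0), a_sg(K, 0), a_th((size_t)nsub * K, 0);
  for (int k = 0; k < K; ++k) {
    double r = support(k, 1) - support(k, 0);
    s_mu[k] = 0.05 * r;
    s_sg[k] = 0.05 * (sg_hi - sg_lo);
    for (int i = 0; i < nsub; ++i) s_th[(size_t)i * K + k] = 0.08 * r;
  }
  const int batch = 50;
  const double target = 0.44;

  int n_keep = n_iter - n_burn;
  NumericMatrix draws(n_keep, 2 * K + nsub * K + 1);
  long long acc_mu = 0, acc_sg = 0, acc_th = 0;
  long long try_mu = 0, try_sg = 0, try_th = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int k = 0; k < K; ++k) {
      double lo = support(k, 0), hi = support(k, 1);

      // group location
      {
        double prop = mu[k] + s_mu[k] * norm_rand();
        ++try_mu;
        if (prop >= lo && prop <= hi) {
          double lr = 0.0;
          for (int i = 0; i < nsub; ++i) {
            double x = th[(size_t)i * K + k];
            lr += ltn(x, prop, sg[k], lo, hi) - ltn(x, mu[k], sg[k], lo, hi);
          }
          if (std::log(unif_rand()) < lr) { mu[k] = prop; ++acc_mu; ++a_mu[k]; }
        }
      }
      // group scale
      {
        double prop = sg[k] + s_sg[k] * norm_rand();
        ++try_sg;
        if (prop >= sg_lo && prop <= sg_hi) {
          double lr = 0.0;
          for (int i = 0; i < nsub; ++i) {
            double x = th[(size_t)i * K + k];
            lr += ltn(x, mu[k], prop, lo, hi) - ltn(x, mu[k], sg[k], lo, hi);
          }
          if (std::log(unif_rand()) < lr) { sg[k] = prop; ++acc_sg; ++a_sg[k]; }
        }
      }
      // subject values
      for (int i = 0; i < nsub; ++i) {
        size_t idx = (size_t)i * K + k;
        double cur = th[idx];
        double prop = cur + s_th[idx] * norm_rand();
        ++try_th;
        if (prop < lo || prop > hi) continue;
        th[idx] = prop;
        double llnew = subj_loglik(d, i, &th[(size_t)i * K]);
        double lr = llnew - llcur[i] + ltn(prop, mu[k], sg[k], lo, hi) -
                    ltn(cur, mu[k], sg[k], lo, hi);
        if (std::log(unif_rand()) < lr) {
          llcur[i] = llnew;
          ++acc_th;
          ++a_th[idx];
        } else {
          th[idx] = cur;
        }
      }
    }

    // batch adaptation, burn-in only (kernel is fixed afterwards)
    if (iter < n_burn && (iter + 1) % batch == 0) {
      for (int k = 0; k < K; ++k) {
        s_mu[k] *= std::exp((double)a_mu[k] / batch - target);
        s_sg[k] *= std::exp((double)a_sg[k] / batch - target);
        a_mu[k] = a_sg[k] = 0;
        for (int i = 0; i < nsub; ++i) {
          size_t idx = (size_t)i * K + k;
          s_th[idx] *= std::exp((double)a_th[idx] / batch - target);
          a_th[idx] = 0;
        }
      }
    }

    if (iter >= n_burn) {
      int row = iter - n_burn;
      for (int k = 0; k < K; ++k) {
        draws(row, k) = mu[k];
        draws(row, K + k) = sg[k];
      }
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < nsub; ++i)
          draws(row, 2 * K + k * nsub + i) = th[(size_t)i * K + k];
      double lltot = 0.0;
      for (int i = 0; i < nsub; ++i) lltot += llcur[i];
      draws(row, 2 * K + nsub * K) = lltot;
    }
  }

  return List::create(
      _["draws"] = draws,
      _["accept"] = NumericVector::create(
          _["mu"] = (double)acc_mu / try_mu, _["sigma"] = (double)acc_sg / try_sg,
          _["theta"] = (double)acc_th / try_th));
}

// Total data log-likelihood at a given subject-parameter matrix (used for
// the plug-in deviance in the DIC).
// [[Rcpp::export]]
double hddm_loglik_cpp(NumericMatrix theta, IntegerVector sub_start,
                       IntegerVector sub_end, NumericVector dm,
                       NumericVector ds, NumericVector rt, IntegerVector resp,
                       IntegerVector mcol, IntegerVector scol,
                       IntegerVector zcol, int col_a, int col_t0) {
  HData d{sub_start, sub_end, dm, ds, rt, resp, mcol, scol, zcol,
          col_a, col_t0, true};
  int nsub = sub_start.size();
  int K = theta.ncol();
  std::vector<double> th(K);
  double ll = 0.0;
  for (int i = 0; i < nsub; ++i) {
    for (int k = 0; k < K; ++k) th[k] = theta(i, k);
    ll += subj_loglik(d, i, th.data());
  }
  return ll;
}
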