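#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mixture log-likelihood and gradients for the five model variants.
//
// model codes: 0 mixture2p, 1 mixture3p, 2 imm_abc, 3 imm_bsc, 4 imm_full
//
// `eta` holds the trial-wise linear predictors on the link scale, one
// column per model parameter in registry order:
//   mixture2p: kappa, thetat
//   mixture3p: kappa, thetat, thetant
//   imm_abc:   kappa, c, a
//   imm_bsc:   kappa, c, s
//   imm_full:  kappa, c, a, s
// `nt` / `dist`: n x M matrices of non-target locations / context
// distances, active slots left-compacted; `m` gives the number of active
// slots per trial. Gradients are d loglik / d eta (chain rule through the
// log links is applied here).

static const double LOG_2PI = std::log(2.0 * M_PI);
// guessing component: kappa fixed at exp(-100), numerically uniform
static const double LOG_F_GUESS = -LOG_2PI;

static inline double log_i0(double k) {
  if (k > 1e6) return k - 0.5 * std::log(2.0 * M_PI * k); // asymptotic
  return std::log(R::bessel_i(k, 0.0, 2.0)) + k;
}

// mean resultant length A(kappa) = I1/I0
static inline double a_ratio(double k) {
  if (k > 1e6) return 1.0 - 1.0 / (2.0 * k);
  return R::bessel_i(k, 1.0, 2.0) / R::bessel_i(k, 0.0, 2.0);
}

static inline double lse(const std::vector<double>& v) {
  double mx = -INFINITY;
  for (double x : v) if (x > mx) mx = x;
  if (!std::isfinite(mx)) return -INFINITY;
  double s = 0.0;
  for (double x : v) s += std::exp(x - mx);
  return mx + std::log(s);
}

// [[Rcpp::export]]
List wmm_loglik_cpp(NumericMatrix eta, int model, NumericVector x,
                    NumericMatrix nt, NumericMatrix dist, IntegerVector m,
                    bool grad) {
  const int n = x.size();
  const int P = eta.ncol();
  NumericVector trial_ll(n);
  NumericMatrix g(grad ? n : 0, grad ? P : 0);
  double total = 0.0;

  for (int i = 0; i < n; ++i) {
    const double eta_k = eta(i, 0);
    const double kappa = std::exp(eta_k);
    const double li0 = log_i0(kappa);
    const double logf_t = kappa * std::cos(x[i]) - LOG_2PI - li0;
    const int mi = m[i];
    double ll = 0.0;

    if (model <= 1) {
      // softmax-weighted mixtures
      const double thetat = eta(i, 1);
      const bool has_nt = (model == 1) && (mi > 0);
      const double thetant = has_nt ? eta(i, 2) : 0.0;
      int K = has_nt ? 3 : 2;
      std::vector<double> th(K);
      th[0] = thetat;
      if (has_nt) th[1] = thetant;
      th[K - 1] = 0.0; // guessing weight is the fixed reference
      double mx = *std::max_element(th.begin(), th.end());
      double denom = 0.0;
      for (int k = 0; k < K; ++k) denom += std::exp(th[k] - mx);
      std::vector<double> p(K);
      for (int k = 0; k < K; ++k) p[k] = std::exp(th[k] - mx) / denom;

      std::vector<double> comp;
      comp.push_back(std::log(p[0]) + logf_t);
      std::vector<double> logf_nt(has_nt ? mi : 0);
      if (has_nt) {
        for (int j = 0; j < mi; ++j) {
          logf_nt[j] = kappa * std::cos(x[i] - nt(i, j)) - LOG_2PI - li0;
          comp.push_back(std::log(p[1] / mi) + logf_nt[j]);
        }
      }
      comp.push_back(std::log(p[K - 1]) + LOG_F_GUESS);
      const double logP = lse(comp);
      ll = logP;

      if (grad) {
        const double A = a_ratio(kappa);
        const double r_t = std::exp(comp[0] - logP);
        double gk = r_t * (std::cos(x[i]) - A);
        double r_nt_sum = 0.0;
        if (has_nt) {
          for (int j = 0; j < mi; ++j) {
            const double r_j = std::exp(comp[1 + j] - logP);
            r_nt_sum += r_j;
            gk += r_j * (std::cos(x[i] - nt(i, j)) - A);
          }
        }
        g(i, 0) = kappa * gk;
        g(i, 1) = r_t - p[0];
        if (model == 1) g(i, 2) = has_nt ? (r_nt_sum - p[1]) : 0.0;
      }
    } else {
      // IMM: per-item activations normalised against background noise b = 1
      const double c = std::exp(eta(i, 1));
      double a = 0.0, s = 0.0;
      int col_a = -1, col_s = -1;
      if (model == 2) { col_a = 2; }
      else if (model == 3) { col_s = 2; }
      else { col_a = 2; col_s = 3; }
      if (col_a >= 0) a = std::exp(eta(i, col_a));
      if (col_s >= 0) s = std::exp(eta(i, col_s));

      const double A_t = a + c; // target: distance 0, exp(-s*0) = 1
      std::vector<double> A_l(mi), w(mi); // w_j = exp(-s * D_j)
      double sumA = A_t;
      for (int j = 0; j < mi; ++j) {
        if (model == 2) w[j] = 0.0;           // abc: no gradient, lure act = a
        else w[j] = std::exp(-s * dist(i, j));
        A_l[j] = a + c * w[j];
        sumA += A_l[j];
      }
      const double Q = 1.0 + sumA; // b = 1
      const double logQ = std::log(Q);

      std::vector<double> comp;
      std::vector<double> logf_nt(mi);
      comp.push_back(std::log(A_t) + logf_t);
      for (int j = 0; j < mi; ++j) {
        logf_nt[j] = kappa * std::cos(x[i] - nt(i, j)) - LOG_2PI - li0;
        if (A_l[j] > 0.0) comp.push_back(std::log(A_l[j]) + logf_nt[j]);
        else comp.push_back(-INFINITY);
      }
      comp.push_back(LOG_F_GUESS); // log(b) = 0
      const double logN = lse(comp);
      ll = logN - logQ;

      if (grad) {
        const double A = a_ratio(kappa);
        // dll/dA_i = f_i / N - 1 / Q
        const double dA_t = std::exp(logf_t - logN) - 1.0 / Q;
        std::vector<double> dA_l(mi);
        for (int j = 0; j < mi; ++j) {
          dA_l[j] = std::exp(logf_nt[j] - logN) - 1.0 / Q;
        }
        double gc = dA_t, ga = dA_t, gs = 0.0;
        for (int j = 0; j < mi; ++j) {
          gc += w[j] * dA_l[j];
          ga += dA_l[j];
          gs += (-c * dist(i, j) * w[j]) * dA_l[j];
        }
        if (model == 2) gc = dA_t; // abc: c reaches only the target
        g(i, 1) = c * gc;
        if (col_a >= 0) g(i, col_a) = a * ga;
        if (col_s >= 0) g(i, col_s) = s * gs;
        // kappa gradient via responsibilities r_i = A_i f_i / N
        const double r_t = std::exp(std::log(A_t) + logf_t - logN);
        double gk = r_t * (std::cos(x[i]) - A);
        for (int j = 0; j < mi; ++j) {
          if (A_l[j] > 0.0) {
            const double r_j = std::exp(std::log(A_l[j]) + logf_nt[j] - logN);
            gk += r_j * (std::cos(x[i] - nt(i, j)) - A);
          }
        }
        g(i, 0) = kappa * gk;
      }
    }
    trial_ll[i] = ll;
    total += ll;
  }
  return List::create(_["total"] = total, _["trial_ll"] = trial_ll,
                      _["grad"] = g);
}
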