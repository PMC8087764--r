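#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Hierarchical F-model MCMC with an environmental covariate.
// Population allele frequencies are beta-distributed around an ancestral
// frequency p_i with locus-by-population precision theta_ij = exp(-eta_ij),
// eta_ij = beta_j + alpha_i (locus model) or beta_j + g_i * E_j (env model)
// or beta_j (neutral).  Observed derived-allele counts are beta-binomial.
// Per-locus model indicators move by product-space jumps proposing the
// auxiliary parameter from its prior.

namespace {

inline double bb_loglik(int a, int n, double theta, double p) {
  if (n == 0) return 0.0;
  double tp = theta * p, tq = theta * (1.0 - p);
  return lgamma(a + tp) + lgamma(n - a + tq) - lgamma(n + theta)
       - lgamma(tp) - lgamma(tq) + lgamma(theta);
}

struct State {
  int L, J;
  std::vector<double> p;        // ancestral freqs (logit-walked)
  std::vector<double> alpha;    // locus effects
  std::vector<double> g;        // env sensitivities
  std::vector<double> beta;     // population effects
  std::vector<int> delta;       // 0 neutral, 1 locus, 2 env
  std::vector<double> ll;       // cached loglik, L x J
};

inline double eta_of(const State& st, const std::vector<double>& E,
                     int i, int j) {
  double e = st.beta[j];
  if (st.delta[i] == 1) e += st.alpha[i];
  else if (st.delta[i] == 2) e += st.g[i] * E[j];
  return e;
}

double row_ll(const State& st, const IntegerMatrix& A, const IntegerMatrix& N,
              const std::vector<double>& E, int i,
              double p, double alpha, double g, int delta,
              std::vector<double>& buf) {
  double s = 0.0;
  for (int j = 0; j < st.J; ++j) {
    double e = st.beta[j];
    if (delta == 1) e += alpha;
    else if (delta == 2) e += g * E[j];
    buf[j] = bb_loglik(A(i, j), N(i, j), exp(-e), p);
    s += buf[j];
  }
  return s;
}

inline double logit(double p) { return log(p / (1.0 - p)); }
inline double inv_logit(double x) { return 1.0 / (1.0 + exp(-x)); }

} // namespace

// [[Rcpp::export]]
List fmodel_mcmc_cpp(IntegerMatrix A, IntegerMatrix N, NumericVector E,
                     int pilot_runs, int pilot_len, int burn_in,
                     int sample_iters, int thin,
                     double prior_neutral, double sd_alpha, double sd_g,
                     double beta_mean, double beta_sd) {
  const int L = A.nrow(), J = A.ncol();
  State st;
  st.L = L; st.J = J;
  std::vector<double> Ev(E.begin(), E.end());

  // initialise at empirical pooled frequencies
  st.p.resize(L); st.alpha.assign(L, 0.0); st.g.assign(L, 0.0);
  st.delta.assign(L, 0);
  st.beta.assign(J, beta_mean);
  for (int i = 0; i < L; ++i) {
    double a = 0.5, n = 1.0;
    for (int j = 0; j < J; ++j) { a += A(i, j); n += N(i, j); }
    st.p[i] = a / n;
  }
  st.ll.assign((size_t)L * J, 0.0);
  std::vector<double> buf(J);
  for (int i = 0; i < L; ++i) {
    row_ll(st, A, N, Ev, i, st.p[i], st.alpha[i], st.g[i], st.delta[i], buf);
    for (int j = 0; j < J; ++j) st.ll[(size_t)i * J + j] = buf[j];
  }

  // proposal widths
  std::vector<double> w_p(L, 0.5), w_a(L, 0.5), w_b(J, 0.1);
  std::vector<int> acc_p(L, 0), try_p(L, 0), acc_a(L, 0), try_a(L, 0);
  std::vector<int> acc_b(J, 0), try_b(J, 0);

  double lp_prior[3] = { log(prior_neutral),
                         log((1.0 - prior_neutral) / 2.0),
                         log((1.0 - prior_neutral) / 2.0) };

  // accumulators
  std::vector<double> cnt_delta((size_t)L * 3, 0.0);
  std::vector<double> sum_alpha(L, 0.0), sum_g(L, 0.0);
  int n_beta_samples = sample_iters / thin + 1;
  NumericMatrix beta_chain(n_beta_samples, J);
  int beta_row = 0;
  double n_rec = 0.0;

  auto one_iter = [&](bool record) {
    // (1) ancestral frequency updates
    for (int i = 0; i < L; ++i) {
      double x = logit(st.p[i]) + norm_rand() * w_p[i];
      double pnew = inv_logit(x);
      if (pnew <= 1e-12 || pnew >= 1.0 - 1e-12) { try_p[i]++; continue; }
      double llnew = row_ll(st, A, N, Ev, i, pnew, st.alpha[i], st.g[i],
                            st.delta[i], buf);
      double llold = 0.0;
      for (int j = 0; j < J; ++j) llold += st.ll[(size_t)i * J + j];
      // uniform prior on p with logit walk: Jacobian p(1-p)
      double lr = llnew - llold
        + log(pnew * (1.0 - pnew)) - log(st.p[i] * (1.0 - st.p[i]));
      try_p[i]++;
      if (log(unif_rand()) < lr) {
        st.p[i] = pnew; acc_p[i]++;
        for (int j = 0; j < J; ++j) st.ll[(size_t)i * J + j] = buf[j];
      }
    }
    // (2) per-locus: random-walk the active parameter or jump models
    for (int i = 0; i < L; ++i) {
      double llold = 0.0;
      for (int j = 0; j < J; ++j) llold += st.ll[(size_t)i * J + j];
      if (unif_rand() < 0.5 && st.delta[i] != 0) {
        // within-model random walk
        try_a[i]++;
        if (st.delta[i] == 1) {
          double anew = st.alpha[i] + norm_rand() * w_a[i];
          double llnew = row_ll(st, A, N, Ev, i, st.p[i], anew, st.g[i], 1, buf);
          double lr = llnew - llold
            + R::dnorm(anew, 0.0, sd_alpha, 1) - R::dnorm(st.alpha[i], 0.0, sd_alpha, 1);
          if (log(unif_rand()) < lr) {
            st.alpha[i] = anew; acc_a[i]++;
            for (int j = 0; j < J; ++j) st.ll[(size_t)i * J + j] = buf[j];
          }
        } else {
          double gnew = st.g[i] + norm_rand() * w_a[i];
          double llnew = row_ll(st, A, N, Ev, i, st.p[i], st.alpha[i], gnew, 2, buf);
          double lr = llnew - llold
            + R::dnorm(gnew, 0.0, sd_g, 1) - R::dnorm(st.g[i], 0.0, sd_g, 1);
          if (log(unif_rand()) < lr) {
            st.g[i] = gnew; acc_a[i]++;
            for (int j = 0; j < J; ++j) st.ll[(size_t)i * J + j] = buf[j];
          }
        }
      } else {
        // model jump: propose one of the other two models, aux from prior
        int dnew = (st.delta[i] + 1 + (unif_rand() < 0.5 ? 0 : 1)) % 3;
        double anew = st.alpha[i], gnew = st.g[i];
        if (dnew == 1) anew = norm_rand() * sd_alpha;
        if (dnew == 2) gnew = norm_rand() * sd_g;
        double llnew = row_ll(st, A, N, Ev, i, st.p[i], anew, gnew, dnew, buf);
        double lr = llnew - llold + lp_prior[dnew] - lp_prior[st.delta[i]];
        if (log(unif_rand()) < lr) {
          st.delta[i] = dnew; st.alpha[i] = anew; st.g[i] = gnew;
          for (int j = 0; j < J; ++j) st.ll[(size_t)i * J + j] = buf[j];
        }
      }
    }
    // (3) population effects
    for (int j = 0; j < J; ++j) {
      double bnew = st.beta[j] + norm_rand() * w_b[j];
      double llnew = 0.0, llold = 0.0;
      std::vector<double> col(L);
      double bsave = st.beta[j];
      st.beta[j] = bnew;
      for (int i = 0; i < L; ++i) {
        double e = eta_of(st, Ev, i, j);
        col[i] = bb_loglik(A(i, j), N(i, j), exp(-e), st.p[i]);
        llnew += col[i];
        llold += st.ll[(size_t)i * J + j];
      }
      st.beta[j] = bsave;
      double lr = llnew - llold
        + R::dnorm(bnew, beta_mean, beta_sd, 1)
        - R::dnorm(st.beta[j], beta_mean, beta_sd, 1);
      try_b[j]++;
      if (log(unif_rand()) < lr) {
        st.beta[j] = bnew; acc_b[j]++;
        for (int i = 0; i < L; ++i) st.ll[(size_t)i * J + j] = col[i];
      }
    }
    if (record) {
      for (int i = 0; i < L; ++i) {
        cnt_delta[(size_t)i * 3 + st.delta[i]] += 1.0;
        sum_alpha[i] += (st.delta[i] == 1) ? st.alpha[i] : 0.0;
        sum_g[i] += (st.delta[i] == 2) ? st.g[i] : 0.0;
      }
      n_rec += 1.0;
    }
  };

  // pilot runs: tune proposal widths toward 25-45% acceptance
  for (int pr = 0; pr < pilot_runs; ++pr) {
    std::fill(acc_p.begin(), acc_p.end(), 0);
    std::fill(try_p.begin(), try_p.end(), 0);
    std::fill(acc_a.begin(), acc_a.end(), 0);
    std::fill(try_a.begin(), try_a.end(), 0);
    std::fill(acc_b.begin(), acc_b.end(), 0);
    std::fill(try_b.begin(), try_b.end(), 0);
    for (int it = 0; it < pilot_len; ++it) one_iter(false);
    for (int i = 0; i < L; ++i) {
      if (try_p[i] > 0) {
        double r = (double)acc_p[i] / try_p[i];
        if (r > 0.45) w_p[i] *= 1.4; else if (r < 0.25) w_p[i] /= 1.4;
      }
      if (try_a[i] > 0) {
        double r = (double)acc_a[i] / try_a[i];
        if (r > 0.45) w_a[i] *= 1.4; else if (r < 0.25) w_a[i] /= 1.4;
      }
    }
    for (int j = 0; j < J; ++j) {
      if (try_b[j] > 0) {
        double r = (double)acc_b[j] / try_b[j];
        if (r > 0.45) w_b[j] *= 1.4; else if (r < 0.25) w_b[j] /= 1.4;
      }
    }
  }

  for (int it = 0; it < burn_in; ++it) one_iter(false);
  int it_since = 0;
  for (int it = 0; it < sample_iters; ++it) {
    bool rec = (it_since++ % thin) == 0;
    one_iter(rec);
    if (rec && beta_row < n_beta_samples) {
      for (int j = 0; j < J; ++j) beta_chain(beta_row, j) = st.beta[j];
      ++beta_row;
    }
  }

  NumericMatrix post(L, 3);
  NumericVector mean_alpha(L), mean_g(L);
  for (int i = 0; i < L; ++i) {
    for (int k = 0; k < 3; ++k)
      post(i, k) = n_rec > 0 ? cnt_delta[(size_t)i * 3 + k] / n_rec : NA_REAL;
    mean_alpha[i] = n_rec > 0 ? sum_alpha[i] / n_rec : NA_REAL;
    mean_g[i] = n_rec > 0 ? sum_g[i] / n_rec : NA_REAL;
  }
  double acc_rate = 0.0; int ntry = 0;
  for (int i = 0; i < L; ++i) { acc_rate += acc_p[i]; ntry += try_p[i]; }
  return List::create(
    _["post_prob"] = post, _["mean_alpha"] = mean_alpha,
    _["mean_g"] = mean_g,
    _["beta_chain"] = beta_chain(Range(0, std::max(beta_row - 1, 0)), _),
    _["accept_p"] = ntry > 0 ? acc_rate / ntry : NA_REAL);
}
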