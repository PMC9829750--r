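#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for a K-state Gaussian-emission HMM.
// Scaling (Rabiner-style) keeps the recursion stable for sequences of 1e5+
// observations; emission densities are floored at 1e-300 so an observation
// far from every state mean cannot zero out the forward variable.

static inline double gauss_pdf(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  double d = std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
  return d > 1e-300 ? d : 1e-300;
}

// Forward-backward for one sequence. Returns the posterior matrix gamma
// (n x K), summed transition expectations xi (K x K), and the log-likelihood.
// [[Rcpp::export(name = ".fb_one_cpp")]]
List fb_one_cpp(NumericVector x, NumericVector mu, NumericVector sd,
                NumericVector start, NumericMatrix trans) {
  const int n = x.size(), K = mu.size();
  NumericMatrix b(n, K), alpha(n, K), beta(n, K), gamma(n, K), xi(K, K);
  NumericVector cscale(n);

  for (int t = 0; t < n; ++t)
    for (int i = 0; i < K; ++i)
      b(t, i) = gauss_pdf(x[t], mu[i], sd[i]);

  // forward
  double c0 = 0.0;
  for (int i = 0; i < K; ++i) { alpha(0, i) = start[i] * b(0, i); c0 += alpha(0, i); }
  cscale[0] = c0;
  for (int i = 0; i < K; ++i) alpha(0, i) /= c0;
  for (int t = 1; t < n; ++t) {
    double ct = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * trans(i, j);
      alpha(t, j) = s * b(t, j);
      ct += alpha(t, j);
    }
    cscale[t] = ct;
    for (int j = 0; j < K; ++j) alpha(t, j) /= ct;
  }

  // backward (scaled by the forward constants)
  for (int i = 0; i < K; ++i) beta(n - 1, i) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += trans(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / cscale[t + 1];
    }
  }

  double loglik = 0.0;
  for (int t = 0; t < n; ++t) loglik += std::log(cscale[t]);

  for (int t = 0; t < n; ++t) {
    double s = 0.0;
    for (int i = 0; i < K; ++i) { gamma(t, i) = alpha(t, i) * beta(t, i); s += gamma(t, i); }
    for (int i = 0; i < K; ++i) gamma(t, i) /= s;
  }

  for (int t = 0; t + 1 < n; ++t) {
    double denom = cscale[t + 1];
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t, i) * trans(i, j) * b(t + 1, j) * beta(t + 1, j) / denom;
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}

// E-step sufficient statistics accumulated over a list of sequences sharing
// one parameter set (joint training across all pair profiles / chromosomes).
// [[Rcpp::export(name = ".fb_stats_cpp")]]
List fb_stats_cpp(List seqs, NumericVector mu, NumericVector sd,
                  NumericVector start, NumericMatrix trans) {
  const int K = mu.size();
  NumericVector g_sum(K), gx(K), gx2(K), g_first(K);
  NumericMatrix xi_sum(K, K);
  double loglik = 0.0;
  long long n_obs = 0;

  for (int s = 0; s < seqs.size(); ++s) {
    NumericVector x = seqs[s];
    List fb = fb_one_cpp(x, mu, sd, start, trans);
    NumericMatrix gamma = fb["gamma"];
    NumericMatrix xi = fb["xi"];
    loglik += as<double>(fb["loglik"]);
    const int n = x.size();
    n_obs += n;
    for (int i = 0; i < K; ++i) {
      g_first[i] += gamma(0, i);
      for (int j = 0; j < K; ++j) xi_sum(i, j) += xi(i, j);
    }
    for (int t = 0; t < n; ++t)
      for (int i = 0; i < K; ++i) {
        double g = gamma(t, i);
        g_sum[i] += g;
        gx[i] += g * x[t];
        gx2[i] += g * x[t] * x[t];
      }
  }

  return List::create(_["gamma_sum"] = g_sum, _["gamma_x"] = gx,
                      _["gamma_x2"] = gx2, _["gamma_first"] = g_first,
                      _["xi_sum"] = xi_sum, _["loglik"] = loglik,
                      _["n_obs"] = (double)n_obs);
}
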