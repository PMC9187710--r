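#include <Rcpp.h>
using namespace Rcpp;

// Sensory adaptation dynamics: C starts at 1; each click is weighted by the
// value of C immediately before the click; C then jumps multiplicatively to
// phi*C and relaxes exponentially back toward 1 with time constant tau_phi.
// `times` must be the merged, ascending click times of one trial.
// [[Rcpp::export]]
NumericVector adapt_clicks_cpp(NumericVector times, double phi,
                               double tau_phi) {
  int n = times.size();
  NumericVector mag(n);
  double C = 1.0;
  double t_prev = 0.0;
  for (int i = 0; i < n; ++i) {
    double dt = times[i] - t_prev;
    if (dt > 0) C = 1.0 + (C - 1.0) * std::exp(-dt / tau_phi);
    mag[i] = C;
    C *= phi;
    t_prev = times[i];
  }
  return mag;
}

// Per-trial sufficient statistics of the forward model at trial end.
// Clicks of all trials are concatenated; `starts` gives the 0-based index of
// each trial's first click and `nclicks` its click count.  For trial k with
// end time T, returns
//   drift  = sum_i side_i * exp(lam*(T - t_i)) * C_i
//   var_c  = sum_i exp(2*lam*(T - t_i)) * C_i
//   var_c2 = sum_i exp(2*lam*(T - t_i)) * C_i^2
// [[Rcpp::export]]
NumericMatrix trial_stats_cpp(NumericVector times, NumericVector sides,
                              IntegerVector starts, IntegerVector nclicks,
                              NumericVector t_end, double lam, double phi,
                              double tau_phi) {
  int ntr = starts.size();
  NumericMatrix out(ntr, 3);
  for (int k = 0; k < ntr; ++k) {
    double C = 1.0, t_prev = 0.0;
    double drift = 0.0, vc = 0.0, vc2 = 0.0;
    double T = t_end[k];
    int s = starts[k];
    for (int i = 0; i < nclicks[k]; ++i) {
      double t = times[s + i];
      double dt = t - t_prev;
      if (dt > 0) C = 1.0 + (C - 1.0) * std::exp(-dt / tau_phi);
      double e1 = std::exp(lam * (T - t));
      drift += sides[s + i] * e1 * C;
      vc += e1 * e1 * C;
      vc2 += e1 * e1 * C * C;
      C *= phi;
      t_prev = t;
    }
    out(k, 0) = drift;
    out(k, 1) = vc;
    out(k, 2) = vc2;
  }
  return out;
}

// Full negative log-likelihood of the observed choices in one pass over
// the concatenated click data (see trial_stats_cpp for the layout).
// `choice` is +1/-1 per trial; probabilities floored at 1e-10.
// var_c2 != 0 selects the per-click variance ~ C^2 convention.
// [[Rcpp::export]]
double nll_cpp(NumericVector times, NumericVector sides,
               IntegerVector starts, IntegerVector nclicks,
               NumericVector t_end, IntegerVector choice,
               double sigma_i2, double sigma_a2, double sigma_s2,
               double lam, double phi, double tau_phi, double B,
               double lapse, int var_c2) {
  int ntr = starts.size();
  double nll = 0.0;
  for (int k = 0; k < ntr; ++k) {
    double C = 1.0, t_prev = 0.0;
    double drift = 0.0, vclick = 0.0;
    double T = t_end[k];
    int s = starts[k];
    for (int i = 0; i < nclicks[k]; ++i) {
      double t = times[s + i];
      double dt = t - t_prev;
      if (dt > 0) C = 1.0 + (C - 1.0) * std::exp(-dt / tau_phi);
      double e1 = std::exp(lam * (T - t));
      drift += sides[s + i] * e1 * C;
      vclick += e1 * e1 * (var_c2 ? C * C : C);
      C *= phi;
      t_prev = t;
    }
    double x = 2.0 * lam * T;
    double exprel = (std::fabs(x) < 1e-8) ? 1.0 + x / 2.0 :
      std::expm1(x) / x;
    double var = sigma_i2 * std::exp(x) + sigma_a2 * T * exprel +
      sigma_s2 * vclick;
    double p_up = (var > 0) ?
      R::pnorm((drift - B) / std::sqrt(var), 0.0, 1.0, 1, 0) :
      (drift > B ? 1.0 : 0.0);
    double p_right = (1.0 - lapse) * p_up + lapse / 2.0;
    double p = (choice[k] == 1) ? p_right : 1.0 - p_right;
    if (p < 1e-10) p = 1e-10;
    nll -= std::log(p);
  }
  return nll;
}

// Exact discrete-time Bayesian filter for the two-state telegraph process.
// Inputs are per-bin right/left click counts (bin width dt).  The total
// click rate is the same in both states, so the no-click likelihood factor
// cancels and each bin contributes kappa*(nR - nL) to the log-likelihood
// ratio, where kappa = log(rate_high/rate_low).  Between observations the
// belief is propagated through the hazard-rate Markov transition.
// Returns the log-odds of state 1 ("go right") after each bin.
// [[Rcpp::export]]
NumericVector ideal_filter_cpp(IntegerVector n_right, IntegerVector n_left,
                               double dt, double hazard, double kappa,
                               double prior_logodds) {
  int n = n_right.size();
  NumericVector out(n);
  double h = hazard * dt;  // per-bin switch probability
  double p = 1.0 / (1.0 + std::exp(-prior_logodds));
  for (int i = 0; i < n; ++i) {
    // hazard transition
    double p1 = (1.0 - h) * p + h * (1.0 - p);
    // click likelihood update in log-odds space
    double lo = std::log(p1) - std::log1p(-p1) +
      kappa * (double)(n_right[i] - n_left[i]);
    out[i] = lo;
    p = 1.0 / (1.0 + std::exp(-lo));
  }
  return out;
}
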