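#include <Rcpp.h>
using namespace Rcpp;

// Daily-step simulation of one agent over n_years blocks of days_per_year
// school days. Uses R's RNG (seed it from R before calling). Fixed draw
// order per day so R-level stepping can reproduce the stream exactly:
//   [yearly gamma draw at the start of each year unless gamma_daily]
//   u_situation; u_choice only in the choice situation with v > 0;
//   TD update if healthy food consumed; u_servings only when v > 0.
// gamma_fixed: per-year override (NA = draw from the environment intervals).
// [[Rcpp::export]]
List sim_agent_cpp(double v0, double alpha, double beta_h, double v_u,
                   IntegerVector ffvp, IntegerVector desert,
                   double p1, double p2, double a,
                   int days_per_year, double lam,
                   int record_every, bool gamma_daily,
                   NumericVector gamma_fixed) {
  const int n_years = ffvp.size();
  const int total = n_years * days_per_year;
  int n_rec = 0;
  for (int s = 1; s <= total; ++s)
    if (s % record_every == 0 || s == total) ++n_rec;

  // Poisson(lam) CDF table: the daily servings quantile is the smallest k
  // with CDF(k) >= u. Tabulating once is much cheaper than per-day qpois;
  // draws in the far upper tail fall back to R's quantile function.
  std::vector<double> cdf;
  {
    double p = std::exp(-lam), cum = p;
    cdf.push_back(cum);
    int k = 0;
    while (cum < 1.0 - 1e-13 && k < 10000) {
      ++k;
      p *= lam / k;
      cum += p;
      cdf.push_back(cum);
    }
  }

  NumericMatrix rec(n_rec, 6);
  NumericVector gammas(n_years);
  NumericVector serv_last(days_per_year);
  double v = v0;
  int ri = 0, step = 0;

  for (int y = 0; y < n_years; ++y) {
    const bool fixed = (gamma_fixed.size() == n_years) &&
                       !NumericVector::is_na(gamma_fixed[y]);
    const double lo = desert[y] ? 0.0 : p1;
    const double hi = desert[y] ? p1 : p2;
    double gamma = 0.0;
    if (!gamma_daily) {
      if (fixed) gamma = gamma_fixed[y];
      else {
        gamma = lo + unif_rand() * (hi - lo);
        if (ffvp[y]) gamma = std::min(gamma + a, 1.0);
      }
      gammas[y] = gamma;
    }
    for (int d = 0; d < days_per_year; ++d) {
      ++step;
      if (gamma_daily) {
        if (fixed) gamma = gamma_fixed[y];
        else {
          gamma = lo + unif_rand() * (hi - lo);
          if (ffvp[y]) gamma = std::min(gamma + a, 1.0);
        }
        if (d == 0) gammas[y] = gamma;
      }
      const bool healthy_only = unif_rand() < gamma;
      bool consumed;
      if (healthy_only) consumed = true;
      else if (v > 0.0) consumed = unif_rand() < v / (v_u + v);
      else consumed = false;
      if (consumed) v += alpha * (beta_h - v);
      double serv = 0.0;
      if (v > 0.0) {
        const double u = unif_rand() * v;
        if (u <= cdf.back()) {
          serv = std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin();
        } else {
          serv = R::qpois(u, lam, 1, 0);
        }
      }
      if (y == n_years - 1) serv_last[d] = serv;
      if (step % record_every == 0 || step == total) {
        rec(ri, 0) = step;
        rec(ri, 1) = v;
        rec(ri, 2) = v / (v_u + v);
        rec(ri, 3) = healthy_only ? 1.0 : 0.0;
        rec(ri, 4) = consumed ? 1.0 : 0.0;
        rec(ri, 5) = serv;
        ++ri;
      }
    }
  }
  return List::create(_["trajectory"] = rec,
                      _["gammas"] = gammas,
                      _["v_final"] = v,
                      _["servings_final_year"] = serv_last);
}
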