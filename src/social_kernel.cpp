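#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// The discretized observations are stored as a flat candidate-cue table:
// cue i belongs to record rec[i] (1-based) and carries the exact time since
// the conspecific dive (dt, s), the distance to it (dist, BL) and the
// absolute bearing from the focal's heading (bearing, degrees in [0, 180]).
// A record is "social" under (lag, d, arc) iff it has at least one cue with
// dt <= lag, dist < d and bearing <= arc / 2.  These boundary conventions
// must match is_social() and the simulator exactly.

// [[Rcpp::export]]
LogicalVector social_labels_cpp(int n_rec, IntegerVector rec,
                                NumericVector dt, NumericVector dist,
                                NumericVector bearing,
                                double lag, double d, double half_arc) {
  LogicalVector out(n_rec);
  const R_xlen_t n = rec.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (dt[i] <= lag && dist[i] < d && bearing[i] <= half_arc)
      out[rec[i] - 1] = true;
  }
  return out;
}

// Sufficient statistics of the two-rate Bernoulli likelihood for a given
// interaction zone: the number of social records and how many of them
// carried a dive.  (Non-social counts follow from the totals.)
// [[Rcpp::export]]
NumericVector social_counts_cpp(int n_rec, IntegerVector rec,
                                NumericVector dt, NumericVector dist,
                                NumericVector bearing, IntegerVector dived,
                                double lag, double d, double half_arc) {
  std::vector<char> soc(n_rec, 0);
  const R_xlen_t n = rec.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (dt[i] <= lag && dist[i] < d && bearing[i] <= half_arc)
      soc[rec[i] - 1] = 1;
  }
  double n1 = 0.0, n1d = 0.0;
  for (int r = 0; r < n_rec; ++r) {
    if (soc[r]) {
      n1 += 1.0;
      if (dived[r]) n1d += 1.0;
    }
  }
  return NumericVector::create(n1, n1d);
}

// Streaming WAIC accumulation over posterior samples.  For each sample the
// per-record log-likelihood takes one of four values (social x dived), so we
// relabel once per sample and update an online log-sum-exp (for lppd) and a
// Welford mean/M2 (for p_waic) per record.  variant: 0 = full, 1 = no-angle
// (half_arc is 180 in the samples), 2 = null (every record uses p0).
// samples columns: p0, p1, lag, dist, arc.
// [[Rcpp::export]]
List waic_stream_cpp(IntegerVector dived, IntegerVector rec,
                     NumericVector dt, NumericVector dist,
                     NumericVector bearing, NumericMatrix samples,
                     double step, int variant) {
  const int n_rec = dived.size();
  const int S = samples.nrow();
  const R_xlen_t n_cue = rec.size();
  std::vector<double> mx(n_rec, R_NegInf), sm(n_rec, 0.0),
      mean(n_rec, 0.0), m2(n_rec, 0.0);
  std::vector<char> soc(n_rec, 0);

  for (int s = 0; s < S; ++s) {
    const double p0 = samples(s, 0), p1 = samples(s, 1);
    const double lag = samples(s, 2), d = samples(s, 3);
    const double ha = samples(s, 4) / 2.0;
    const double q0 = 1.0 - std::pow(1.0 - p0, step);
    const double q1 = 1.0 - std::pow(1.0 - p1, step);
    const double l0d = std::log(q0), l0n = std::log1p(-q0);
    const double l1d = std::log(q1), l1n = std::log1p(-q1);

    std::fill(soc.begin(), soc.end(), 0);
    if (variant != 2) {
      for (R_xlen_t i = 0; i < n_cue; ++i) {
        if (dt[i] <= lag && dist[i] < d && bearing[i] <= ha)
          soc[rec[i] - 1] = 1;
      }
    }
    for (int r = 0; r < n_rec; ++r) {
      const double ll =
          soc[r] ? (dived[r] ? l1d : l1n) : (dived[r] ? l0d : l0n);
      if (ll <= mx[r]) {
        sm[r] += std::exp(ll - mx[r]);
      } else {
        sm[r] = (mx[r] == R_NegInf) ? 1.0 : sm[r] * std::exp(mx[r] - ll) + 1.0;
        mx[r] = ll;
      }
      const double d1 = ll - mean[r];
      mean[r] += d1 / (s + 1);
      m2[r] += d1 * (ll - mean[r]);
    }
  }

  double lppd = 0.0, p_waic = 0.0;
  const double logS = std::log((double)S);
  for (int r = 0; r < n_rec; ++r) {
    lppd += mx[r] + std::log(sm[r]) - logS;
    p_waic += m2[r] / (S - 1);
  }
  return List::create(_["lppd"] = lppd, _["p_waic"] = p_waic,
                      _["waic"] = -2.0 * (lppd - p_waic));
}
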