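#include <Rcpp.h>
using namespace Rcpp;

// Euler--Maruyama walk for a single-accumulator diffusion between symmetric
// absorbing bounds +/- B(t), B(t) = max(0, a - theta * t), diffusion
// coefficient fixed at 1.  Start x(0) = a * (2z - 1).  The walk runs over
// decision time only; rt = crossing time + t0.  Non-absorbed mass at
// deadline - t0 is an omission.  With probability p_outlier the trial is a
// lapse: uniform response, rt uniform on (0, deadline).
//
// The effective bound is pulled inward by 0.5826 * sqrt(dt) (the
// Broadie-Glasserman-Kou continuity correction), removing the O(sqrt(dt))
// absorption bias of discrete-time barrier checks.
//
// response codes: 1 = upper bound, 0 = lower bound, -1 = omission.

// [[Rcpp::export]]
List ddm_simulate_cpp(NumericVector v, NumericVector a, NumericVector theta,
                      NumericVector z, NumericVector t0,
                      NumericVector p_outlier,
                      double dt, double deadline) {
  int n = v.size();
  IntegerVector response(n);
  NumericVector rt(n);
  double sqdt = std::sqrt(dt);
  double shift = 0.5826 * sqdt;  // continuity correction, noise sd = 1

  for (int i = 0; i < n; ++i) {
    if (p_outlier[i] > 0.0 && unif_rand() < p_outlier[i]) {
      response[i] = (unif_rand() < 0.5) ? 1 : 0;
      rt[i] = unif_rand() * deadline;
      continue;
    }
    double ai = a[i], thi = theta[i];
    double x = ai * (2.0 * z[i] - 1.0);
    double tmax = deadline - t0[i];
    double t = 0.0;
    int resp = -1;
    double rti = NA_REAL;
    // check absorption before the first step (collapsed or degenerate bound)
    while (true) {
      double B = ai - thi * t - shift;
      if (B < 0.0) B = 0.0;
      if (x >= B || x <= -B) {
        if (B <= 0.0 && x == 0.0) {
          resp = (unif_rand() < 0.5) ? 1 : 0;
        } else {
          resp = (x >= B) ? 1 : 0;
        }
        rti = t + t0[i];
        break;
      }
      if (t >= tmax) break;  // deadline reached without absorption
      x += v[i] * dt + sqdt * norm_rand();
      t += dt;
    }
    response[i] = resp;
    rt[i] = rti;
  }
  return List::create(_["response"] = response, _["rt"] = rt);
}
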