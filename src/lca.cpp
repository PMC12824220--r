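#include <Rcpp.h>
using namespace Rcpp;

// Rectified leaky competing accumulator, two units racing to a shared
// linearly collapsing bound B(t) = max(0, a0 - c * t).
//
//   y1 <- ReLU(y1 + dt * (I1 - k*y1 - w*y2) + s1 * sqrt(dt))
//   y2 <- ReLU(y2 + dt * (I2 - k*y2 - w*y1) + s2 * sqrt(dt))   [cross inhibition]
//
// printed_inhibition = true reproduces the printed self-inhibition variant in
// which unit 2's inhibition term uses its own activation (w redundant with
// leak for unit 2); kept for auditability only.
//
// Noise s ~ N(0, sigma) enters before rectification.  First unit to reach
// B(t) wins; if the bound floor (B = 0) is reached before any crossing, the
// unit with the larger activation wins at that moment (tie -> fair coin).
// rt = crossing time + t0; no crossing before deadline - t0 is an omission.
//
// winner codes: 1 = unit 1, 2 = unit 2, -1 = omission.

// [[Rcpp::export]]
List lca_simulate_cpp(NumericVector I1, NumericVector I2,
                      double k, double w, double a0, double c,
                      double sigma, double t0,
                      double dt, double deadline,
                      bool printed_inhibition) {
  int n = I1.size();
  IntegerVector winner(n);
  NumericVector rt(n);
  double sqdt = std::sqrt(dt);

  for (int i = 0; i < n; ++i) {
    double y1 = 0.0, y2 = 0.0, t = 0.0;
    double tmax = deadline - t0;
    int win = -1;
    double rti = NA_REAL;
    while (true) {
      double B = a0 - c * t;
      if (B <= 0.0) {
        // bound fully collapsed: larger activation wins immediately
        if (y1 > y2)      win = 1;
        else if (y2 > y1) win = 2;
        else              win = (unif_rand() < 0.5) ? 1 : 2;
        rti = t + t0;
        break;
      }
      if (y1 >= B || y2 >= B) {
        if (y1 >= B && y2 >= B) {
          win = (y1 > y2) ? 1 : (y2 > y1 ? 2 : ((unif_rand() < 0.5) ? 1 : 2));
        } else {
          win = (y1 >= B) ? 1 : 2;
        }
        rti = t + t0;
        break;
      }
      if (t >= tmax) break;
      double inh2 = printed_inhibition ? y2 : y1;
      double d1 = y1 + dt * (I1[i] - k * y1 - w * y2) + sigma * norm_rand() * sqdt;
      double d2 = y2 + dt * (I2[i] - k * y2 - w * inh2) + sigma * norm_rand() * sqdt;
      y1 = (d1 > 0.0) ? d1 : 0.0;
      y2 = (d2 > 0.0) ? d2 : 0.0;
      t += dt;
    }
    winner[i] = win;
    rt[i] = rti;
  }
  return List::create(_["winner"] = winner, _["rt"] = rt);
}
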