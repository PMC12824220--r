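#include <Rcpp.h>
using namespace Rcpp;

// Inverse-binomial-sampling draw counts with in-loop simulators.
//
// For each observed trial, outcomes are simulated until the first draw whose
// stratified RT-decile category matches the observed category.  Returns the
// number of draws K per trial; K_max + 1 encodes "cap hit without a match".
//
// Category layout per split level g in {1, 2} (2Q + 1 categories each):
//   correct bins 1..Q, error bins 1..Q, omission.
// Edge matrix: (Q - 1) rows, 4 columns ordered
//   g1/correct, g1/error, g2/correct, g2/error.
// Bins are right-closed: rt equal to an edge falls in the lower bin.

static inline int rt_bin(double rt, const NumericMatrix& edges, int col) {
  int Q1 = edges.nrow();  // Q - 1 internal edges
  int below = 0;
  for (int j = 0; j < Q1; ++j) if (edges(j, col) < rt) ++below;
  return below + 1;
}

static inline int category_of(bool omitted, bool correct, double rt, int g,
                              const NumericMatrix& edges, int Q) {
  int per = 2 * Q + 1;
  int base = (g - 1) * per;
  if (omitted) return base + per;
  int col = (g - 1) * 2 + (correct ? 0 : 1);
  return base + (correct ? 0 : Q) + rt_bin(rt, edges, col);
}

// One DDM trial; returns category. correct_left: 1 = left is the better
// bundle, 0 = right, -1 = tie (counts as error).  upper_left: does the upper
// bound denote the left response on this trial.
static int ddm_draw(double v, double a, double theta, double z, double t0,
                    double p_outlier, double dt, double deadline,
                    int correct_left, bool upper_left, int g,
                    const NumericMatrix& edges, int Q, double sqdt,
                    double shift) {
  if (p_outlier > 0.0 && unif_rand() < p_outlier) {
    bool up = unif_rand() < 0.5;
    bool left = up ? upper_left : !upper_left;
    bool correct = (correct_left == 1 && left) || (correct_left == 0 && !left);
    return category_of(false, correct, unif_rand() * deadline, g, edges, Q);
  }
  double x = a * (2.0 * z - 1.0);
  double tmax = deadline - t0;
  double t = 0.0;
  while (true) {
    double B = a - theta * t - shift;
    if (B < 0.0) B = 0.0;
    if (x >= B || x <= -B) {
      bool up = (B <= 0.0 && x == 0.0) ? (unif_rand() < 0.5) : (x >= B);
      bool left = up ? upper_left : !upper_left;
      bool correct = (correct_left == 1 && left) || (correct_left == 0 && !left);
      return category_of(false, correct, t + t0, g, edges, Q);
    }
    if (t >= tmax) return category_of(true, false, NA_REAL, g, edges, Q);
    x += v * dt + sqdt * norm_rand();
    t += dt;
  }
}

// H and H2 have length K_max + 1; H[k] = sum_{j=1}^{k-1} 1/j (0-based index
// k), H2 the squared-reciprocal companion for the variance estimate.
// stop_sum > 0 aborts once the accumulated negative log-likelihood exceeds
// it (the returned nll is then a lower bound and complete = false).

// [[Rcpp::export]]
List ibs_ddm_cpp(IntegerVector obs, NumericVector v, NumericVector a,
                 NumericVector theta, NumericVector z,
                 NumericVector t0, NumericVector p_outlier,
                 IntegerVector correct_left, LogicalVector upper_left,
                 IntegerVector g, NumericMatrix edges, int Q,
                 int K_max, double dt, double deadline,
                 NumericVector H, NumericVector H2, double stop_sum) {
  int n = obs.size();
  double sqdt = std::sqrt(dt);
  double shift = 0.5826 * sqdt;
  double nll = 0.0, varsum = 0.0;
  int n_capped = 0;
  bool complete = true;
  for (int i = 0; i < n; ++i) {
    int k = 0;
    bool matched = false;
    while (k < K_max) {
      ++k;
      int cat = ddm_draw(v[i], a[i], theta[i], z[i], t0[i], p_outlier[i],
                         dt, deadline, correct_left[i], upper_left[i], g[i],
                         edges, Q, sqdt, shift);
      if (cat == obs[i]) { matched = true; break; }
    }
    if (!matched) ++n_capped;
    nll += H[k];
    varsum += H2[k];
    if (stop_sum > 0.0 && nll > stop_sum) { complete = false; break; }
  }
  return List::create(_["nll"] = nll, _["varsum"] = varsum,
                      _["n_capped"] = n_capped, _["complete"] = complete);
}

// One LCA trial; unit 1 carries the correct option (ties: unit 1 = left,
// counts as error either way).
static int lca_draw(double I1, double I2, double k_leak, double w, double a0,
                    double c, double sigma, double t0, double dt,
                    double deadline, bool tie, int g,
                    const NumericMatrix& edges, int Q, double sqdt) {
  double y1 = 0.0, y2 = 0.0, t = 0.0;
  double tmax = deadline - t0;
  while (true) {
    double B = a0 - c * t;
    if (B <= 0.0) {
      bool u1 = (y1 > y2) || (y1 == y2 && unif_rand() < 0.5);
      return category_of(false, u1 && !tie, t + t0, g, edges, Q);
    }
    if (y1 >= B || y2 >= B) {
      bool u1 = (y1 >= B && y2 >= B) ? (y1 > y2 || (y1 == y2 && unif_rand() < 0.5))
                                     : (y1 >= B);
      return category_of(false, u1 && !tie, t + t0, g, edges, Q);
    }
    if (t >= tmax) return category_of(true, false, NA_REAL, g, edges, Q);
    double d1 = y1 + dt * (I1 - k_leak * y1 - w * y2) + sigma * norm_rand() * sqdt;
    double d2 = y2 + dt * (I2 - k_leak * y2 - w * y1) + sigma * norm_rand() * sqdt;
    y1 = (d1 > 0.0) ? d1 : 0.0;
    y2 = (d2 > 0.0) ? d2 : 0.0;
    t += dt;
  }
}

// [[Rcpp::export]]
List ibs_lca_cpp(IntegerVector obs, NumericVector I1, NumericVector I2,
                 double k_leak, double w, double a0, double c,
                 double sigma, double t0, LogicalVector tie,
                 IntegerVector g, NumericMatrix edges, int Q,
                 int K_max, double dt, double deadline,
                 NumericVector H, NumericVector H2, double stop_sum) {
  int n = obs.size();
  double sqdt = std::sqrt(dt);
  double nll = 0.0, varsum = 0.0;
  int n_capped = 0;
  bool complete = true;
  for (int i = 0; i < n; ++i) {
    int k = 0;
    bool matched = false;
    while (k < K_max) {
      ++k;
      int cat = lca_draw(I1[i], I2[i], k_leak, w, a0, c, sigma, t0, dt,
                         deadline, tie[i], g[i], edges, Q, sqdt);
      if (cat == obs[i]) { matched = true; break; }
    }
    if (!matched) ++n_capped;
    nll += H[k];
    varsum += H2[k];
    if (stop_sum > 0.0 && nll > stop_sum) { complete = false; break; }
  }
  return List::create(_["nll"] = nll, _["varsum"] = varsum,
                      _["n_capped"] = n_capped, _["complete"] = complete);
}
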