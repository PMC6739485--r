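#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact continuous-time Markov simulation of single-progenitor clones.
//
// State columns (integer matrix, one row per clone):
//   0 n_p   basal progenitors
//   1 n_d   basal post-mitotic (differentiating) cells
//   2 n_s   suprabasal cells
//   3 n_shed cumulative shed cells
//   4..7    EdU-labelled sub-counts of the four compartments above
//   8 n_div cumulative divisions
//
// Events (rates per hour, constant over the step):
//   division      lambda * n_p, outcome PP/PD/DD with probs (p_pp,p_pd,p_dd)
//   induced diff  rho * n_p     (P -> D)
//   stratification gamma * n_d  (D -> S)
//   shedding      mu * n_s      (S -> shed)
//
// A dividing/converting/stratifying/shedding cell is EdU-labelled with
// probability (labelled count)/(compartment count); daughters inherit the
// label and it is never removed.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix sim_step_cpp(IntegerMatrix states,
                           double lambda, double p_pp, double p_pd, double p_dd,
                           double gamma, double mu, double rho,
                           double dt) {
  IntegerMatrix out = clone(states);
  const int n = out.nrow();
  for (int i = 0; i < n; ++i) {
    double t = 0.0;
    int np = out(i, 0), nd = out(i, 1), ns = out(i, 2), shed = out(i, 3);
    int lp = out(i, 4), ld = out(i, 5), ls = out(i, 6), lshed = out(i, 7);
    int ndiv = out(i, 8);
    for (;;) {
      const double r_div = lambda * np, r_rho = rho * np;
      const double r_gam = gamma * nd, r_mu = mu * ns;
      const double R = r_div + r_rho + r_gam + r_mu;
      if (R <= 0.0) break;
      t += R::rexp(1.0) / R;
      if (t >= dt) break;
      const double u = unif_rand() * R;
      if (u < r_div) {
        const bool lab = (lp > 0) && (unif_rand() * np < lp);
        const double v = unif_rand();
        ++ndiv;
        if (v < p_pp) {                 // PP
          ++np; if (lab) ++lp;
        } else if (v < p_pp + p_pd) {   // PD
          ++nd; if (lab) ++ld;
        } else {                        // DD
          --np; nd += 2;
          if (lab) { --lp; ld += 2; }
        }
      } else if (u < r_div + r_rho) {   // induced P -> D
        const bool lab = (lp > 0) && (unif_rand() * np < lp);
        --np; ++nd;
        if (lab) { --lp; ++ld; }
      } else if (u < r_div + r_rho + r_gam) { // D -> S
        const bool lab = (ld > 0) && (unif_rand() * nd < ld);
        --nd; ++ns;
        if (lab) { --ld; ++ls; }
      } else {                          // S -> shed
        const bool lab = (ls > 0) && (unif_rand() * ns < ls);
        --ns; ++shed;
        if (lab) { --ls; ++lshed; }
      }
    }
    out(i, 0) = np; out(i, 1) = nd; out(i, 2) = ns; out(i, 3) = shed;
    out(i, 4) = lp; out(i, 5) = ld; out(i, 6) = ls; out(i, 7) = lshed;
    out(i, 8) = ndiv;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Peacock two-sample two-dimensional Kolmogorov-Smirnov statistic.
//
// D is the maximum absolute difference between the two samples' empirical
// quadrant probabilities, taken over every corner of the full pooled
// coordinate lattice (pooled unique x times pooled unique y), all four
// quadrant orientations, and both boundary conventions (closed <= and
// strict <), which makes the supremum tie-safe on integer-valued data.
// ---------------------------------------------------------------------------

namespace {

struct PooledGrid {
  std::vector<double> xs, ys;      // sorted unique pooled coordinates
  std::vector<int> ix, iy;         // 0-based grid index of every pooled point
  int n1, n2, nx, ny;
};

PooledGrid build_grid(const NumericMatrix& s1, const NumericMatrix& s2) {
  PooledGrid g;
  g.n1 = s1.nrow(); g.n2 = s2.nrow();
  const int n = g.n1 + g.n2;
  g.xs.reserve(n); g.ys.reserve(n);
  for (int i = 0; i < g.n1; ++i) { g.xs.push_back(s1(i, 0)); g.ys.push_back(s1(i, 1)); }
  for (int i = 0; i < g.n2; ++i) { g.xs.push_back(s2(i, 0)); g.ys.push_back(s2(i, 1)); }
  std::vector<double> px = g.xs, py = g.ys;
  std::sort(g.xs.begin(), g.xs.end());
  g.xs.erase(std::unique(g.xs.begin(), g.xs.end()), g.xs.end());
  std::sort(g.ys.begin(), g.ys.end());
  g.ys.erase(std::unique(g.ys.begin(), g.ys.end()), g.ys.end());
  g.nx = (int) g.xs.size(); g.ny = (int) g.ys.size();
  g.ix.resize(n); g.iy.resize(n);
  for (int i = 0; i < n; ++i) {
    g.ix[i] = (int) (std::lower_bound(g.xs.begin(), g.xs.end(), px[i]) - g.xs.begin());
    g.iy[i] = (int) (std::lower_bound(g.ys.begin(), g.ys.end(), py[i]) - g.ys.begin());
  }
  return g;
}

// labels: for each pooled point, true if it belongs to sample 1
double peacock_D_from_labels(const PooledGrid& g, const std::vector<char>& in1) {
  const int nx = g.nx, ny = g.ny, W = ny + 1;
  // padded cumulative count grids: C[(i+1)*W + (j+1)] = #{x <= xs[i], y <= ys[j]}
  std::vector<double> c1((nx + 1) * W, 0.0), c2((nx + 1) * W, 0.0);
  const int n = g.n1 + g.n2;
  for (int k = 0; k < n; ++k) {
    const int pos = (g.ix[k] + 1) * W + (g.iy[k] + 1);
    if (in1[k]) c1[pos] += 1.0; else c2[pos] += 1.0;
  }
  for (int i = 1; i <= nx; ++i)
    for (int j = 1; j <= ny; ++j) {
      const int p = i * W + j;
      c1[p] += c1[p - 1] + c1[p - W] - c1[p - W - 1];
      c2[p] += c2[p - 1] + c2[p - W] - c2[p - W - 1];
    }
  const double inv1 = 1.0 / g.n1, inv2 = 1.0 / g.n2;
  double D = 0.0;
  for (int i = 0; i < nx; ++i) {
    const double fx1c = c1[(i + 1) * W + ny] * inv1, fx2c = c2[(i + 1) * W + ny] * inv2;
    const double fx1o = c1[i * W + ny] * inv1,       fx2o = c2[i * W + ny] * inv2;
    for (int j = 0; j < ny; ++j) {
      // closed convention (<= on both axes)
      const double fy1c = c1[nx * W + j + 1] * inv1, fy2c = c2[nx * W + j + 1] * inv2;
      const double q1c = c1[(i + 1) * W + j + 1] * inv1;
      const double q2c = c2[(i + 1) * W + j + 1] * inv2;
      double d;
      d = std::abs(q1c - q2c); if (d > D) D = d;                                 // (<=, <=)
      d = std::abs((fx1c - q1c) - (fx2c - q2c)); if (d > D) D = d;               // (<=, >)
      d = std::abs((fy1c - q1c) - (fy2c - q2c)); if (d > D) D = d;               // (>, <=)
      d = std::abs((1.0 - fx1c - fy1c + q1c) - (1.0 - fx2c - fy2c + q2c));
      if (d > D) D = d;                                                          // (>, >)
      // strict convention (< on both axes)
      const double fy1o = c1[nx * W + j] * inv1, fy2o = c2[nx * W + j] * inv2;
      const double q1o = c1[i * W + j] * inv1;
      const double q2o = c2[i * W + j] * inv2;
      d = std::abs(q1o - q2o); if (d > D) D = d;                                 // (<, <)
      d = std::abs((fx1o - q1o) - (fx2o - q2o)); if (d > D) D = d;               // (<, >=)
      d = std::abs((fy1o - q1o) - (fy2o - q2o)); if (d > D) D = d;               // (>=, <)
      d = std::abs((1.0 - fx1o - fy1o + q1o) - (1.0 - fx2o - fy2o + q2o));
      if (d > D) D = d;                                                          // (>=, >=)
    }
  }
  return D;
}

} // namespace

// [[Rcpp::export]]
double peacock_D_cpp(NumericMatrix s1, NumericMatrix s2) {
  PooledGrid g = build_grid(s1, s2);
  std::vector<char> in1(g.n1 + g.n2, 0);
  std::fill(in1.begin(), in1.begin() + g.n1, 1);
  return peacock_D_from_labels(g, in1);
}

// Permutation null: random relabellings of the pooled points. Returns the
// observed D and the vector of permuted statistics; RNG is R's (so set.seed
// in R governs the result).
// [[Rcpp::export]]
List peacock_perm_cpp(NumericMatrix s1, NumericMatrix s2, int n_perm) {
  PooledGrid g = build_grid(s1, s2);
  const int n = g.n1 + g.n2;
  std::vector<char> in1(n, 0);
  std::fill(in1.begin(), in1.begin() + g.n1, 1);
  const double D_obs = peacock_D_from_labels(g, in1);
  NumericVector D_perm(n_perm);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<char> lab(n);
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates with R's RNG
    for (int i = n - 1; i > 0; --i) {
      const int j = (int) (unif_rand() * (i + 1));
      std::swap(idx[i], idx[j]);
    }
    std::fill(lab.begin(), lab.end(), 0);
    for (int i = 0; i < g.n1; ++i) lab[idx[i]] = 1;
    D_perm[b] = peacock_D_from_labels(g, lab);
  }
  return List::create(_["D"] = D_obs, _["D_perm"] = D_perm);
}
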