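#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overflow guard shared by all recursions. Trajectories leaving the
// contractive regime grow double-exponentially, so a fixed magnitude cap
// gives a clean diagnostic long before IEEE overflow.
static const double OVERFLOW_CAP = 1e10;

static inline double nlari_update(double y1, double y2,
                                  double alpha, double beta, double eps) {
  return (2.0 - alpha) * y1 - (1.0 - alpha) * y2
         - beta * y1 * std::exp(-y1 * y1) + eps;
}

// [[Rcpp::export]]
NumericVector cpp_nlari_recursion(NumericVector eps, double alpha, double beta,
                                  double y_init1, double y_init2) {
  // y_init1 = Y_0 (one step back), y_init2 = Y_{-1} (two steps back)
  R_xlen_t n = eps.size();
  NumericVector out(n);
  double y1 = y_init1, y2 = y_init2;
  for (R_xlen_t t = 0; t < n; ++t) {
    double yt = nlari_update(y1, y2, alpha, beta, eps[t]);
    if (!std::isfinite(yt) || std::fabs(yt) > OVERFLOW_CAP)
      stop("trajectory overflow at step %d (|Y| > 1e10): parameters outside "
           "the contractive regime for this stimulus scale", (int)(t + 1));
    out[t] = yt;
    y2 = y1;
    y1 = yt;
  }
  return out;
}

static inline double gate1(double x, double c1, double sigma1) {
  if (x >= c1) return c1;
  return sigma1 > 0.0 ? R::rnorm(0.0, sigma1) : 0.0;
}

static inline double decode1(double y, double c1, double c2, double c3,
                             double sigma1) {
  if (y >= c1) return c1;
  if (y >= c2) return y;
  if (y >= c3) return c2;
  return sigma1 > 0.0 ? R::rnorm(0.0, sigma1) : 0.0;
}

// mode: 0 = nomodulation, 1 = all-or-none, 2 = encoder-decoder
// Returns list(final = Y_m, traces = optional list of all Y_i,
//              drives = optional list of per-relay drives,
//              decoded = decode(Y_m) in encoder-decoder mode)
// [[Rcpp::export]]
List cpp_chain(NumericVector stim, double alpha, double beta, int m, int mode,
               double c1, double c2, double c3, double sigma1, bool keep_all) {
  R_xlen_t n = stim.size();
  List traces(keep_all ? m : 0);
  List drives(keep_all ? m : 0);
  NumericVector drive(n), y(n);

  // initial drive entering relay 1
  for (R_xlen_t t = 0; t < n; ++t)
    drive[t] = (mode == 0) ? stim[t] : gate1(stim[t], c1, sigma1);

  for (int i = 1; i <= m; ++i) {
    double y1 = 0.0, y2 = 0.0;  // each relay starts at rest
    for (R_xlen_t t = 0; t < n; ++t) {
      double yt = nlari_update(y1, y2, alpha, beta, drive[t]);
      if (!std::isfinite(yt) || std::fabs(yt) > OVERFLOW_CAP)
        stop("trajectory overflow at relay %d, step %d (|Y| > 1e10)",
             i, (int)(t + 1));
      y[t] = yt;
      y2 = y1;
      y1 = yt;
    }
    if (keep_all) {
      traces[i - 1] = clone(y);
      drives[i - 1] = clone(drive);
    }
    if (i < m) {
      for (R_xlen_t t = 0; t < n; ++t) {
        if (mode == 0)      drive[t] = y[t];
        else if (mode == 1) drive[t] = gate1(y[t], c1, sigma1);
        else                drive[t] = decode1(y[t], c1, c2, c3, sigma1);
      }
    }
  }

  List out = List::create(_["final"] = y);
  if (mode == 2) {
    NumericVector dec(n);
    for (R_xlen_t t = 0; t < n; ++t)
      dec[t] = decode1(y[t], c1, c2, c3, sigma1);
    out["decoded"] = dec;
  }
  if (keep_all) {
    out["traces"] = traces;
    out["drives"] = drives;
  }
  return out;
}

// One grid point of the reliability sweep: T replicates of
// (sound stimulus -> all-or-none gate -> m-relay encoder-decoder chain ->
//  success rate of the c3-binarized output against the binarized stimulus).
// All randomness comes from R's RNG stream so a single set.seed() in R
// makes the whole grid point reproducible.
// [[Rcpp::export]]
NumericVector cpp_sweep_point(int T, int n, int m,
                              double alpha, double beta,
                              double stim_alpha, double stim_beta,
                              double stim_sigma,
                              double c1, double c2, double c3, double sigma1) {
  NumericVector rates(T);
  NumericVector y0(n), stim(n), drive(n), y(n);
  for (int rep = 0; rep < T; ++rep) {
    // sound-wave original signal
    double y1 = 0.0, y2 = 0.0;
    for (int t = 0; t < n; ++t) {
      double yt = nlari_update(y1, y2, stim_alpha, stim_beta,
                               R::rnorm(0.0, stim_sigma));
      if (!std::isfinite(yt) || std::fabs(yt) > OVERFLOW_CAP)
        stop("stimulus overflow at replicate %d, step %d", rep + 1, t + 1);
      y0[t] = yt;
      y2 = y1;
      y1 = yt;
    }
    // all-or-none gating to the initial stimulus
    for (int t = 0; t < n; ++t) stim[t] = gate1(y0[t], c1, sigma1);
    // chain entry gate per the decoder's initialisation
    for (int t = 0; t < n; ++t) drive[t] = gate1(stim[t], c1, sigma1);

    for (int i = 1; i <= m; ++i) {
      y1 = 0.0;
      y2 = 0.0;
      for (int t = 0; t < n; ++t) {
        double yt = nlari_update(y1, y2, alpha, beta, drive[t]);
        if (!std::isfinite(yt) || std::fabs(yt) > OVERFLOW_CAP)
          stop("trajectory overflow at replicate %d, relay %d, step %d",
               rep + 1, i, t + 1);
        y[t] = yt;
        y2 = y1;
        y1 = yt;
      }
      if (i < m)
        for (int t = 0; t < n; ++t)
          drive[t] = decode1(y[t], c1, c2, c3, sigma1);
    }

    int mismatches = 0;
    for (int t = 0; t < n; ++t) {
      int v0 = stim[t] >= c3 ? 1 : 0;
      int vm = y[t] >= c3 ? 1 : 0;
      if (v0 != vm) ++mismatches;
    }
    rates[rep] = 100.0 * (1.0 - (double)mismatches / (double)n);
  }
  return rates;
}
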