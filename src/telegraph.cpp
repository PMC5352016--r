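#include <Rcpp.h>
using namespace Rcpp;

// Two-state Markov chain on a fixed time grid.  p_down[i] / p_up[i] are the
// per-step flip probabilities 1 - exp(-r dt) out of the +1 / -1 state during
// step i (they vary in time when the applied field does).  Uses R's RNG so
// set.seed() makes trajectories exactly reproducible.

// [[Rcpp::export]]
IntegerVector telegraph_chain(NumericVector p_down, NumericVector p_up,
                              int state0) {
  const R_xlen_t n = p_down.size();
  if (p_up.size() != n) stop("probability vectors must have equal length");
  IntegerVector out(n);
  int st = (state0 >= 0) ? 1 : -1;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double p = (st > 0) ? p_down[i] : p_up[i];
    if (unif_rand() < p) st = -st;
    out[i] = st;
  }
  return out;
}
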