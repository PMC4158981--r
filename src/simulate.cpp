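#include <Rcpp.h>
using namespace Rcpp;

// Step the birth-death walk for a batch of trials.
//
// order:     n_trials x L, 1-based attribute index per stage
// durations: n_trials x L, steps per stage; NA in the last column means the
//            stage runs until absorption (infinite horizon)
// p_up:      (m-2) x K matrix of up-move probabilities per transient state
// start:     1-based transient state index per trial
// max_steps: safety cap on total steps per trial
//
// Returns choice (+1 A, -1 B, 0 none) and the absorption step count
// (NA for none).  Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List walk_trials_cpp(IntegerMatrix order, IntegerMatrix durations,
                     NumericMatrix p_up, IntegerVector start,
                     double max_steps) {
  const int n_trials = order.nrow();
  const int L = order.ncol();
  const int S = p_up.nrow();  // number of transient states

  IntegerVector choice(n_trials);
  NumericVector steps(n_trials);

  for (int t = 0; t < n_trials; ++t) {
    int s = start[t];          // 1..S
    double n = 0.0;
    int out = 0;
    for (int l = 0; l < L && out == 0; ++l) {
      const int k = order(t, l) - 1;
      const int dur = durations(t, l);
      const bool unbounded = (dur == NA_INTEGER);
      double remaining = unbounded ? max_steps - n : (double)dur;
      for (double j = 0; j < remaining; ++j) {
        const double u = unif_rand();
        if (u < p_up(s - 1, k)) ++s; else --s;
        n += 1.0;
        if (s < 1) { out = -1; break; }
        if (s > S) { out = 1; break; }
      }
    }
    choice[t] = out;
    steps[t] = (out == 0) ? NA_REAL : n;
  }
  return List::create(_["choice"] = choice, _["steps"] = steps);
}
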