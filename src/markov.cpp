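#include <Rcpp.h>
using namespace Rcpp;

// Generate one realization of an order-1 Markov chain over 4 states.
// cum: 4x4 matrix of row-wise cumulative transition probabilities.
// init_cum: length-4 cumulative initial (stationary) distribution.
// Uses R's RNG (one uniform per symbol), so draws are reproducible from
// set.seed() and interleave deterministically with R-level draws.
// [[Rcpp::export]]
IntegerVector markov_chunk_cpp(NumericMatrix cum, NumericVector init_cum, int n) {
  IntegerVector out(n);
  if (n <= 0) return out;
  double u = unif_rand();
  int state = 0;
  while (state < 3 && u > init_cum[state]) ++state;
  out[0] = state + 1;
  for (int i = 1; i < n; ++i) {
    u = unif_rand();
    int s = 0;
    while (s < 3 && u > cum(state, s)) ++s;
    state = s;
    out[i] = state + 1;
  }
  return out;
}
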