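#include <Rcpp.h>
using namespace Rcpp;

// Generic Viterbi best-path decoding over an arbitrary left-to-right graph.
// logemis: T x S matrix of per-frame state log emission densities.
// Arcs (from, to, logp) are 1-based state indices; init/final likewise.
// Ties resolve to the earlier-indexed predecessor (deterministic decoding).
// [[Rcpp::export]]
List viterbi_decode(NumericMatrix logemis, IntegerVector arc_from,
                    IntegerVector arc_to, NumericVector arc_logp,
                    IntegerVector init_states, NumericVector init_logp,
                    IntegerVector final_states) {
  const int T = logemis.nrow();
  const int S = logemis.ncol();
  const int A = arc_from.size();
  const double NEG = -1e300;
  if (T < 1) stop("empty observation sequence");

  std::vector<double> prev(S, NEG), cur(S, NEG);
  IntegerMatrix psi(T, S);
  std::fill(psi.begin(), psi.end(), -1);

  for (int i = 0; i < init_states.size(); ++i) {
    int s = init_states[i] - 1;
    double v = init_logp[i] + logemis(0, s);
    if (v > prev[s]) prev[s] = v;
  }
  for (int t = 1; t < T; ++t) {
    std::fill(cur.begin(), cur.end(), NEG);
    for (int a = 0; a < A; ++a) {
      int u = arc_from[a] - 1, v = arc_to[a] - 1;
      if (prev[u] <= NEG) continue;
      double cand = prev[u] + arc_logp[a];
      if (cand > cur[v]) { cur[v] = cand; psi(t, v) = u; }
    }
    for (int s = 0; s < S; ++s)
      if (cur[s] > NEG) cur[s] += logemis(t, s);
    std::swap(prev, cur);
  }
  int best = -1;
  double best_lp = NEG;
  for (int i = 0; i < final_states.size(); ++i) {
    int s = final_states[i] - 1;
    if (prev[s] > best_lp) { best_lp = prev[s]; best = s; }
  }
  if (best < 0) stop("no admissible path through the grammar");
  IntegerVector path(T);
  path[T - 1] = best + 1;
  for (int t = T - 1; t > 0; --t) {
    best = psi(t, best);
    if (best < 0) stop("broken backtrace");
    path[t - 1] = best + 1;
  }
  return List::create(_["path"] = path, _["logprob"] = best_lp);
}
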