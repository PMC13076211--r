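#include <Rcpp.h>
using namespace Rcpp;

// Minimum-penalty path through the decoder state space.
//
// Penalties are additive: an emission penalty per base per state (genic
// class column plus, for CDS substates, a phase column) and a transition
// penalty per step looked up from the per-position condition-penalty matrix
// (kindpen).  Ties are broken deterministically by transition order: the
// transition list is pre-sorted so that, for equal costs, the earlier
// (intergenic-first, lower state id) predecessor wins via strict-less
// updates.
//
// All indices are 0-based on entry.
// [[Rcpp::export]]
List viterbi_min_path(IntegerVector tr_from, IntegerVector tr_to,
                      IntegerVector tr_kind,
                      NumericMatrix clpen, NumericMatrix phpen,
                      NumericMatrix kindpen,
                      IntegerVector state_class, IntegerVector state_phase,
                      int init_state, int final_state) {
  const int n = clpen.nrow();
  const int S = state_class.size();
  const int T = tr_from.size();
  const double INF = R_PosInf;

  std::vector<double> prev(S, INF), cur(S, INF);
  IntegerMatrix ptr(n, S);
  std::fill(ptr.begin(), ptr.end(), -1);

  auto emis = [&](int i, int s) -> double {
    double e = clpen(i, state_class[s]);
    if (state_phase[s] >= 0) e += phpen(i, state_phase[s]);
    return e;
  };

  prev[init_state] = emis(0, init_state);

  for (int i = 1; i < n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    for (int t = 0; t < T; ++t) {
      const double a = prev[tr_from[t]];
      if (a == INF) continue;
      const double p = kindpen(i, tr_kind[t]);
      if (p == INF) continue;
      const double cand = a + p;
      if (cand < cur[tr_to[t]]) {
        cur[tr_to[t]] = cand;
        ptr(i, tr_to[t]) = tr_from[t];
      }
    }
    for (int s = 0; s < S; ++s) {
      if (cur[s] < INF) cur[s] += emis(i, s);
    }
    std::swap(prev, cur);
  }

  const double total = prev[final_state];
  IntegerVector path(n, -1);
  if (total < INF) {
    int s = final_state;
    for (int i = n - 1; i >= 0; --i) {
      path[i] = s;
      if (i > 0) s = ptr(i, s);
    }
  }
  return List::create(_["cost"] = total, _["path"] = path);
}
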