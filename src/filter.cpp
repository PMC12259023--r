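#include <Rcpp.h>
using namespace Rcpp;

// Sequential Bayesian filtering of a belief over the discretised preference
// grid through one pass of phase-2 partner decisions.
//
// P        : states x unique-trial-types matrix of p(option 1 | state)
// type_idx : 1-based column of P for each trial
// d        : observed partner decision per trial (1 or 2)
// prior    : normalised belief vector over states
// floor_val: noise floor added before each normalisation
// keep_path: also return the states x trials matrix of post-update beliefs
//
// Returns the pre-update predictive probability of option 1 on every trial
// (used for probability-matched predictions) and the final posterior.
// [[Rcpp::export]]
List phase2_filter_cpp(NumericMatrix P, IntegerVector type_idx, IntegerVector d,
                       NumericVector prior, double floor_val, bool keep_path) {
  const int S = prior.size();
  const int T = type_idx.size();
  NumericVector bel = clone(prior);
  NumericVector predp(T);
  NumericMatrix path;
  if (keep_path) path = NumericMatrix(S, T);
  double *b = REAL(bel);
  const double *Pm = REAL(P);

  for (int t = 0; t < T; ++t) {
    const double *pc = Pm + (R_xlen_t)(type_idx[t] - 1) * S;
    double p = 0.0;
    for (int s = 0; s < S; ++s) p += pc[s] * b[s];
    predp[t] = p;
    double tot = 0.0;
    if (d[t] == 1) {
      for (int s = 0; s < S; ++s) { b[s] = b[s] * pc[s] + floor_val; tot += b[s]; }
    } else {
      for (int s = 0; s < S; ++s) { b[s] = b[s] * (1.0 - pc[s]) + floor_val; tot += b[s]; }
    }
    const double inv = 1.0 / tot;
    for (int s = 0; s < S; ++s) b[s] *= inv;
    if (keep_path) {
      double *pt = REAL(path) + (R_xlen_t)t * S;
      for (int s = 0; s < S; ++s) pt[s] = b[s];
    }
  }
  if (keep_path)
    return List::create(_["pred_p"] = predp, _["posterior"] = bel, _["path"] = path);
  return List::create(_["pred_p"] = predp, _["posterior"] = bel);
}
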