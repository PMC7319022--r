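#include <Rcpp.h>
using namespace Rcpp;

// Forward-algorithm marginal log-likelihood for joint live-recapture /
// dead-recovery encounter histories over the four latent states
// (1 alive inside, 2 alive outside, 3 recently dead, 4 dead).
//
// sym:   n x T matrix, codes 0 not seen / 1 seen alive / 2 recovered dead,
//        -1 before the marking occasion.
// first: 1-based marking occasion per history.
// mult:  multiplicity weight per history.
// S,F,r: per-interval probabilities (length T-1), interval t -> t+1.
// p:     recapture probability at occasions 2..T (length T-1).
//
// Conditioning: state at the marking occasion is alive-inside with
// probability 1; the marking observation carries no information.
// A history ends at its dead-recovery occasion: the dead state is absorbing
// and silent, so later not-seen symbols have probability 1.
// [[Rcpp::export]]
double je_loglik_cpp(IntegerMatrix sym, IntegerVector first,
                     NumericVector mult, NumericVector S, NumericVector F,
                     NumericVector r, NumericVector p) {
  const int n = sym.nrow(), T = sym.ncol();
  if (S.size() != T - 1 || F.size() != T - 1 || r.size() != T - 1 ||
      p.size() != T - 1)
    stop("parameter vectors must have length n_occasions - 1");
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const int f = first[i];  // 1-based
    double a1 = 1.0, a2 = 0.0, a3 = 0.0, a4 = 0.0;  // alpha at occasion f
    double ll = 0.0;
    bool impossible = false;
    for (int t = f + 1; t <= T; ++t) {
      const int k = t - 2;  // 0-based interval / recapture index
      const double St = S[k], Ft = F[k], rt = r[k], pt = p[k];
      // propagate one interval
      const double b1 = a1 * St * Ft;
      const double b2 = a1 * St * (1.0 - Ft) + a2 * St;
      const double b3 = (a1 + a2) * (1.0 - St) * rt;
      const double b4 = (a1 + a2) * (1.0 - St) * (1.0 - rt) + a3 + a4;
      const int y = sym(i, t - 1);
      if (y == 1) {            // seen alive: only possible inside
        a1 = b1 * pt; a2 = 0.0; a3 = 0.0; a4 = 0.0;
      } else if (y == 2) {     // recovered dead: only recently dead
        a1 = 0.0; a2 = 0.0; a3 = b3; a4 = 0.0;
      } else {                 // not seen
        a1 = b1 * (1.0 - pt); a2 = b2; a3 = 0.0; a4 = b4;
      }
      const double s = a1 + a2 + a3 + a4;
      if (s <= 0.0) { impossible = true; break; }
      // rescale to guard against underflow on long silent histories
      ll += std::log(s);
      a1 /= s; a2 /= s; a3 /= s; a4 /= s;
      if (y == 2) break;  // absorbed: the remainder is deterministic
    }
    total += mult[i] * (impossible ? R_NegInf : ll);
  }
  return total;
}
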