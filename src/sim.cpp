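#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama simulation of the bounded accumulation process
//   dV = a dt + dW,  V(0) = 0,  absorption at |V| >= B.
//
// Controlled-duration trials (freeResponse = false) integrate until the
// bound or until tDur, whichever comes first; unabsorbed trials are decided
// by the sign of the integrated evidence.  Free-response trials integrate
// until absorption (capped at tCap; capped trials are flagged).
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List sim_ddm_paths(NumericVector drift, NumericVector tDur, double B,
                   double dt, bool freeResponse, double tCap) {
  const int n = drift.size();
  if (!freeResponse && tDur.size() != n)
    stop("tDur must match drift length for controlled-duration trials");
  if (B <= 0.0) stop("bound height B must be positive");
  if (dt > 1e-3 + 1e-12)
    stop("Euler step dt must be <= 1 ms for acceptable absorption bias");

  IntegerVector choice(n);
  LogicalVector absorbed(n);
  NumericVector decTime(n);
  const double sdt = std::sqrt(dt);

  for (int i = 0; i < n; ++i) {
    const double a = drift[i];
    const double tEnd = freeResponse ? tCap : tDur[i];
    double V = 0.0, t = 0.0;
    bool hit = false;
    while (t < tEnd - 1e-12) {
      V += a * dt + sdt * norm_rand();
      t += dt;
      if (V >= B) { choice[i] = 1; hit = true; break; }
      if (V <= -B) { choice[i] = -1; hit = true; break; }
    }
    absorbed[i] = hit;
    if (hit) {
      decTime[i] = t;
    } else {
      decTime[i] = NA_REAL;
      choice[i] = (V > 0.0) ? 1 : (V < 0.0 ? -1 : (unif_rand() < 0.5 ? 1 : -1));
    }
  }
  return List::create(_["choice"] = choice, _["absorbed"] = absorbed,
                      _["decTime"] = decTime);
}
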