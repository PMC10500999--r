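#include <Rcpp.h>
using namespace Rcpp;

// Crank-Nicolson march of the Fokker-Planck equation
//   dp/dt = -a dp/dV + 0.5 d2p/dV2
// on V in (-B, B) with absorbing (Dirichlet) boundaries and initial
// condition p(V,0) = delta(V).  The diffusion coefficient is fixed at 1
// (evidence is accumulated against a standard Wiener process), so drift a
// and bound B are in those normalized units.
//
// nv is the number of grid intervals (must be even so V = 0 is a node);
// interior nodes j = 1..nv-1.  The first two time steps are taken as four
// backward-Euler half-steps (Rannacher smoothing) to damp the oscillations
// Crank-Nicolson produces from the delta initial condition.
//
// Returned per time step: instantaneous absorption densities at the two
// bounds (one-sided second-order flux), their running integrals, and the
// probability mass still in (0, B) and in (-B, B).
// [[Rcpp::export]]
List fp_march(double drift, double B, double tMax, double dt, int nv) {
  if (B <= 0.0) stop("bound height B must be positive");
  if (dt <= 0.0 || tMax <= 0.0) stop("dt and tMax must be positive");
  if (nv < 8) stop("nv too small");
  if (nv % 2 != 0) nv += 1;

  const int m = nv - 1;            // interior nodes
  const double h = 2.0 * B / nv;
  const int nt = (int) std::ceil(tMax / dt - 1e-9);

  // operator L coefficients (constant over the grid)
  const double lo = 0.5 / (h * h) + drift / (2.0 * h); // p_{j-1}
  const double di = -1.0 / (h * h);                    // p_j
  const double up = 0.5 / (h * h) - drift / (2.0 * h); // p_{j+1}

  // LHS = I - dt/2 L, RHS matrix = I + dt/2 L
  const double al = -0.5 * dt * lo;
  const double ad = 1.0 - 0.5 * dt * di;
  const double au = -0.5 * dt * up;
  const double bl = 0.5 * dt * lo;
  const double bd = 1.0 + 0.5 * dt * di;
  const double bu = 0.5 * dt * up;

  // Thomas factorization of the constant tridiagonal LHS
  std::vector<double> cp(m), den(m);
  den[0] = ad;
  cp[0] = au / ad;
  for (int j = 1; j < m; ++j) {
    den[j] = ad - al * cp[j - 1];
    cp[j] = au / den[j];
  }

  std::vector<double> p(m, 0.0), rhs(m);
  const int jc = nv / 2 - 1;       // interior index of V = 0
  p[jc] = 1.0 / h;

  NumericVector tGrid(nt), fPlus(nt), fMinus(nt), FPlus(nt), FMinus(nt),
                survPos(nt), survTot(nt);

  auto thomas = [&](std::vector<double>& x) {
    x[0] = x[0] / den[0];
    for (int j = 1; j < m; ++j) x[j] = (x[j] - al * x[j - 1]) / den[j];
    for (int j = m - 2; j >= 0; --j) x[j] -= cp[j] * x[j + 1];
  };

  auto record = [&](int n) {
    tGrid[n] = (n + 1) * dt;
    // outgoing flux at the bounds; p = 0 on the boundary nodes
    double fp = (4.0 * p[m - 1] - p[m - 2]) / (4.0 * h);
    double fm = (4.0 * p[0] - p[1]) / (4.0 * h);
    fPlus[n] = fp > 0.0 ? fp : 0.0;
    fMinus[n] = fm > 0.0 ? fm : 0.0;
    if (n == 0) {
      FPlus[n] = 0.5 * dt * fPlus[n];
      FMinus[n] = 0.5 * dt * fMinus[n];
    } else {
      FPlus[n] = FPlus[n - 1] + 0.5 * dt * (fPlus[n - 1] + fPlus[n]);
      FMinus[n] = FMinus[n - 1] + 0.5 * dt * (fMinus[n - 1] + fMinus[n]);
    }
    // trapezoid over V >= 0 (half weight at V = 0) and over all V
    double sPos = 0.5 * p[jc];
    for (int j = jc + 1; j < m; ++j) sPos += p[j];
    double sTot = 0.0;
    for (int j = 0; j < m; ++j) sTot += p[j];
    survPos[n] = sPos * h;
    survTot[n] = sTot * h;
  };

  int n = 0;
  if (nt >= 2) {
    // Rannacher: 4 backward-Euler half-steps share the CN LHS matrix
    for (int s = 0; s < 4; ++s) {
      thomas(p);
      if (s == 1) record(n++);
      if (s == 3) record(n++);
    }
  }
  for (; n < nt; ++n) {
    rhs[0] = bd * p[0] + bu * p[1];
    for (int j = 1; j < m - 1; ++j)
      rhs[j] = bl * p[j - 1] + bd * p[j] + bu * p[j + 1];
    rhs[m - 1] = bl * p[m - 2] + bd * p[m - 1];
    p.swap(rhs);
    thomas(p);
    record(n);
  }

  NumericVector vGrid(m), pFinal(m);
  for (int j = 0; j < m; ++j) {
    vGrid[j] = -B + (j + 1) * h;
    pFinal[j] = p[j];
  }

  return List::create(
    _["t"] = tGrid, _["v"] = vGrid,
    _["fPlus"] = fPlus, _["fMinus"] = fMinus,
    _["FPlus"] = FPlus, _["FMinus"] = FMinus,
    _["survPos"] = survPos, _["survTot"] = survTot,
    _["pFinal"] = pFinal, _["h"] = h, _["dt"] = dt, _["drift"] = drift,
    _["B"] = B);
}
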