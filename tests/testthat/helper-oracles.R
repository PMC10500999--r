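# Independent closed-form oracles used by the tests.  These are derived
# directly from standard results (inverse-CDF of the truncated
# exponential; spectral series for absorption of drifted Brownian motion
# on an interval; logistic asymptote of the two-bound absorption
# probability) and never call the solver paths they check.

# truncated-exponential CDF on [tMin, tMax] with time constant tau
truncExpCDF <- function(t, tMin, tMax, tau) {
  z <- (1 - exp(-(pmin(pmax(t, tMin), tMax) - tMin) / tau)) /
    (1 - exp(-(tMax - tMin) / tau))
  ifelse(t < tMin, 0, ifelse(t > tMax, 1, z))
}

# asymptotic probability of absorption at +B for drift a, bounds +-B,
# start 0, unit diffusion
logisticAbsorption <- function(a, B) 1 / (1 + exp(-2 * a * B))

# cumulative probability absorbed at the upper (or lower) bound by time t:
# eigenfunction series for Brownian motion with drift a on [0, 2B]
# started at B, written as the asymptote minus the decaying tail so the
# series converges fast for t > 0
seriesAbsorbed <- function(t, a, B, upper = TRUE, nTerms = 400) {
  L <- 2 * B
  x0 <- B
  n <- seq_len(nTerms)
  lam <- a^2 / 2 + n^2 * pi^2 / (2 * L^2)
  sgn <- if (upper) (-1)^(n + 1) else rep(1, nTerms)
  pref <- if (upper) exp(a * (L - x0)) else exp(-a * x0)
  pUp <- if (abs(a) < 1e-12) x0 / L else
    (1 - exp(-2 * a * x0)) / (1 - exp(-2 * a * L))
  pInf <- if (upper) pUp else 1 - pUp
  vapply(t, function(tt)
    pInf - pref * (pi / L^2) *
      sum(sgn * n * sin(n * pi * x0 / L) * exp(-lam * tt) / lam),
    numeric(1))
}

# exact mean absorption time for symmetric bounds and start at 0
meanAbsorptionTime <- function(a, B) {
  if (abs(a) < 1e-12) B^2 else (B / a) * tanh(a * B)
}

# probability-conservation error of an FPSolution
conservationError <- function(sol) {
  n <- length(sol@t)
  abs(sol@FPlus[n] + sol@FMinus[n] + sol@survTot[n] - 1)
}
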