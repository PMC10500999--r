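---
title: "Models and methods behind lipbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lipbeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipbeta)
```

lipbeta implements the computational core of a study of *routed*
perceptual decisions in the primate lateral intraparietal area (LIP):
a bounded drift-diffusion model of choice with misrouting extensions,
fitted by maximum likelihood through a Fokker-Planck solver, and a
Matching-Pursuit / Wigner-Ville quantification of brief low-beta
(12-20 Hz) oscillations in firing rates and local field potentials,
together with the resampling statistics and spike-field phase analysis
that accompany those measurements.  Because the recordings themselves
are not public, the package ships seeded generators that produce
behavioural, spike-train and LFP data with the statistical structure the
analyses assume; every downstream stage is exercised end to end on that
synthetic data.

## The behavioural model

Momentary motion evidence is integrated as a drifted Wiener process

$$dV = \kappa\,(C + C_0)\,dt + dW, \qquad V(0) = 0,$$

with unit diffusion coefficient (so the drift gain $\kappa$ and the bound
height $B$ are expressed in those normalized units), absorbed at $\pm B$.
In the controlled-duration tasks the stimulus is switched off at
$t_{dur}$ and unabsorbed trials are decided by the sign of the integrated
evidence; in the free-response task the absorption time plus a
direction-specific non-decision time expectation
($T_{nd}^{+}, T_{nd}^{-}$, modeled as deterministic shifts) gives the
response time.

Two misrouting extensions apply to the cued-attention task, where an
uninformative motion patch accompanies the cued one:

* **incomplete suppression** - on trials where the two patches move in
  opposite directions the drift gain is a separate parameter
  $\kappa_{opp} < \kappa$;
* **wrong-patch routing** - on a fraction $\lambda$ of
  opposite-direction trials the decision is based on the wrong patch, so
  the observed choice probability is the mixture
  $P_+ = (1-\lambda)\,\tilde P_+ + \lambda\,\tilde P_-$.

The generator realizes the mixture by flipping the simulated choice on a
$\lambda$ fraction of opposite-direction trials, which is exactly the
contract the likelihood assumes (a coherence sign flip would differ
whenever $C_0 \ne 0$).

### Numerical solution and likelihood

`solveBoundedDiffusion()` marches the Fokker-Planck equation with
Crank-Nicolson finite differences: absorbing Dirichlet boundaries,
evidence grid step $B/250$, default time step 0.5 ms, and four
backward-Euler half-steps at the start (Rannacher smoothing) to damp the
oscillations the scheme otherwise develops from the delta initial
condition.  Bound absorption densities are read from one-sided
second-order boundary fluxes.  The three solution components - upper
absorption, lower absorption, unabsorbed interior mass - must sum to one
within $10^{-3}$ on every solve; a violation raises an error suggesting
grid refinement rather than returning a silently wrong density.

The controlled-duration likelihood needs one march per coherence-by-
condition group; the running readout of
$\tilde P_+(t) = F_+(t) + \int_0^B f_{un}\,dV$ is interpolated at each
trial's exact duration.  The free-response likelihood bins each trial's
decision time (response time minus the fitted non-decision shift) into
10 ms bins of the absorption-time distribution for the chosen bound.  A
per-trial probability floor of $10^{-6}$ keeps the objective finite
anywhere in the box.

`fitDDM()` runs a derivative-free simplex (Nelder-Mead on transformed
coordinates that respect the bounds $\kappa,\kappa_{opp} \in (0,100]$,
$B \in (0,5]$, $C_0 \in [-0.3, 0.3]$, $\lambda \in [0, 0.5]$,
$T_{nd} \in [0,1]$) from eight random starts by default.  The
exploratory starts are scored on a half-resolution grid (2 ms, $B/125$)
and the winner is polished on the full likelihood grid (1 ms, $B/250$);
Crank-Nicolson is second order, and the 1 ms marching step used in the
likelihood changes choice probabilities by under $10^{-4}$ - far below
the statistical error of any fit - while halving fit time relative to
the solver's display default of 0.5 ms.

Two identifiability facts, both visible in the test suite, are worth
knowing.  First, with choice-only controlled-duration data the bound is
weakly identified (the likelihood is nearly flat in $B$ once absorption
becomes rare); response times identify it sharply.  Second,
$\lambda$ and $\kappa_{opp}$ trade off against each other - both flatten
the opposite-direction psychometric curve - so the maximum-likelihood
$\lambda$ has a replicate-to-replicate dispersion of roughly $\pm 0.015$
at 20,000 trials even though its average is unbiased.

### Model comparison

`compareDDM()` reports BIC differences; the conventional reading is that
the model with the smaller BIC is supported, with $|\Delta\mathrm{BIC}|$
the strength of support.  The nesting identities (the full model with
$\lambda = 0$, $\kappa_{opp} = \kappa$ reproduces the base likelihood
exactly) are asserted in the tests.

## Oscillation quantification

Firing rates enter the analysis as raw 1 ms PSTHs over
$-0.3 \le t < 0.724$ s around the event (no smoothing - the 100 ms
boxcar in `boxcarSmooth()` is a display convention that would erase the
oscillations).  LFPs enter as the trial-averaged voltage at 1 kHz.

`matchingPursuit()` decomposes the mean-subtracted signal into Gabor
atoms

$$g_{\gamma}(t) = e^{-\pi (t-\tau)^2/\sigma^2}
  \cos\!\big(\xi (t-\tau) + \phi\big), \qquad \gamma = \{\tau, \sigma, \xi\},$$

greedily: each iteration screens every $(\sigma, \xi)$ pair over all
centers $\tau$ at once through an FFT cross-correlation of the residual
with the complex kernel, then re-projects the winning candidate exactly
in the time domain (a two-dimensional projection onto its cosine and
sine quadratures over the truncated support).  The exact re-projection
is what makes the energy bookkeeping - atom energies plus residual
energy equal signal energy - hold to float precision even for atoms
clipped by the window edges.  The dictionary places $\tau$ at every
sample, $\sigma$ on a dyadic ladder from two samples to the signal
length (its extremes standing in for the impulse and windowed-sinusoid
limit atoms of classical MP dictionaries), and carriers every 0.5 Hz up
to 50 Hz.  The stop rule is 50 atoms or residual energy below 1% of
signal energy.  Mean subtraction happens first so the DC offset does not
consume iterations.

The Wigner-Ville distribution of a Gabor atom has a closed form - a 2-D
Gaussian centered at $(\tau, \xi/2\pi)$ with time spread
$\sigma/(2\sqrt{\pi})$ and frequency spread $1/(2\sqrt{\pi}\sigma)$ -
and `wignerVilleMap()` sums these per-atom terms, omitting cross terms.
The band/epoch statistic $\bar P$ is the mean of that map over a
frequency band and time epoch; `bandEpochPower()` evaluates it in closed
form from the atom parameters (identical, up to grid discretization, to
averaging the map cells), with the conventional band 12-20 Hz and the
half-open epochs $[-90, 0)$ ms (pre) and $[40, 130)$ ms (post).

One physical caveat the tests respect: a transient of envelope width
$\sigma$ has frequency spread $1/(2\sqrt{\pi}\sigma)$, so very short
transients (2 cycles or fewer) smear across neighbouring bands no matter
how the analysis is tuned.  Band-selectivity fixtures therefore use
envelopes of four or more carrier cycles.

## Synthetic data: what it emulates and what it does not

* **Durations** are truncated-exponential (`sampleTruncExp()`), with the
  task's stated ranges (0.1-1.5 s, $\tau$ = 0.35 s for cued attention;
  0.1-1 s, $\tau$ = 0.25 s for variable location).
* **Trials** draw a coherence magnitude uniformly from
  \{0, 3.2, 6.4, 12.8, 25.6, 51.2\}% (the strongest value excluded for
  the free-response monkey), a uniform sign, an equiprobable cue
  location, and a same/opposite relation with probability 1/3 same.
  Zero-coherence trials are rewarded with probability one half.
* **Choices** come from Euler-Maruyama paths of the diffusion at a
  0.1 ms step (absorption-time bias well under a millisecond) with the
  choice-flip implementation of $\lambda$.
* **Spike trains** are inhomogeneous Poisson by thinning (exact; no bin
  discretization), with a rate of baseline + optional
  coherence-proportional ramp + Gabor transient, rectified at zero.
  Per-trial temporal jitter of the transient center (one normal shift
  per trial, not per-sample noise, which would change the spectrum)
  reproduces the dephasing that hides oscillations from trial averages.
* **LFPs** are the deterministic transient plus 1/f-amplitude noise
  (spectral shaping of white noise, high-passed at 1 Hz - the
  conventional surrogate for extracellular background).  Spike-LFP
  coupling re-times spikes inside the transient support by thinning
  against the carrier, making spike density maximal at the trough
  (phase $\pi$).
* The canonical fixture `dm49RateSpec()` mirrors the vividly
  oscillating example neuron: baseline 20 spikes/s, transient at
  16.7 Hz, center 85 ms, envelope width 80 ms, peak 25 spikes/s - three
  to four raster-visible cycles peaking at two to three times baseline.
  The oscillation amplitude relative to baseline is not published, so
  this prominence is a package choice, fixed once; at 500 trials it
  yields dominant-atom carrier recovery within 1 Hz and a post/pre
  band-power ratio above ten.

What the generators do **not** emulate: sub-Poisson (refractory) spiking
statistics, rate adaptation, cross-trial nonstationarity, electrode
drift, volume conduction, or any coupling between decision state and
oscillation amplitude beyond the cued-location contrast.  Passing tests
therefore certify the *analysis pipeline* - not that real LIP data must
behave this way.

## Resampling statistics

* `subsampledPowerDifference()` implements the N10 bootstrap for
  unequal trial counts: $N_{10}$ is 10% of the smaller condition
  (rounded half-up, floored at 5), subsets are drawn **without**
  replacement, and the statistic is the mean power difference over the
  inner resamples.  The null repeats the identical procedure after
  randomly splitting the pooled trials into pseudo-conditions of the
  original sizes, once per outer repetition; the p value is the
  two-tailed tail probability with add-one correction.  The
  permutation-style null is what makes the test exact under
  exchangeability - building the null from subsets of the union without
  re-splitting leaves dataset-level variability out of the null and
  makes the test conservative, which the calibration suite would catch.
* `perUnitBlockTest()` splits a unit's trials into consecutive blocks
  (incomplete final block dropped) and applies the signed-rank test to
  per-block pre/post powers.
* `locationPreferenceTest()` permutes cued-location labels and
  recomputes the trial-averaged powers for the absolute post-power
  difference.
* `preferredRatioAnalysis()` fixes each unit's preferred location from
  all trials (so the all-trials ratio is at least one by construction),
  recomputes the ratio on correct-only and error-only trials with the
  designation retained, and compares the log-ratio distributions by a
  two-sample Kolmogorov-Smirnov test (log scale for symmetry between a
  ratio and its reciprocal).  Because the band-power estimate has an
  additive noise floor that scales inversely with trial count, unequal
  cell sizes would bias correct-vs-error comparisons even when the
  underlying amplitudes are outcome-independent; the analysis therefore
  subsamples every location-by-outcome cell to the unit's smallest cell
  (seeded) before computing the outcome-specific ratios.

All resampling is seeded and reproducible; the calibration suite runs
each bespoke test 200 times under its own null and requires the
empirical type-I rate at $\alpha = 0.05$ to fall in [0.02, 0.08].  The
calibration and power replicates run with `fastPowerConfig()` - a
256 ms window at 2 ms bins with a lean dictionary that preserves the
band and epochs - so the suites finish in minutes; the statistics
themselves are configuration-agnostic.

## Spike-field alignment

A neuron-LFP recording qualifies when one of the ten strongest atoms of
the trial-averaged LFP decomposition has its carrier in 12-20 Hz and
support ($\tau \pm 2\sigma$) overlapping the post epoch.  Spike phases
are the inverse cosine of that atom's carrier at the spike time -
principal values in $[0, \pi]$, peak $\mapsto 0$, trough
$\mapsto \pi$; the folding is deliberate and matches the convention of
reporting cosine phase without distinguishing rising from falling
half-cycles.  Because a regularly sampled epoch represents cosine phase
nonuniformly (the arccos density diverges at 0 and $\pi$), the phase
histogram divides spike-phase counts per 10 degree bin by the counts of
all candidate phases the carrier contributes over the epoch samples;
uniformity is tested by comparing the spike-phase cumulative
distribution with the candidate-phase cumulative distribution
(Kolmogorov-Smirnov; the comparison is one-sample against the candidate
CDF because the candidates are a deterministic sampling of the carrier,
not a random sample - treating them as a second random sample makes the
test wildly conservative, which the calibration suite exposes).  A bin
the carrier never visits cannot
be corrected and is merged into its nearest populated neighbour.  The
bin width is configurable; 10 degrees is the documented convention,
though coarser displays (30 degrees) appear in published figures.

## Design choices on genuinely open points

* **Fitting pools stimulus locations.**  Whether the published fits
  pooled the two locations per monkey is unstated; the likelihood here
  pools, and location-resolved fits can be had by subsetting the trial
  table.
* **Subsets without replacement** in the N10 bootstrap (the published
  description does not say); with $N_{10}$ at 10% of the pool the
  difference is minor.
* **Strong versus weak coherence strata** for the error analysis are
  the top two and bottom two magnitudes (the bottom including 0%).
* **Euler step** 0.1 ms for the path generator; **Crank-Nicolson**
  0.5 ms / $B/250$ for the solver; both stated above with their
  rationale.
* **Pipeline seeding**: a single master seed spawns per-stage seeds by
  hashing the stage name (`stageSeed()`), so stages rerun in isolation.

## Problem sizes used by the shipped suites

The acceptance computations regenerate 20,000 cued-attention trials per
monkey row and 15,000 free-response trials, fit with 8 starts; the
oscillation fixture uses 500 trials at 1 ms resolution with the full
dictionary.  Calibration suites use 200 replicates per test with the
reduced configuration, 100-200 trials per replicate, and scaled inner /
outer resampling counts (the outer count never below 39, the smallest
that can resolve a two-tailed p of 0.05).  These sizes were chosen so
the entire suite runs on one CPU in tens of minutes while leaving every
acceptance band at its stated value.

## Known limitations

* The Fokker-Planck solver covers constant drift within a trial - no
  collapsing bounds, no drift variability, matching the model it
  implements.
* MP screening uses the full-kernel Gram for atoms near the window
  edges, so edge-atom *selection* is approximate (the projection and
  energy bookkeeping remain exact); for signals whose features sit well
  inside the window this is immaterial.
* The Wigner-Ville map places each real atom's full energy at positive
  frequency; atoms with carriers near 0 Hz would be misplaced, but such
  atoms carry no band power in the analyses' 4 Hz-and-above bands.
* Absolute $\bar P$ values depend on the energy normalization
  convention; all shipped statistics are ratios, differences or ranks,
  which are invariant to it.
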