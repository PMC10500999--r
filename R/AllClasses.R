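# S4 containers for the central data objects.

#' Drift-diffusion model parameters
#'
#' Parameters of the bounded drift-diffusion choice model and its
#' misrouting extensions.  Evidence is accumulated as
#' \eqn{dV = \kappa (C + C_0)\,dt + dW} with a standard Wiener increment
#' \eqn{dW}, absorbed at \eqn{\pm B}.  On trials where the two motion
#' patches move in opposite directions, incomplete suppression of the
#' uncued patch replaces the drift gain \eqn{\kappa} by \eqn{\kappa_{opp}},
#' and on a fraction \eqn{\lambda} of those trials the decision is based on
#' the wrong patch, flipping the choice probabilities.  Free-response
#' variants add direction-specific non-decision time expectations.
#'
#' @slot kappa drift gain per unit signed coherence (model units).
#' @slot B bound height (model units); must be positive.
#' @slot C0 bias expressed as an offset in signed coherence.
#' @slot kappaOpp drift gain on opposite-direction trials (`NA` when unused).
#' @slot lambda wrong-patch fraction in \[0, 1\] (`NA` when unused).
#' @slot TndPos,TndNeg non-decision time expectations (s) for positive and
#'   negative choices (`NA` for controlled-duration tasks).
#' @export
setClass("DDMParams",
  representation(kappa = "numeric", B = "numeric", C0 = "numeric",
                 kappaOpp = "numeric", lambda = "numeric",
                 TndPos = "numeric", TndNeg = "numeric"),
  prototype(kappaOpp = NA_real_, lambda = NA_real_,
            TndPos = NA_real_, TndNeg = NA_real_))

setValidity("DDMParams", function(object) {
  msg <- character()
  if (length(object@B) != 1L || !is.finite(object@B) || object@B <= 0)
    msg <- c(msg, "B must be a positive scalar")
  if (length(object@kappa) != 1L || !is.finite(object@kappa))
    msg <- c(msg, "kappa must be a finite scalar")
  if (!is.na(object@lambda) && (object@lambda < 0 || object@lambda > 1))
    msg <- c(msg, "lambda must lie in [0, 1]")
  for (s in c("TndPos", "TndNeg")) {
    v <- slot(object, s)
    if (!is.na(v) && v < 0) msg <- c(msg, paste(s, "must be >= 0"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct drift-diffusion model parameters
#'
#' @param kappa drift gain per unit signed coherence.
#' @param B bound height (> 0).
#' @param C0 coherence bias offset.
#' @param kappaOpp drift gain on opposite-direction trials; `NA` if unused.
#' @param lambda wrong-patch fraction in \[0, 1\]; `NA` if unused.
#' @param TndPos,TndNeg non-decision time expectations in seconds (free
#'   response only); `NA` if unused.
#' @return a [DDMParams-class] object.
#' @examples
#' ddmParams(kappa = 7.9, B = 0.74, C0 = -0.047, kappaOpp = 4.6,
#'           lambda = 0.029)
#' @export
ddmParams <- function(kappa, B, C0 = 0, kappaOpp = NA_real_,
                      lambda = NA_real_, TndPos = NA_real_,
                      TndNeg = NA_real_) {
  new("DDMParams", kappa = as.numeric(kappa), B = as.numeric(B),
      C0 = as.numeric(C0), kappaOpp = as.numeric(kappaOpp),
      lambda = as.numeric(lambda), TndPos = as.numeric(TndPos),
      TndNeg = as.numeric(TndNeg))
}

#' Fokker-Planck solution of the bounded diffusion
#'
#' Numerical solution of the Fokker-Planck equation for one drift value:
#' absorption-time densities at the two bounds, their running integrals,
#' and the unabsorbed density over evidence values at the final time.
#' The three components sum to one.
#'
#' @slot t time grid (s).
#' @slot v evidence grid in (-B, B).
#' @slot fPlus,fMinus absorption-time densities at the upper/lower bound.
#' @slot FPlus,FMinus cumulative absorbed probability by each time.
#' @slot survPos probability mass in (0, B) at each time.
#' @slot survTot probability mass in (-B, B) at each time.
#' @slot fUn unabsorbed density over `v` at the final time.
#' @slot drift,B,h drift rate, bound height and evidence grid step.
#' @export
setClass("FPSolution",
  representation(t = "numeric", v = "numeric", fPlus = "numeric",
                 fMinus = "numeric", FPlus = "numeric", FMinus = "numeric",
                 survPos = "numeric", survTot = "numeric", fUn = "numeric",
                 drift = "numeric", B = "numeric", h = "numeric"))

setValidity("FPSolution", function(object) {
  msg <- character()
  if (any(object@fPlus < 0) || any(object@fMinus < 0) || any(object@fUn < 0))
    msg <- c(msg, "densities must be non-negative")
  if (length(object@t) != length(object@fPlus))
    msg <- c(msg, "time grid and densities must have equal length")
  if (length(msg)) msg else TRUE
})

#' Spike-train ensemble
#'
#' Per-trial spike times relative to an alignment event, with the common
#' recording window.
#'
#' @slot spikes list of numeric vectors of spike times (s), strictly
#'   increasing within each trial and contained in `window`.
#' @slot trialId integer trial identifiers, parallel to `spikes`.
#' @slot window length-2 numeric, the recorded window (s) around the event.
#' @slot alignEvent name of the alignment event.
#' @export
setClass("SpikeEnsemble",
  representation(spikes = "list", trialId = "integer", window = "numeric",
                 alignEvent = "character"))

setValidity("SpikeEnsemble", function(object) {
  msg <- character()
  if (length(object@spikes) != length(object@trialId))
    msg <- c(msg, "spikes and trialId must have equal length")
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "window must be an increasing length-2 numeric")
  bad <- vapply(object@spikes, function(s) {
    length(s) > 0 && (is.unsorted(s, strictly = TRUE) ||
                      s[1] < object@window[1] ||
                      s[length(s)] > object@window[2])
  }, logical(1))
  if (any(bad))
    msg <- c(msg, "spike times must be strictly increasing and inside window")
  if (length(msg)) msg else TRUE
})

#' Construct a spike-train ensemble
#'
#' @param spikes list of per-trial spike-time vectors (s).
#' @param trialId integer trial ids (defaults to sequence).
#' @param window recorded window (s) around the alignment event.
#' @param alignEvent alignment event name.
#' @return a [SpikeEnsemble-class] object.
#' @export
spikeEnsemble <- function(spikes, trialId = seq_along(spikes),
                          window, alignEvent = "event") {
  new("SpikeEnsemble", spikes = lapply(spikes, as.numeric),
      trialId = as.integer(trialId), window = as.numeric(window),
      alignEvent = alignEvent)
}

#' Local field potential ensemble
#'
#' Regularly sampled voltage traces, one column per trial, on a common time
#' base aligned to an event at t = 0.
#'
#' @slot data numeric matrix, samples x trials.
#' @slot times sample times (s).
#' @slot samplingRate sampling rate (Hz), at least 500 so the beta band is
#'   well below Nyquist.
#' @slot alignEvent alignment event name.
#' @export
setClass("LfpEnsemble",
  representation(data = "matrix", times = "numeric",
                 samplingRate = "numeric", alignEvent = "character"))

setValidity("LfpEnsemble", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@times))
    msg <- c(msg, "times must match the number of samples")
  if (object@samplingRate < 500)
    msg <- c(msg, "samplingRate must be >= 500 Hz")
  if (length(msg)) msg else TRUE
})

#' Matching-Pursuit decomposition
#'
#' Ordered Gabor atoms extracted greedily from a signal, with the residual
#' and energy bookkeeping.  Each atom contributes
#' \eqn{A\, e^{-\pi (t-\tau)^2/\sigma^2} \cos(\xi (t-\tau) + \phi)} with
#' center `tau` (s), width `sigma` (s), carrier `freq` (Hz,
#' \eqn{\xi/2\pi}), envelope amplitude `amplitude` (signal units) and
#' `phase` (rad).  `energy` is the squared-norm energy the atom removed
#' from the residual, in continuous-time units (signal units squared times
#' seconds).
#'
#' @slot atoms data.frame with columns tau, sigma, freq, amplitude, phase,
#'   energy, order; rows sorted by decreasing energy.
#' @slot residual residual signal after all atoms.
#' @slot signal the analysed (mean-subtracted) signal.
#' @slot signalEnergy total signal energy (continuous-time units).
#' @slot dt sample interval (s).
#' @slot t0 time of the first sample (s).
#' @export
setClass("MPDecomposition",
  representation(atoms = "data.frame", residual = "numeric",
                 signal = "numeric", signalEnergy = "numeric",
                 dt = "numeric", t0 = "numeric"))

setValidity("MPDecomposition", function(object) {
  msg <- character()
  need <- c("tau", "sigma", "freq", "amplitude", "phase", "energy", "order")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, "atoms must have tau/sigma/freq/amplitude/phase/energy/order")
  if (nrow(object@atoms) > 1 && is.unsorted(rev(object@atoms$energy)))
    msg <- c(msg, "atoms must be sorted by decreasing energy")
  if (length(msg)) msg else TRUE
})

#' Fitted drift-diffusion model
#'
#' @slot params fitted [DDMParams-class].
#' @slot variant model variant ("base", "lambda_only", "kopp_only", "full",
#'   or "fr" for the free-response likelihood).
#' @slot logLik maximized log-likelihood.
#' @slot nTrials number of trials.
#' @slot nParams fitted degrees of freedom.
#' @slot bic Bayesian information criterion,
#'   `nParams * log(nTrials) - 2 * logLik`.
#' @slot convergence list with per-start results, winner index and seed.
#' @export
setClass("DDMFit",
  representation(params = "DDMParams", variant = "character",
                 logLik = "numeric", nTrials = "integer",
                 nParams = "integer", bic = "numeric",
                 convergence = "list"))

setValidity("DDMFit", function(object) {
  expect <- object@nParams * log(object@nTrials) - 2 * object@logLik
  if (abs(object@bic - expect) > 1e-6 * max(1, abs(expect)))
    "bic inconsistent with nParams * log(n) - 2 * logLik" else TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "DDMParams", function(object) {
  cat("DDMParams: kappa =", format(object@kappa, digits = 4),
      " B =", format(object@B, digits = 4),
      " C0 =", format(object@C0, digits = 4), "\n")
  if (!is.na(object@kappaOpp) || !is.na(object@lambda))
    cat("  misrouting: kappaOpp =", format(object@kappaOpp, digits = 4),
        " lambda =", format(object@lambda, digits = 4), "\n")
  if (!is.na(object@TndPos))
    cat("  non-decision times:", format(object@TndPos, digits = 3), "/",
        format(object@TndNeg, digits = 3), "s (pos/neg)\n")
})

setMethod("show", "FPSolution", function(object) {
  n <- length(object@t)
  cat("FPSolution: drift =", format(object@drift, digits = 4),
      " B =", format(object@B, digits = 4), "\n",
      " t in [0,", format(object@t[n], digits = 4), "] s,",
      length(object@v), "evidence nodes\n",
      " P(absorbed +):", format(object@FPlus[n], digits = 4),
      " P(absorbed -):", format(object@FMinus[n], digits = 4),
      " P(unabsorbed):", format(object@survTot[n], digits = 4), "\n")
})

setMethod("show", "SpikeEnsemble", function(object) {
  cat("SpikeEnsemble:", length(object@spikes), "trials aligned to",
      object@alignEvent, "\n  window [", object@window[1], ",",
      object@window[2], ") s; mean spikes/trial:",
      format(mean(lengths(object@spikes)), digits = 4), "\n")
})

setMethod("show", "LfpEnsemble", function(object) {
  cat("LfpEnsemble:", ncol(object@data), "trials x", nrow(object@data),
      "samples at", object@samplingRate, "Hz, aligned to",
      object@alignEvent, "\n")
})

setMethod("show", "MPDecomposition", function(object) {
  cat("MPDecomposition:", nrow(object@atoms), "atoms;",
      "captured", format(100 * (1 - residualEnergy(object) /
                                  object@signalEnergy), digits = 4),
      "% of signal energy\n")
  if (nrow(object@atoms) > 0)
    print(utils::head(object@atoms[, c("tau", "sigma", "freq", "amplitude",
                                       "energy")], 5), digits = 4)
})

setMethod("show", "DDMFit", function(object) {
  cat("DDMFit (", object@variant, "): logLik =",
      format(object@logLik, digits = 8), " BIC =",
      format(object@bic, digits = 8), " n =", object@nTrials, "\n")
  show(object@params)
})

# ---- accessors ------------------------------------------------------------

#' Accessors for lipbeta S4 containers
#'
#' `atoms()` returns the atom table of a decomposition, `residualEnergy()`
#' the residual energy, `spikeTimes()` the per-trial spike list,
#' `trialWindow()` the recorded window, `lfpMatrix()` the samples-by-trials
#' voltage matrix, `sampleTimes()` the LFP time base, `fittedParams()` the
#' parameters of a fit, and `bic()` its information criterion.
#'
#' @param x an object of the documented class.
#' @return see individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
atoms <- function(x) { stopifnot(is(x, "MPDecomposition")); x@atoms }

#' @rdname accessors
#' @export
residualEnergy <- function(x) {
  stopifnot(is(x, "MPDecomposition"))
  sum(x@residual^2) * x@dt
}

#' @rdname accessors
#' @export
spikeTimes <- function(x) { stopifnot(is(x, "SpikeEnsemble")); x@spikes }

#' @rdname accessors
#' @export
trialWindow <- function(x) { stopifnot(is(x, "SpikeEnsemble")); x@window }

#' @rdname accessors
#' @export
lfpMatrix <- function(x) { stopifnot(is(x, "LfpEnsemble")); x@data }

#' @rdname accessors
#' @export
sampleTimes <- function(x) { stopifnot(is(x, "LfpEnsemble")); x@times }

#' @rdname accessors
#' @export
fittedParams <- function(x) { stopifnot(is(x, "DDMFit")); x@params }

#' @rdname accessors
#' @export
bic <- function(x) { stopifnot(is(x, "DDMFit")); x@bic }
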