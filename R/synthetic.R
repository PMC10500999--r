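# Synthetic-data generators: behavioural trials, Poisson spike trains and
# LFP traces with the statistical structure the downstream analyses assume.

#' Truncated-exponential duration distribution
#'
#' Delay and viewing durations are drawn from an exponential density with
#' time constant `tau`, truncated to `[tMin, tMax]` and renormalized.
#' Because of the truncation the expectation is less than `tMin + tau`.
#'
#' @param tMin,tMax truncation bounds (s), `tMin <= tMax`.
#' @param tau exponential time constant (s), positive.
#' @return a validated list of class `"durationDist"`.
#' @export
durationDist <- function(tMin, tMax, tau) {
  if (!is.finite(tMin) || !is.finite(tMax) || tMin > tMax)
    stop("invalid truncation bounds: need tMin <= tMax")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  structure(list(tMin = tMin, tMax = tMax, tau = tau),
            class = "durationDist")
}

#' Sample truncated-exponential durations
#'
#' Inverse-CDF sampling from [durationDist()].
#'
#' @param dist a [durationDist()].
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return numeric vector of durations in `[tMin, tMax]`.
#' @examples
#' d <- sampleTruncExp(durationDist(0.2, 0.6, 0.1), 1e4, seed = 1)
#' mean(d) < 0.3   # truncation pulls the mean below tMin + tau
#' @export
sampleTruncExp <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "durationDist"), n >= 1)
  withSeed(seed, {
    if (dist$tMax == dist$tMin) return(rep(dist$tMin, n))
    u <- runif(n)
    z <- 1 - exp(-(dist$tMax - dist$tMin) / dist$tau)
    dist$tMin - dist$tau * log(1 - u * z)
  })
}

#' Behavioural trial design
#'
#' Task structure for the three variants: the cued-attention task (two
#' matched-strength motion patches, one cued; uncued direction equal to the
#' cued one on `pSame` of trials), the controlled-duration variable-location
#' task (single patch) and its free-response version.
#'
#' @param task one of `"cued_attention"`, `"variable_location"`,
#'   `"variable_location_FR"`.
#' @param coherenceSet unsigned coherence magnitudes drawn with equal
#'   probability (sign assigned uniformly).
#' @param pSame fraction of cued-task trials on which the uncued patch
#'   moves in the same direction as the cued patch.
#' @param durations [durationDist()] for the viewing duration
#'   (ignored for the free-response task).
#' @return list of class `"trialDesign"`.
#' @export
trialDesign <- function(task = c("cued_attention", "variable_location",
                                 "variable_location_FR"),
                        coherenceSet = NULL, pSame = 1 / 3,
                        durations = NULL) {
  task <- match.arg(task)
  if (is.null(coherenceSet))
    coherenceSet <- if (task == "variable_location_FR")
      c(0, 0.032, 0.064, 0.128, 0.256)
    else c(0, 0.032, 0.064, 0.128, 0.256, 0.512)
  if (is.null(durations))
    durations <- if (task == "cued_attention")
      durationDist(0.1, 1.5, 0.35) else durationDist(0.1, 1.0, 0.25)
  structure(list(task = task, coherenceSet = sort(unique(coherenceSet)),
                 pSame = pSame, durations = durations),
            class = "trialDesign")
}

#' Sample per-trial task conditions
#'
#' Draws signed coherence (magnitude uniform over the design set, sign
#' uniform), cue location (upper/lower, equiprobable), the same/opposite
#' relation of the uncued patch (cued task only) and the viewing duration.
#'
#' @param design a [trialDesign()].
#' @param n number of trials.
#' @param seed optional integer seed.
#' @return data.frame with columns trial_id, task, coherence, cue_location,
#'   relation, t_dur_s.
#' @export
sampleTrialConditions <- function(design, n, seed = NULL) {
  stopifnot(inherits(design, "trialDesign"), n >= 1)
  withSeed(seed, {
    mag <- sample(design$coherenceSet, n, replace = TRUE)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    coh <- mag * sgn
    cue <- sample(c("upper", "lower"), n, replace = TRUE)
    relation <- if (design$task == "cued_attention")
      ifelse(runif(n) < design$pSame, "same", "opposite")
    else rep("single", n)
    tdur <- if (design$task == "variable_location_FR") rep(NA_real_, n)
    else sampleTruncExp(design$durations, n)
    data.frame(trial_id = seq_len(n), task = design$task, coherence = coh,
               cue_location = cue, relation = relation, t_dur_s = tdur,
               stringsAsFactors = FALSE)
  })
}

#' Simulate choices (and response times) from the misrouting diffusion model
#'
#' Euler-Maruyama path simulation of the bounded accumulator.  The drift on
#' each trial is `kappa * (C + C0)` (same-direction and single-patch
#' trials) or `kappaOpp * (C + C0)` (opposite-direction trials).
#' Controlled-duration trials are decided at the bound or, if unabsorbed at
#' the end of viewing, by the sign of the integrated evidence.  On a
#' `lambda` fraction of opposite-direction trials the decision is routed
#' from the wrong patch, which flips the realized choice — the generative
#' equivalent of the wrong-patch mixture of choice probabilities.
#' Free-response trials run to absorption; the response time adds the
#' direction-specific non-decision time.  Zero-coherence trials are
#' rewarded with probability one half regardless of choice.
#'
#' @param design a [trialDesign()].
#' @param params a [DDMParams-class] object (ground truth).
#' @param n number of trials.
#' @param seed optional integer seed.
#' @param dt Euler step (s), at most 1 ms.
#' @return a trial table: the conditions of [sampleTrialConditions()] plus
#'   columns rt_s, choice (+1/-1), correct, rewarded.
#' @export
simulateChoices <- function(design, params, n, seed = NULL, dt = 1e-4) {
  stopifnot(inherits(design, "trialDesign"), is(params, "DDMParams"), n >= 1)
  validObject(params)
  if (dt > 1e-3 + 1e-12) stop("Euler step dt must be <= 1 ms")
  fr <- design$task == "variable_location_FR"
  if (fr && (is.na(params@TndPos) || is.na(params@TndNeg)))
    stop("free-response simulation needs TndPos and TndNeg")
  withSeed(seed, {
    cond <- sampleTrialConditions(design, n)
    gain <- ifelse(cond$relation == "opposite",
                   ifelse(is.na(params@kappaOpp), params@kappa,
                          params@kappaOpp), params@kappa)
    drift <- gain * (cond$coherence + params@C0)
    sim <- sim_ddm_paths(drift, if (fr) numeric(0) else cond$t_dur_s,
                         params@B, dt, fr, 10)
    choice <- sim$choice
    # wrong-patch misrouting: flip the realized choice on a lambda fraction
    # of opposite-direction trials
    if (!is.na(params@lambda) && params@lambda > 0) {
      flip <- cond$relation == "opposite" & runif(n) < params@lambda
      choice[flip] <- -choice[flip]
    }
    rt <- if (fr)
      sim$decTime + ifelse(choice > 0, params@TndPos, params@TndNeg)
    else rep(NA_real_, n)
    correct <- ifelse(cond$coherence == 0, NA,
                      sign(cond$coherence) == choice)
    rewarded <- ifelse(cond$coherence == 0, runif(n) < 0.5, correct)
    cbind(cond, data.frame(rt_s = rt, choice = choice, correct = correct,
                           rewarded = rewarded))
  })
}

#' Transient Gabor oscillation parameters
#'
#' A Gaussian-windowed cosine
#' \eqn{A e^{-\pi (t-\tau)^2/\sigma^2} \cos(2\pi f (t-\tau) + \phi)} used
#' both as an additive component of firing rates (units spikes/s) and as
#' the deterministic LFP transient.
#'
#' @param tau envelope center (s, relative to the alignment event).
#' @param sigma envelope width (s), positive.
#' @param freqHz carrier frequency (Hz), non-negative.
#' @param amplitude envelope peak amplitude (signal units).
#' @param phase carrier phase at the center (rad).
#' @return list of class `"gaborAtom"`.
#' @export
gaborAtom <- function(tau, sigma, freqHz, amplitude = 1, phase = 0) {
  if (sigma <= 0) stop("sigma must be positive")
  if (freqHz < 0) stop("freqHz must be non-negative")
  structure(list(tau = tau, sigma = sigma, freqHz = freqHz,
                 amplitude = amplitude, phase = phase),
            class = "gaborAtom")
}

#' Evaluate a Gabor transient
#'
#' @param atom a [gaborAtom()] (or a row of an [MPDecomposition-class]
#'   atom table).
#' @param t times (s).
#' @param shift additional shift of the envelope center (s), used for
#'   per-trial temporal jitter.
#' @return numeric vector of the transient at `t`.
#' @export
evalGabor <- function(atom, t, shift = 0) {
  s <- t - (atom$tau + shift)
  atom$amplitude * exp(-pi * s^2 / atom$sigma^2) *
    cos(2 * pi * atom$freqHz * s + atom$phase)
}

#' Firing-rate specification for spike-train simulation
#'
#' The instantaneous rate of each trial is
#' `baseline + rampGain * C * max(0, t - rampOnset) + transient`, rectified
#' at zero.  The transient's center can be jittered per trial by a normal
#' shift with standard deviation `jitterSD`, emulating oscillations that
#' are time-locked only approximately to the event.
#'
#' @param baseline baseline rate (spikes/s), non-negative.
#' @param transient a [gaborAtom()] with amplitude in spikes/s, or NULL.
#' @param rampGain coherence-dependent ramp slope
#'   (spikes/s per unit signed coherence per s).
#' @param rampOnset ramp onset latency (s).
#' @param jitterSD SD of the per-trial transient center jitter (s), >= 0.
#' @return list of class `"rateSpec"`.
#' @export
rateSpec <- function(baseline, transient = NULL, rampGain = 0,
                     rampOnset = 0.2, jitterSD = 0) {
  if (baseline < 0) stop("baseline rate must be non-negative")
  if (jitterSD < 0) stop("jitterSD must be non-negative")
  if (!is.null(transient)) stopifnot(inherits(transient, "gaborAtom"))
  structure(list(baseline = baseline, transient = transient,
                 rampGain = rampGain, rampOnset = rampOnset,
                 jitterSD = jitterSD), class = "rateSpec")
}

#' Canonical strong-transient fixture
#'
#' Rate specification mirroring a vividly oscillating example neuron: a
#' 20 spikes/s baseline carrying a 16.7 Hz Gabor transient (center 85 ms,
#' envelope width 80 ms, peak 25 spikes/s) that erupts in the epoch just
#' after the event — three to four raster-visible cycles, peaks at two to
#' three times the baseline rate, the vivid end of what the recordings
#' show.
#'
#' @param amplitude transient peak amplitude (spikes/s).
#' @param jitterSD per-trial center jitter SD (s).
#' @return a [rateSpec()].
#' @export
dm49RateSpec <- function(amplitude = 25, jitterSD = 0) {
  rateSpec(baseline = 20,
           transient = gaborAtom(tau = 0.085, sigma = 0.08,
                                 freqHz = 16.7, amplitude = amplitude),
           rampGain = 0, jitterSD = jitterSD)
}

# instantaneous rate for one trial (rectified at zero)
trialRate <- function(spec, t, coherence = 0, shift = 0) {
  r <- rep(spec$baseline, length(t))
  if (spec$rampGain != 0)
    r <- r + spec$rampGain * coherence * pmax(0, t - spec$rampOnset)
  if (!is.null(spec$transient))
    r <- r + evalGabor(spec$transient, t, shift)
  pmax(r, 0)
}

#' Simulate inhomogeneous-Poisson spike trains
#'
#' Exact simulation by thinning: candidate events from a homogeneous
#' Poisson process at the per-trial rate ceiling are retained with
#' probability rate(t)/ceiling, so counts in any window are Poisson with
#' mean equal to the integrated rate and no binning artifacts are
#' introduced.
#'
#' @param spec a [rateSpec()].
#' @param trials trial table (only the coherence column is used; a plain
#'   count is also accepted).
#' @param window recording window (s) around the event.
#' @param seed optional integer seed.
#' @param alignEvent event name recorded in the ensemble.
#' @return a [SpikeEnsemble-class] object.
#' @export
simulateSpikeTrains <- function(spec, trials, window = c(-0.3, 0.724),
                                seed = NULL, alignEvent = "cue_onset") {
  stopifnot(inherits(spec, "rateSpec"))
  if (is.numeric(trials) && length(trials) == 1L)
    trials <- data.frame(trial_id = seq_len(trials), coherence = 0)
  n <- nrow(trials)
  coh <- if ("coherence" %in% names(trials)) trials$coherence else rep(0, n)
  withSeed(seed, {
    shifts <- if (spec$jitterSD > 0) rnorm(n, 0, spec$jitterSD) else
      rep(0, n)
    T <- diff(window)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      rmax <- spec$baseline +
        (if (!is.null(spec$transient)) abs(spec$transient$amplitude) else 0) +
        abs(spec$rampGain * coh[i]) * max(0, window[2] - spec$rampOnset)
      if (rmax <= 0) { out[[i]] <- numeric(0); next }
      m <- rpois(1, rmax * T)
      if (m == 0) { out[[i]] <- numeric(0); next }
      cand <- sort(runif(m, window[1], window[2]))
      keep <- runif(m) < trialRate(spec, cand, coh[i], shifts[i]) / rmax
      # the RNG's finite granularity can produce exact ties; two spikes
      # cannot be simultaneous, so drop duplicates
      out[[i]] <- unique(cand[keep])
    }
    spikeEnsemble(out, trialId = seq_len(n), window = window,
                  alignEvent = alignEvent)
  })
}

#' Simulate LFP traces with a Gabor transient and 1/f noise
#'
#' Each trial is the deterministic transient plus pink noise synthesized by
#' spectral shaping of white noise with a 1/f amplitude profile (high-pass
#' at 1 Hz).  If a spike ensemble is supplied with `coupling > 0`, spikes
#' inside the transient's support are re-timed by thinning against the
#' carrier so spike density peaks at the carrier trough (phase pi); the
#' modulation depth grows with `coupling` (1 = density proportional to
#' `1 - cos`).
#'
#' @param nTrials number of trials.
#' @param transient a [gaborAtom()] (LFP units).
#' @param noiseAmp pink-noise RMS amplitude (LFP units; 0 for noiseless).
#' @param window time window (s) around the event.
#' @param samplingRate sampling rate (Hz), >= 500.
#' @param coupling spike-LFP coupling strength in \[0, 1\].
#' @param spikes optional [SpikeEnsemble-class] to couple.
#' @param seed optional integer seed.
#' @param alignEvent event name.
#' @return list with elements `lfp` ([LfpEnsemble-class]) and `spikes`
#'   (re-timed [SpikeEnsemble-class], or NULL if none supplied).
#' @export
simulateLfp <- function(nTrials, transient, noiseAmp = 0.5,
                        window = c(-0.3, 0.724), samplingRate = 1000,
                        coupling = 0, spikes = NULL, seed = NULL,
                        alignEvent = "cue_onset") {
  stopifnot(inherits(transient, "gaborAtom"))
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  if (samplingRate < 500) stop("samplingRate must be >= 500 Hz")
  withSeed(seed, {
    dt <- 1 / samplingRate
    tt <- seq(window[1], window[2] - dt / 2, by = dt)
    ns <- length(tt)
    base <- evalGabor(transient, tt)
    dat <- matrix(0, ns, nTrials)
    for (i in seq_len(nTrials)) {
      dat[, i] <- base +
        if (noiseAmp > 0) pinkNoise(ns, dt, noiseAmp) else 0
    }
    lfp <- new("LfpEnsemble", data = dat, times = tt,
               samplingRate = samplingRate, alignEvent = alignEvent)
    newSpikes <- NULL
    if (!is.null(spikes)) {
      stopifnot(is(spikes, "SpikeEnsemble"))
      newSpikes <- if (coupling > 0)
        coupleSpikes(spikes, transient, coupling) else spikes
    }
    list(lfp = lfp, spikes = newSpikes)
  })
}

# 1/f-amplitude noise via spectral shaping, high-passed at 1 Hz,
# standardized to RMS `amp`
pinkNoise <- function(n, dt, amp) {
  f <- seq(0, 1 / (2 * dt), length.out = floor(n / 2) + 1)
  shape <- c(0, 1 / pmax(f[-1], 1))
  nf <- length(f)
  re <- rnorm(nf) * shape
  im <- rnorm(nf) * shape
  im[1] <- 0
  if (n %% 2 == 0) im[nf] <- 0
  spec <- complex(real = re, imaginary = im)
  full <- c(spec, Conj(rev(spec[2:(nf - 1 + n %% 2)])))
  x <- Re(fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x * amp / s else x
}

# re-time spikes within the transient support so spike density is maximal
# at carrier phase pi (the trough); thinning with acceptance
# (1 - c*cos(theta)) / (1 + c)
coupleSpikes <- function(spikes, transient, coupling) {
  half <- 2.5 * transient$sigma
  lo <- max(transient$tau - half, spikes@window[1])
  hi <- min(transient$tau + half, spikes@window[2])
  if (lo >= hi) return(spikes)
  resample <- function(s) {
    inside <- s >= lo & s <= hi
    n <- sum(inside)
    if (n == 0) return(s)
    kept <- numeric(0)
    while (length(kept) < n) {
      cand <- runif(2 * n + 8, lo, hi)
      theta <- 2 * pi * transient$freqHz * (cand - transient$tau) +
        transient$phase
      acc <- (1 - coupling * cos(theta)) / (1 + coupling)
      kept <- c(kept, cand[runif(length(cand)) < acc])
    }
    unique(sort(c(s[!inside], kept[seq_len(n)])))
  }
  spikeEnsemble(lapply(spikes@spikes, resample), trialId = spikes@trialId,
                window = spikes@window, alignEvent = spikes@alignEvent)
}

#' Simulate a cohort of units for the preferred-ratio error analysis
#'
#' Each unit oscillates more strongly when one cued location (its
#' preferred one, drawn at random) is cued: the transient amplitude is
#' `ampPref` at the preferred location and `ampPref / ampRatio` at the
#' other.  Trials are balanced across the two cued locations and labelled
#' correct or error at rate `errRate`.  Under `errorMode = "misrouting"`
#' the oscillation on error trials is generated with the OTHER location's
#' amplitude (routing from the wrong patch); under `"perceptual"` the
#' amplitude depends only on the cued location, so outcome carries no
#' information about the oscillation.
#'
#' @param nUnits number of units.
#' @param trialsPerLoc trials per cued location per unit.
#' @param errorMode `"misrouting"` or `"perceptual"`.
#' @param errRate error-trial fraction.
#' @param ampPref preferred-location transient amplitude (spikes/s).
#' @param ampRatio preferred/nonpreferred amplitude ratio (> 1).
#' @param baseline baseline rate (spikes/s).
#' @param window recording window (s).
#' @param seed integer seed.
#' @return list of unit records usable by [preferredRatioAnalysis()]:
#'   each has `spikes`, `location`, `correct`, and the generating
#'   `preferred` label.
#' @export
simulateUnitCohort <- function(nUnits = 24, trialsPerLoc = 80,
                               errorMode = c("misrouting", "perceptual"),
                               errRate = 0.25, ampPref = 30, ampRatio = 3,
                               baseline = 10, window = c(-0.096, 0.160),
                               seed = 1) {
  errorMode <- match.arg(errorMode)
  stopifnot(ampRatio > 1, errRate > 0, errRate < 1)
  withSeed(seed, {
    units <- vector("list", nUnits)
    for (u in seq_len(nUnits)) {
      pref <- sample(c("upper", "lower"), 1)
      loc <- rep(c("upper", "lower"), each = trialsPerLoc)
      n <- length(loc)
      correct <- runif(n) >= errRate
      ampAt <- function(L) ifelse(L == pref, ampPref, ampPref / ampRatio)
      srcLoc <- loc
      if (errorMode == "misrouting") {
        other <- ifelse(loc == "upper", "lower", "upper")
        srcLoc[!correct] <- other[!correct]
      }
      amp <- ampAt(srcLoc)
      spk <- vector("list", n)
      for (a in unique(amp)) {
        idx <- which(amp == a)
        spec <- rateSpec(baseline,
                         gaborAtom(0.085, 0.05, 16.7, amplitude = a))
        spk[idx] <- simulateSpikeTrains(spec, length(idx),
                                        window = window)@spikes
      }
      units[[u]] <- list(spikes = spikeEnsemble(spk, window = window),
                         location = loc, correct = correct,
                         preferred = pref)
    }
    units
  })
}

#' Reference parameter sets for the recorded monkeys
#'
#' Published maximum-likelihood fits of the diffusion model used as ground
#' truth by the synthetic generators: cued-attention fits with misrouting
#' parameters for Monkeys Dm and Np, controlled-duration variable-location
#' fits for Dm and Ap, and the free-response fit (with direction-specific
#' non-decision times) for Dz.
#'
#' @param which one of `"Dm_cued"`, `"Np_cued"`, `"Dm_var"`, `"Ap_var"`,
#'   `"Dz_fr"`.
#' @return a [DDMParams-class] object.
#' @export
referenceParams <- function(which = c("Dm_cued", "Np_cued", "Dm_var",
                                      "Ap_var", "Dz_fr")) {
  switch(match.arg(which),
    Dm_cued = ddmParams(7.9, 0.74, -0.047, kappaOpp = 4.6, lambda = 0.029),
    Np_cued = ddmParams(17.9, 0.44, -0.011, kappaOpp = 7.9, lambda = 0.006),
    Dm_var = ddmParams(10.3, 0.64, 0.013),
    Ap_var = ddmParams(11.4, 0.61, -0.001),
    Dz_fr = ddmParams(17.1, 0.74, -0.02, TndPos = 0.33, TndNeg = 0.34))
}
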