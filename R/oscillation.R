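# PSTH construction and Matching-Pursuit quantification of transient
# oscillations: Gabor decomposition, Wigner-Ville power and the band/epoch
# power statistic.

#' Peristimulus time histogram
#'
#' Trial-averaged firing rate in uniform bins aligned to the ensemble's
#' event: rate = spike count per bin / (number of trials x bin width).
#' By convention 1 ms bins feed the Matching-Pursuit analysis, 5 ms bins
#' population averages and 10 ms bins single-neuron displays.
#'
#' @param spikes a [SpikeEnsemble-class] object (or plain list of
#'   spike-time vectors with `window` supplied).
#' @param binWidth bin width (s).
#' @param window analysis window (s); defaults to the ensemble window.
#' @return list of class `"rateSeries"` with bin centers `t` (s), `rate`
#'   (spikes/s), `binWidth` and `nTrials`.
#' @export
buildPsth <- function(spikes, binWidth = 0.001, window = NULL) {
  if (is(spikes, "SpikeEnsemble")) {
    if (is.null(window)) window <- spikes@window
    lst <- spikes@spikes
  } else {
    stopifnot(is.list(spikes), !is.null(window))
    lst <- spikes
  }
  n <- length(lst)
  if (n == 0) stop("empty spike ensemble")
  nb <- floor((window[2] - window[1]) / binWidth + 1e-9)
  if (nb < 1) stop("window shorter than one bin")
  edges <- window[1] + (0:nb) * binWidth
  all <- unlist(lst, use.names = FALSE)
  all <- all[all >= edges[1] & all < edges[nb + 1]]
  counts <- tabulate(pmin(floor((all - window[1]) / binWidth) + 1L, nb),
                     nbins = nb)
  structure(list(t = edges[-1] - binWidth / 2,
                 rate = counts / (n * binWidth),
                 binWidth = binWidth, nTrials = n),
            class = "rateSeries")
}

#' Population-average PSTH weighted by trial counts
#'
#' Averages rate series across neurons with each neuron weighted by its
#' number of recorded trials.
#'
#' @param rates list of `"rateSeries"` on a common grid.
#' @return a `"rateSeries"` whose `nTrials` is the summed weight.
#' @export
populationPsth <- function(rates) {
  stopifnot(length(rates) >= 1,
            all(vapply(rates, inherits, logical(1), "rateSeries")))
  w <- vapply(rates, `[[`, numeric(1), "nTrials")
  mat <- vapply(rates, `[[`, numeric(length(rates[[1]]$rate)), "rate")
  structure(list(t = rates[[1]]$t,
                 rate = as.numeric(mat %*% w) / sum(w),
                 binWidth = rates[[1]]$binWidth, nTrials = sum(w)),
            class = "rateSeries")
}

#' Noncausal boxcar smoothing of a rate series
#'
#' Centered moving average (window rounded to an odd number of bins) with
#' truncated-window normalization at the edges.  Display convention only;
#' never applied before Matching Pursuit, which requires the raw rates.
#'
#' @param rate a `"rateSeries"`.
#' @param width filter width (s), a multiple of the bin width.
#' @return smoothed `"rateSeries"`.
#' @export
boxcarSmooth <- function(rate, width = 0.100) {
  stopifnot(inherits(rate, "rateSeries"))
  nb <- width / rate$binWidth
  if (abs(nb - round(nb)) > 1e-6 || round(nb) < 1)
    stop("width must be a positive multiple of the bin width")
  h <- floor(round(nb) / 2)
  x <- rate$rate
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  out <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  structure(list(t = rate$t, rate = out, binWidth = rate$binWidth,
                 nTrials = rate$nTrials), class = "rateSeries")
}

#' Detrend responses by the low-coherence average
#'
#' Subtracts, per neuron, the mean rate trace over the lowest coherences
#' (0 and +/-3.2 percent by default) from every condition's trace, so that
#' decision-related ramping is shown relative to the weak-evidence
#' baseline.  For neurons preferring the ipsilateral direction the sign of
#' the coherence labels is reversed before grouping.
#'
#' @param rates list of `"rateSeries"`, one per signed coherence.
#' @param coherences signed coherence of each element of `rates`.
#' @param flipForIpsilateral reverse the sign of the motion labels.
#' @param lowMax magnitude threshold defining the low-coherence set.
#' @return list with `rates` (detrended series) and `coherence` (possibly
#'   sign-flipped labels).
#' @export
detrendLowCoherence <- function(rates, coherences,
                                flipForIpsilateral = FALSE,
                                lowMax = 0.032) {
  stopifnot(length(rates) == length(coherences))
  low <- abs(coherences) <= lowMax + 1e-12
  if (!any(abs(coherences) < 1e-12) || sum(low) < 2)
    stop("low-coherence conditions (0 and weakest) must be present")
  mat <- vapply(rates, `[[`, numeric(length(rates[[1]]$rate)), "rate")
  ref <- rowMeans(mat[, low, drop = FALSE])
  out <- lapply(rates, function(r) {
    r$rate <- r$rate - ref
    r
  })
  list(rates = out,
       coherence = if (flipForIpsilateral) -coherences else coherences)
}

#' Gabor dictionary specification for Matching Pursuit
#'
#' Centers at every sample; envelope widths on a dyadic ladder from two
#' samples up to the signal length (the extremes standing in for the
#' impulse and windowed-sinusoid limits); carrier frequencies gridded at
#' `freqStepHz` up to `maxFreqHz`.
#'
#' @param n signal length in samples.
#' @param dt sample interval (s).
#' @param maxFreqHz top carrier frequency (Hz); must be below Nyquist.
#' @param freqStepHz carrier frequency step (Hz).
#' @param sigmaSamp optional explicit envelope widths in samples.
#' @return list of class `"mpDictionary"`.
#' @export
mpDictionary <- function(n, dt, maxFreqHz = 50, freqStepHz = 0.5,
                         sigmaSamp = NULL) {
  if (maxFreqHz >= 0.5 / dt)
    stop("maxFreqHz must be below the Nyquist frequency")
  if (is.null(sigmaSamp)) {
    sigmaSamp <- 2^(1:floor(log2(n)))
    if (sigmaSamp[length(sigmaSamp)] < n) sigmaSamp <- c(sigmaSamp, n)
  }
  structure(list(sigmaSamp = sigmaSamp,
                 freqHz = seq(0, maxFreqHz, by = freqStepHz), dt = dt),
            class = "mpDictionary")
}

#' Matching-Pursuit decomposition into Gabor atoms
#'
#' Greedy decomposition: at each iteration the dictionary atom with the
#' largest magnitude projection onto the residual is selected and its
#' exact real-amplitude/phase projection subtracted, so atom energies and
#' the residual account for the signal energy to float precision.  The
#' signal mean is subtracted first so the DC offset does not consume
#' iterations.  Deterministic given signal and dictionary.
#'
#' @param signal a `"rateSeries"`, an [LfpEnsemble-class] (decomposed as
#'   its trial average) or a numeric vector (then supply `dt` and `t0`).
#' @param dictionary an [mpDictionary()]; sensible default built from the
#'   signal.
#' @param maxAtoms iteration cap.
#' @param residualFraction stop once residual energy falls below this
#'   fraction of signal energy.
#' @param meanSubtract subtract the signal mean first (recommended).
#' @param dt,t0 sampling interval and first-sample time for numeric input.
#' @return an [MPDecomposition-class] object.
#' @export
matchingPursuit <- function(signal, dictionary = NULL, maxAtoms = 50,
                            residualFraction = 0.01, meanSubtract = TRUE,
                            dt = NULL, t0 = NULL) {
  if (inherits(signal, "rateSeries")) {
    dt <- signal$binWidth
    t0 <- signal$t[1]
    x <- signal$rate
  } else if (is(signal, "LfpEnsemble")) {
    dt <- 1 / signal@samplingRate
    t0 <- signal@times[1]
    x <- rowMeans(signal@data)
  } else {
    stopifnot(is.numeric(signal), !is.null(dt))
    if (is.null(t0)) t0 <- 0
    x <- as.numeric(signal)
  }
  if (any(!is.finite(x))) stop("signal must be finite")
  if (meanSubtract) x <- x - mean(x)
  if (is.null(dictionary)) dictionary <- mpDictionary(length(x), dt)
  stopifnot(inherits(dictionary, "mpDictionary"))
  raw <- mp_decompose_cpp(x, dictionary$sigmaSamp,
                          dictionary$freqHz * dt,
                          as.integer(maxAtoms), residualFraction)
  a <- raw$atoms
  df <- if (nrow(a) == 0)
    data.frame(tau = numeric(0), sigma = numeric(0), freq = numeric(0),
               amplitude = numeric(0), phase = numeric(0),
               energy = numeric(0), order = integer(0))
  else
    data.frame(tau = t0 + a[, "tau"] * dt, sigma = a[, "sigma"] * dt,
               freq = a[, "freq"] / dt, amplitude = a[, "amplitude"],
               phase = a[, "phase"], energy = a[, "energy"] * dt,
               order = seq_len(nrow(a)))
  df <- df[order(-df$energy), , drop = FALSE]
  rownames(df) <- NULL
  new("MPDecomposition", atoms = df, residual = raw$residual, signal = x,
      signalEnergy = raw$signalEnergy * dt, dt = dt, t0 = t0)
}

#' Reconstruct the atom sum of a decomposition
#'
#' @param dec an [MPDecomposition-class] object.
#' @param which atom rows to include (default all).
#' @return numeric vector on the signal's time grid.
#' @export
reconstructAtoms <- function(dec, which = seq_len(nrow(dec@atoms))) {
  stopifnot(is(dec, "MPDecomposition"))
  t <- dec@t0 + (seq_along(dec@signal) - 1) * dec@dt
  out <- numeric(length(t))
  for (i in which) {
    a <- dec@atoms[i, ]
    out <- out + evalGabor(list(tau = a$tau, sigma = a$sigma,
                                freqHz = a$freq, amplitude = a$amplitude,
                                phase = a$phase), t)
  }
  out
}

#' Wigner-Ville power map of a decomposition
#'
#' Cross-term-free sum of each atom's closed-form Wigner-Ville
#' distribution: a two-dimensional Gaussian centered at (tau, xi/2pi) with
#' time spread proportional to sigma and frequency spread proportional to
#' 1/sigma, scaled so the map integrates to the atom's energy.
#'
#' @param dec an [MPDecomposition-class] object.
#' @param tGrid,fGrid map grids (s, Hz); defaults: the signal's sample
#'   times and 0-50 Hz in 0.5 Hz steps.
#' @return list of class `"wvMap"` with `t`, `f` and `power`
#'   (time x frequency matrix, signal units squared times seconds).
#' @export
wignerVilleMap <- function(dec, tGrid = NULL, fGrid = NULL) {
  stopifnot(is(dec, "MPDecomposition"))
  if (is.null(tGrid))
    tGrid <- dec@t0 + (seq_along(dec@signal) - 1) * dec@dt
  if (is.null(fGrid)) fGrid <- seq(0, 50, by = 0.5)
  if (max(fGrid) > 0.5 / dec@dt)
    stop("fGrid extends beyond the signal's Nyquist frequency")
  pow <- matrix(0, length(tGrid), length(fGrid))
  for (i in seq_len(nrow(dec@atoms))) {
    a <- dec@atoms[i, ]
    gt <- exp(-2 * pi * ((tGrid - a$tau) / a$sigma)^2)
    gf <- exp(-2 * pi * (a$sigma * (fGrid - a$freq))^2)
    pow <- pow + 2 * a$energy * outer(gt, gf)
  }
  structure(list(t = tGrid, f = fGrid, power = pow), class = "wvMap")
}

# mean of a Gaussian profile exp(-2 pi ((x - mu)/s)^2) over [a, b)
gaussBandMean <- function(a, b, mu, s) {
  sd <- s / (2 * sqrt(pi))
  (s / sqrt(2)) * (pnorm((b - mu) / sd) - pnorm((a - mu) / sd)) / (b - a)
}

#' Mean Wigner-Ville power in a band and epoch
#'
#' The band/epoch power statistic: the mean of the Wigner-Ville map over
#' a frequency band and time epoch (12-20 Hz and, by convention, the 90 ms
#' before or the 40-130 ms after the event).  For an
#' [MPDecomposition-class] the mean is evaluated in closed form from the
#' atoms' Gaussian profiles; for a `"wvMap"` it is the mean of the cells
#' intersecting the band and epoch.  Rate-derived powers are in
#' (spikes/s)^2 x s; LFP powers in squared input units x s.
#'
#' @param x an [MPDecomposition-class] or `"wvMap"`.
#' @param band frequency band (Hz), length 2.
#' @param epoch half-open time epoch (s), length 2.
#' @return scalar mean power.
#' @export
bandEpochPower <- function(x, band = c(12, 20), epoch = c(0.040, 0.130)) {
  stopifnot(band[1] < band[2], epoch[1] < epoch[2])
  if (is(x, "MPDecomposition")) {
    if (nrow(x@atoms) == 0) return(0)
    tm <- gaussBandMean(epoch[1], epoch[2], x@atoms$tau, x@atoms$sigma)
    fm <- gaussBandMean(band[1], band[2], x@atoms$freq,
                        1 / x@atoms$sigma)
    return(sum(2 * x@atoms$energy * tm * fm))
  }
  if (inherits(x, "wvMap")) {
    ti <- inHalfOpen(x$t, epoch)
    fi <- x$f >= band[1] & x$f <= band[2]
    if (!any(ti) || !any(fi))
      stop("band/epoch does not intersect the map grid")
    return(mean(x$power[ti, fi]))
  }
  stop("x must be an MPDecomposition or a wvMap")
}

#' Pre/post band power of a spike ensemble or rate series
#'
#' Convenience pipeline: PSTH (for spike input), Matching Pursuit with the
#' configured dictionary, and the band power in the pre- and post-event
#' epochs.
#'
#' @param x a [SpikeEnsemble-class], `"rateSeries"`, or list of spike-time
#'   vectors (with the config window).
#' @param config an [mpPowerConfig()].
#' @return named numeric `c(pre, post)`.
#' @export
bandPowerPrePost <- function(x, config = mpPowerConfig()) {
  rs <- if (inherits(x, "rateSeries")) x
  else buildPsth(x, binWidth = config$binWidth, window = config$window)
  dic <- mpDictionary(length(rs$rate), rs$binWidth,
                      maxFreqHz = config$maxFreqHz,
                      freqStepHz = config$freqStepHz,
                      sigmaSamp = config$sigmaSamp)
  dec <- matchingPursuit(rs, dictionary = dic, maxAtoms = config$maxAtoms,
                         residualFraction = config$residualFraction)
  c(pre = bandEpochPower(dec, config$band, config$epochPre),
    post = bandEpochPower(dec, config$band, config$epochPost))
}

#' Analysis configuration for band-power pipelines
#'
#' Bundles the analysis window, PSTH bin width, frequency band, epochs and
#' dictionary controls used by [bandPowerPrePost()] and the resampling
#' tests.  Defaults follow the conventions of the transient low-beta
#' analysis: window -0.3 to 0.724 s, 1 ms bins, 12-20 Hz band, epochs
#' \[-90, 0) and \[40, 130) ms.
#'
#' @param window analysis window (s).
#' @param binWidth PSTH bin width (s).
#' @param band frequency band (Hz).
#' @param epochPre,epochPost half-open epochs (s).
#' @param maxFreqHz,freqStepHz,sigmaSamp dictionary controls
#'   (see [mpDictionary()]).
#' @param maxAtoms,residualFraction stop rule (see [matchingPursuit()]).
#' @return list of class `"mpPowerConfig"`.
#' @export
mpPowerConfig <- function(window = c(-0.3, 0.724), binWidth = 0.001,
                          band = c(12, 20), epochPre = c(-0.090, 0),
                          epochPost = c(0.040, 0.130), maxFreqHz = 50,
                          freqStepHz = 0.5, sigmaSamp = NULL,
                          maxAtoms = 50, residualFraction = 0.01) {
  structure(list(window = window, binWidth = binWidth, band = band,
                 epochPre = epochPre, epochPost = epochPost,
                 maxFreqHz = maxFreqHz, freqStepHz = freqStepHz,
                 sigmaSamp = sigmaSamp, maxAtoms = maxAtoms,
                 residualFraction = residualFraction),
            class = "mpPowerConfig")
}

#' Reduced configuration for resampling-heavy analyses
#'
#' A shorter window, coarser bins and a lean dictionary that preserve the
#' 12-20 Hz band and the pre/post epochs while making the thousands of
#' decompositions of the bootstrap and permutation procedures affordable.
#'
#' @param binWidth PSTH bin width (s).
#' @return an [mpPowerConfig()].
#' @export
fastPowerConfig <- function(binWidth = 0.002) {
  mpPowerConfig(window = c(-0.096, 0.160), binWidth = binWidth,
                maxFreqHz = 30, freqStepHz = 1,
                sigmaSamp = c(8, 32), maxAtoms = 6,
                residualFraction = 0.05)
}

#' Classify a spike waveform by its trough-to-peak interval
#'
#' Narrow-spiking (putative inhibitory) and broad-spiking (putative
#' excitatory) cells are separated by the interval between the waveform
#' trough and the subsequent peak: at most 150 microseconds is classed
#' inhibitory, at least 350 microseconds excitatory, and intervals between
#' the thresholds are left unclassified.
#'
#' @param waveform numeric samples of the mean spike waveform.
#' @param samplingRate waveform sampling rate (Hz).
#' @return list with `deltaMicro` (trough-to-peak interval, microseconds)
#'   and `label` (`"inhibitory"`, `"excitatory"` or `"unclassified"`).
#' @export
classifyWaveform <- function(waveform, samplingRate = 40000) {
  d <- diff(waveform)
  if (all(d >= 0) || all(d <= 0))
    stop("waveform is monotone; no peak/trough structure")
  trough <- which.min(waveform)
  if (trough >= length(waveform))
    stop("waveform trough has no subsequent peak")
  peak <- trough + which.max(waveform[(trough + 1):length(waveform)])
  deltaMicro <- (peak - trough) / samplingRate * 1e6
  label <- if (deltaMicro <= 150) "inhibitory"
  else if (deltaMicro >= 350) "excitatory"
  else "unclassified"
  list(deltaMicro = deltaMicro, label = label)
}
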