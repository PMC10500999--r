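# Spike-LFP phase alignment: select oscillatory LFP recordings, assign
# spike phases from the dominant Gabor carrier, and build the
# nonuniformity-corrected phase histogram with a uniformity test.

#' Select an oscillatory LFP recording
#'
#' A recording qualifies when at least one of the ten highest-energy atoms
#' of the trial-averaged LFP decomposition has its carrier inside the
#' frequency band and its temporal support (center plus or minus two
#' envelope widths) overlapping the epoch.  The qualifying atom of
#' greatest energy is returned.
#'
#' @param dec an [MPDecomposition-class] of the trial-averaged LFP.
#' @param band frequency band (Hz).
#' @param epoch half-open epoch (s).
#' @param topN how many of the strongest atoms are screened.
#' @return list with `selected` (logical) and `atom` (one-row data.frame
#'   or NULL).
#' @export
selectOscillatoryLfp <- function(dec, band = c(12, 20),
                                 epoch = c(0.040, 0.130), topN = 10) {
  stopifnot(is(dec, "MPDecomposition"))
  a <- dec@atoms
  if (nrow(a) == 0) return(list(selected = FALSE, atom = NULL))
  a <- a[seq_len(min(topN, nrow(a))), , drop = FALSE]
  ok <- a$freq >= band[1] & a$freq <= band[2] &
    (a$tau + 2 * a$sigma) > epoch[1] & (a$tau - 2 * a$sigma) < epoch[2]
  if (!any(ok)) return(list(selected = FALSE, atom = NULL))
  list(selected = TRUE, atom = a[which(ok)[1], , drop = FALSE])
}

#' Assign spike phases from an atom's carrier
#'
#' Each spike time is mapped to the inverse cosine of the atom's carrier,
#' giving principal-value phases in \[0, pi\]: spikes at a carrier peak get
#' phase 0 and spikes at a trough get phase pi.  The carrier is defined
#' everywhere, so spikes outside the atom's envelope support are still
#' assigned a phase (flagged in the `outsideSupport` attribute).
#'
#' @param spikeTimes spike times (s), typically restricted to the
#'   post-event epoch.
#' @param atom a one-row atom table (from [atoms()] or
#'   [selectOscillatoryLfp()]) or a [gaborAtom()].
#' @return numeric phases in \[0, pi\] with attribute `outsideSupport`.
#' @export
assignSpikePhases <- function(spikeTimes, atom) {
  if (is.data.frame(atom)) atom <- as.list(atom[1, ])
  if (!is.null(atom$freqHz)) atom$freq <- atom$freqHz
  theta <- 2 * pi * atom$freq * (spikeTimes - atom$tau) + atom$phase
  phi <- acos(cos(theta))
  attr(phi, "outsideSupport") <-
    abs(spikeTimes - atom$tau) > 2.5 * atom$sigma
  phi
}

#' Corrected spike-phase histogram with uniformity test
#'
#' Cosine phase is represented nonuniformly in a regularly sampled epoch,
#' so raw spike-phase counts are divided, per bin, by the counts of the
#' candidate phases that the carrier contributes over all epoch samples.
#' Uniformity of the spike phases relative to the candidate distribution
#' is evaluated by comparing the two cumulative distributions
#' (Kolmogorov-Smirnov test, one-sample against the candidate CDF: the
#' candidates are a deterministic sampling of the carrier, not a random
#' sample, so a two-sample comparison would be miscalibrated).
#'
#' @param phases spike phases in \[0, pi\] (see [assignSpikePhases()]).
#' @param atom the atom the phases came from.
#' @param epoch half-open epoch (s) over which candidates are sampled.
#' @param samplingRate candidate sampling rate (Hz), normally the LFP
#'   sampling rate.
#' @param binDeg bin width in degrees (10 by default).
#' @return list with `edges` (deg), `spikeCounts`, `candidateCounts`,
#'   `ratio` (corrected per-bin ratio), `ks` (statistic and p) and
#'   `merged` (bins merged into a neighbor because no candidate fell in
#'   them).
#' @export
correctedPhaseHistogram <- function(phases, atom, epoch = c(0.040, 0.130),
                                    samplingRate = 1000, binDeg = 10) {
  if (is.data.frame(atom)) atom <- as.list(atom[1, ])
  if (!is.null(atom$freqHz)) atom$freq <- atom$freqHz
  dt <- 1 / samplingRate
  tt <- seq(epoch[1], epoch[2] - dt / 2, by = dt)
  cand <- acos(cos(2 * pi * atom$freq * (tt - atom$tau) + atom$phase))
  edges <- seq(0, 180, by = binDeg)
  nb <- length(edges) - 1
  binOf <- function(x) pmin(floor(x * 180 / pi / binDeg) + 1L, nb)
  sc <- tabulate(binOf(phases), nbins = nb)
  cc <- tabulate(binOf(cand), nbins = nb)
  merged <- integer(0)
  # a bin the carrier never visits cannot be corrected; merge into the
  # nearest populated neighbor
  for (b in which(cc == 0)) {
    nbr <- which(cc > 0)
    if (!length(nbr)) stop("no candidate phases in the epoch")
    j <- nbr[which.min(abs(nbr - b))]
    cc[j] <- cc[j]
    sc[j] <- sc[j] + sc[b]
    sc[b] <- 0L
    merged <- c(merged, b)
  }
  ratio <- ifelse(cc > 0, sc / cc, NA_real_)
  # the candidate phases are a deterministic, effectively exhaustive
  # sampling of the carrier, not a random sample, so spike phases are
  # tested one-sample against the candidate cumulative distribution
  ks <- suppressWarnings(ks.test(phases, stats::ecdf(cand)))
  list(edges = edges, spikeCounts = sc, candidateCounts = cc,
       ratio = ratio, ks = list(statistic = unname(ks$statistic),
                                p = ks$p.value), merged = merged)
}
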