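# Inferential procedures on band-power statistics: paired/unpaired rank
# tests, the N10 subsampling bootstrap, per-neuron block tests, the
# location-preference permutation test and the preferred/nonpreferred
# ratio analysis of errors.

# band power of a subset of trials: PSTH -> MP -> band/epoch mean.
# Lean path for resampling loops: identical math to
# matchingPursuit() + bandEpochPower() without the container overhead
# (equality is covered by a regression test).
subsetPower <- function(spikeList, idx, config, epoch) {
  rs <- buildPsth(spikeList[idx], binWidth = config$binWidth,
                  window = config$window)
  x <- rs$rate - mean(rs$rate)
  dic <- mpDictionary(length(x), rs$binWidth,
                      maxFreqHz = config$maxFreqHz,
                      freqStepHz = config$freqStepHz,
                      sigmaSamp = config$sigmaSamp)
  raw <- mp_decompose_cpp(x, dic$sigmaSamp, dic$freqHz * rs$binWidth,
                          as.integer(config$maxAtoms),
                          config$residualFraction)
  a <- raw$atoms
  if (nrow(a) == 0) return(0)
  dt <- rs$binWidth
  tau <- rs$t[1] + a[, "tau"] * dt
  sig <- a[, "sigma"] * dt
  frq <- a[, "freq"] / dt
  en <- a[, "energy"] * dt
  sum(2 * en * gaussBandMean(epoch[1], epoch[2], tau, sig) *
        gaussBandMean(config$band[1], config$band[2], frq, 1 / sig))
}

asSpikeList <- function(x) {
  if (is(x, "SpikeEnsemble")) x@spikes
  else if (is.list(x)) x
  else stop("expected a SpikeEnsemble or list of spike-time vectors")
}

#' Paired band-power test across units
#'
#' Wilcoxon signed-rank test of the per-unit pre-event versus post-event
#' band powers (two-sided).
#'
#' @param pre,post paired per-unit band powers (>= 6 units).
#' @return list with `statistic` and `p`.
#' @export
pairedBandPowerTest <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  if (length(pre) < 6) stop("need at least 6 paired units")
  if (all(post - pre == 0))
    stop("all paired differences are zero; test undefined")
  ht <- suppressWarnings(wilcox.test(post, pre, paired = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Unpaired band-power test between groups
#'
#' Two-sided Mann-Whitney (rank-sum) test of post-event band powers from
#' two independent groups of recordings.
#'
#' @param a,b band powers for the two groups (each >= 5 values).
#' @return list with `statistic` and `p`.
#' @export
unpairedBandPowerTest <- function(a, b) {
  if (length(a) < 5 || length(b) < 5)
    stop("need at least 5 values per group")
  ht <- suppressWarnings(wilcox.test(a, b))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Subsampled band-power difference test
#'
#' Bootstrap comparison of band power between two conditions with unequal
#' trial counts.  `N10` (about 10 percent of the smaller condition, floored
#' at 5) trials are drawn without replacement from each condition, the
#' band power of each subset average is computed, and the difference of
#' powers recorded; the mean over `inner` such draws is the statistic
#' `Dbar`.  Its null distribution is built by repeating the identical
#' procedure on random subsets drawn from the union of the two
#' conditions: each of `outer` repetitions splits the pooled trials at
#' random into pseudo-conditions of the original sizes and recomputes
#' `Dbar`.  The p value is the two-tailed tail probability of `Dbar` in
#' that null sample.  When both arguments are the same object the same
#' subsets are drawn for the two conditions, so `Dbar` is exactly zero.
#'
#' @param spikesA,spikesB [SpikeEnsemble-class] objects (or spike-time
#'   lists) for the two conditions.
#' @param config an [mpPowerConfig()].
#' @param epoch epoch compared (defaults to the post-event epoch).
#' @param inner resamples per statistic.
#' @param outer null-distribution repetitions.
#' @param seed integer seed.
#' @return list with `N10`, `Dbar`, `null`, `p`, `inner`, `outer`.
#' @export
subsampledPowerDifference <- function(spikesA, spikesB,
                                      config = mpPowerConfig(),
                                      epoch = NULL, inner = 1000,
                                      outer = 100, seed = 1) {
  la <- asSpikeList(spikesA)
  lb <- asSpikeList(spikesB)
  same <- identical(la, lb)
  if (is.null(epoch)) epoch <- config$epochPost
  nA <- length(la)
  nB <- length(lb)
  N10 <- floor(0.1 * min(nA, nB) + 0.5)
  if (N10 < 5)
    stop("too few trials: the 10% subsample would have fewer than 5 trials")
  withSeed(seed, {
    draws <- numeric(inner)
    for (r in seq_len(inner)) {
      ia <- sample.int(nA, N10)
      ib <- if (same) ia else sample.int(nB, N10)
      draws[r] <- subsetPower(la, ia, config, epoch) -
        subsetPower(lb, ib, config, epoch)
    }
    Dbar <- mean(draws)
    pool <- c(la, lb)
    nP <- nA + nB
    null <- numeric(outer)
    for (o in seq_len(outer)) {
      perm <- sample.int(nP)
      pa <- pool[perm[seq_len(nA)]]
      pb <- pool[perm[(nA + 1):nP]]
      d <- numeric(inner)
      for (r in seq_len(inner)) {
        d[r] <- subsetPower(pa, sample.int(nA, N10), config, epoch) -
          subsetPower(pb, sample.int(nB, N10), config, epoch)
      }
      null[o] <- mean(d)
    }
    pHi <- (1 + sum(null >= Dbar)) / (outer + 1)
    pLo <- (1 + sum(null <= Dbar)) / (outer + 1)
    list(N10 = N10, Dbar = Dbar, null = null,
         p = min(1, 2 * min(pHi, pLo)), inner = inner, outer = outer)
  })
}

#' Per-neuron block test of oscillation onset
#'
#' The unit's trials are divided into consecutive blocks of `blockSize`
#' (an incomplete final block is dropped); pre- and post-event band powers
#' are computed per block and compared with a Wilcoxon signed-rank test.
#'
#' @param spikes a [SpikeEnsemble-class] (or spike-time list).
#' @param blockSize trials per block.
#' @param config an [mpPowerConfig()].
#' @return list with `p`, `nBlocks` and a data.frame of per-block powers.
#' @export
perUnitBlockTest <- function(spikes, blockSize = 50,
                             config = mpPowerConfig()) {
  lst <- asSpikeList(spikes)
  nBlocks <- as.integer(length(lst) %/% blockSize)
  if (nBlocks < 2) stop("need at least 2 complete blocks")
  pre <- post <- numeric(nBlocks)
  for (b in seq_len(nBlocks)) {
    idx <- ((b - 1) * blockSize + 1):(b * blockSize)
    pre[b] <- subsetPower(lst, idx, config, config$epochPre)
    post[b] <- subsetPower(lst, idx, config, config$epochPost)
  }
  ht <- suppressWarnings(wilcox.test(post, pre, paired = TRUE))
  list(p = ht$p.value, nBlocks = nBlocks,
       blocks = data.frame(block = seq_len(nBlocks), pre = pre,
                           post = post))
}

#' Permutation test for a location preference in oscillation strength
#'
#' Statistic: the absolute difference in post-event band power between the
#' two cued locations, computed from the trial-averaged PSTH of each
#' location.  The null is built by permuting the location labels across
#' trials and recomputing both averages and powers.
#'
#' @param spikes a [SpikeEnsemble-class] (or spike-time list).
#' @param location per-trial location labels (two levels, each >= 25
#'   trials).
#' @param config an [mpPowerConfig()].
#' @param nPerm number of permutations (a count below 100 triggers a
#'   precision warning).
#' @param seed integer seed.
#' @return list with `statistic`, `p` and `nPerm`.
#' @export
locationPreferenceTest <- function(spikes, location,
                                   config = mpPowerConfig(),
                                   nPerm = 1000, seed = 1) {
  lst <- asSpikeList(spikes)
  stopifnot(length(location) == length(lst))
  lev <- unique(location)
  if (length(lev) != 2) stop("location must have exactly two levels")
  if (min(table(location)) < 25)
    stop("need at least 25 trials per location")
  if (nPerm < 100)
    warning("fewer than 100 permutations gives a coarse p value")
  stat <- function(lab) {
    abs(subsetPower(lst, which(lab == lev[1]), config, config$epochPost) -
        subsetPower(lst, which(lab == lev[2]), config, config$epochPost))
  }
  withSeed(seed, {
    obs <- stat(location)
    perm <- numeric(nPerm)
    for (i in seq_len(nPerm)) perm[i] <- stat(sample(location))
    list(statistic = obs, p = (1 + sum(perm >= obs)) / (nPerm + 1),
         nPerm = nPerm)
  })
}

#' Preferred/nonpreferred oscillation ratio analysis of errors
#'
#' For each unit the cued location with the larger post-event band power
#' over all trials (correct and error combined) is deemed preferred, so
#' the all-trials ratio of powers (preferred over nonpreferred) is at
#' least one by construction.  The ratio is then recomputed on correct
#' and error trials separately, retaining the original designation.  If
#' errors arise by misrouting, the error-trial oscillation takes on the
#' amplitude of the other location, pulling the error ratios toward or
#' below one; the distributions of log ratios on correct versus error
#' trials are compared with a two-sample Kolmogorov-Smirnov test.
#'
#' @param units list of unit records, each a list with `spikes` (a
#'   [SpikeEnsemble-class] or spike list), `location` (per-trial labels,
#'   two levels) and `correct` (per-trial logical).
#' @param config an [mpPowerConfig()].
#' @param minTrials minimum trials per location-by-outcome cell; units
#'   below it are excluded and reported.
#' @param balanceTrials subsample every location-by-outcome cell to the
#'   unit's smallest cell before computing the correct/error ratios, so a
#'   trial-count-dependent noise floor in the power estimate cannot
#'   masquerade as an outcome effect.
#' @param seed seed for the balancing subsample.
#' @return list with `table` (per-unit ratios), `ks` (statistic and p of
#'   the correct-vs-error comparison) and `excluded` (unit indices).
#' @export
preferredRatioAnalysis <- function(units, config = mpPowerConfig(),
                                   minTrials = 5, balanceTrials = TRUE,
                                   seed = 1) {
  rows <- list()
  excluded <- integer(0)
  withSeed(seed, for (u in seq_along(units)) {
    unit <- units[[u]]
    lst <- asSpikeList(unit$spikes)
    loc <- unit$location
    ok <- unit$correct
    lev <- sort(unique(loc))
    stopifnot(length(lev) == 2, length(loc) == length(lst),
              length(ok) == length(lst))
    cells <- table(loc, ok)
    if (nrow(cells) < 2 || ncol(cells) < 2 || min(cells) < minTrials) {
      excluded <- c(excluded, u)
      next
    }
    m <- min(cells)
    pw <- function(sel) vapply(lev, function(L) {
      idx <- which(sel & loc == L)
      if (balanceTrials && length(idx) > m) idx <- sample(idx, m)
      subsetPower(lst, idx, config, config$epochPost)
    }, numeric(1))
    pAll <- vapply(lev, function(L)
      subsetPower(lst, which(loc == L), config, config$epochPost),
      numeric(1))
    pref <- lev[which.max(pAll)]
    npref <- setdiff(lev, pref)
    pCor <- pw(ok)
    pErr <- pw(!ok)
    rows[[length(rows) + 1]] <- data.frame(
      unit = u, preferred = pref,
      ratio_all = max(pAll) / min(pAll),
      ratio_correct = pCor[pref] / pCor[npref],
      ratio_error = pErr[pref] / pErr[npref])
  })
  if (!length(rows)) stop("no unit had enough trials in every cell")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ks <- suppressWarnings(ks.test(log(tab$ratio_correct),
                                 log(tab$ratio_error)))
  list(table = tab,
       ks = list(statistic = unname(ks$statistic), p = ks$p.value),
       excluded = excluded)
}
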