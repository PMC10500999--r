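# PSTH conventions, boxcar display filter, detrending, Matching Pursuit,
# Wigner-Ville power and waveform classification.

test_that("PSTH counts, units and trial weighting are correct", {
  spk <- spikeEnsemble(list(0.0005), window = c(0, 0.01))
  rs <- buildPsth(spk, binWidth = 0.001)
  expect_equal(rs$rate[1], 1000)
  expect_true(all(rs$rate[-1] == 0))

  hom <- simulateSpikeTrains(rateSpec(20), 2000, window = c(0, 1),
                             seed = 31)
  rh <- buildPsth(hom, binWidth = 0.01)
  se <- sqrt(20 / (2000 * 0.01))
  expect_true(all(abs(rh$rate - 20) < 4 * se))

  a <- structure(list(t = 1:3, rate = rep(10, 3), binWidth = 1,
                      nTrials = 100), class = "rateSeries")
  b <- structure(list(t = 1:3, rate = rep(30, 3), binWidth = 1,
                      nTrials = 300), class = "rateSeries")
  expect_equal(populationPsth(list(a, b))$rate, rep(25, 3))
  expect_error(buildPsth(spikeEnsemble(list(), window = c(0, 1))), "empty")
})

test_that("boxcar smoothing has unit DC gain and the sinc response", {
  rs <- structure(list(t = seq(0, 1.023, by = 0.001),
                       rate = rep(7, 1024), binWidth = 0.001,
                       nTrials = 1), class = "rateSeries")
  expect_equal(boxcarSmooth(rs)$rate, rs$rate)

  imp <- rs
  imp$rate <- rep(0, 1024)
  imp$rate[500] <- 1000   # unit impulse: area 1000 sp/s * 1 ms = 1
  sm <- boxcarSmooth(imp, width = 0.1)
  expect_equal(max(sm$rate), 1 / 0.101, tolerance = 0.01)

  sine <- rs
  sine$rate <- sin(2 * pi * 16 * sine$t)
  smS <- boxcarSmooth(sine, width = 0.1)
  mid <- 300:700
  att <- max(abs(smS$rate[mid]))
  W <- 0.101  # effective window, rounded to an odd bin count
  expect_equal(att, abs(sin(pi * 16 * W) / (pi * 16 * W)),
               tolerance = 0.05)
  expect_error(boxcarSmooth(rs, width = 0.0017), "multiple")
})

test_that("low-coherence detrending and the ipsilateral flip behave", {
  t <- seq(0, 0.5, by = 0.01)
  coh <- c(-0.256, -0.032, 0, 0.032, 0.256)
  mk <- function(slope) structure(
    list(t = t, rate = 20 + slope * t, binWidth = 0.01, nTrials = 50),
    class = "rateSeries")
  rates <- lapply(coh * 40, mk)  # ramp proportional to coherence
  out <- detrendLowCoherence(rates, coh)
  lowIdx <- which(abs(coh) <= 0.032)
  lowMean <- Reduce(`+`, lapply(out$rates[lowIdx], `[[`, "rate")) /
    length(lowIdx)
  expect_lt(max(abs(lowMean)), 1e-10)
  late <- vapply(out$rates, function(r) r$rate[length(t)], numeric(1))
  expect_true(all(diff(late[order(out$coherence)]) >= 0))

  flip <- detrendLowCoherence(rates, coh, flipForIpsilateral = TRUE)
  expect_equal(flip$coherence, -coh)
  expect_error(detrendLowCoherence(rates[c(1, 5)], coh[c(1, 5)]),
               "low-coherence")
})

test_that("MP recovers dictionary atoms exactly and separates two atoms", {
  dt <- 0.001
  tt <- -0.3 + (0:1023) * dt
  g <- evalGabor(gaborAtom(0.1, 0.064, 16, amplitude = 5, phase = 0.7), tt)
  dec <- matchingPursuit(g, dt = dt, t0 = tt[1], meanSubtract = FALSE,
                         residualFraction = 1e-10, maxAtoms = 3)
  a1 <- atoms(dec)[1, ]
  expect_equal(a1$tau, 0.1, tolerance = 1e-9)
  expect_equal(a1$sigma, 0.064, tolerance = 1e-9)
  expect_equal(a1$freq, 16, tolerance = 1e-9)
  expect_equal(a1$amplitude, 5, tolerance = 1e-6)
  expect_lt(residualEnergy(dec) / dec@signalEnergy, 1e-6)

  two <- evalGabor(gaborAtom(-0.1, 0.032, 14, amplitude = 4), tt) +
    evalGabor(gaborAtom(0.35, 0.064, 8, amplitude = 3), tt)
  dec2 <- matchingPursuit(two, dt = dt, t0 = tt[1], meanSubtract = FALSE,
                          maxAtoms = 2)
  a <- atoms(dec2)
  expect_equal(sort(a$freq), c(8, 14), tolerance = 0.51)
  expect_equal(sort(a$tau), c(-0.1, 0.35), tolerance = 0.002)
})

test_that("MP screening agrees with brute-force projection search", {
  dt <- 0.002
  n <- 128
  tt <- (0:(n - 1)) * dt
  set.seed(33)
  x <- evalGabor(gaborAtom(0.12, 0.05, 15, amplitude = 3), tt) + rnorm(n)
  x <- x - mean(x)
  dic <- mpDictionary(n, dt, maxFreqHz = 25, freqStepHz = 2.5,
                      sigmaSamp = c(8, 25))
  dec <- matchingPursuit(x, dt = dt, t0 = 0, dictionary = dic,
                         maxAtoms = 1, meanSubtract = FALSE)
  # exhaustive search over the same dictionary
  best <- -Inf
  bestAtom <- NULL
  for (sg in dic$sigmaSamp * dt) for (f in dic$freqHz) for (tau in tt) {
    s <- tt - tau
    w <- exp(-pi * s^2 / sg^2)
    u <- w * cos(2 * pi * f * s)
    v <- w * sin(2 * pi * f * s)
    G <- matrix(c(sum(u * u), sum(u * v), sum(u * v), sum(v * v)), 2)
    if (abs(det(G)) < 1e-10) next
    cv <- c(sum(x * u), sum(x * v))
    gain <- drop(t(cv) %*% solve(G, cv))
    if (gain > best) {
      best <- gain
      bestAtom <- c(tau, sg, f)
    }
  }
  a <- atoms(dec)[1, ]
  expect_equal(c(a$tau, a$sigma, a$freq), bestAtom, tolerance = 1e-9)
  expect_equal(a$energy, best * dt, tolerance = 1e-6)
})

test_that("MP is deterministic, greedy and energy conserving", {
  set.seed(34)
  x <- rnorm(512)
  d1 <- matchingPursuit(x, dt = 0.001, maxAtoms = 12)
  d2 <- matchingPursuit(x, dt = 0.001, maxAtoms = 12)
  expect_identical(atoms(d1), atoms(d2))

  en <- d1@atoms$energy[order(d1@atoms$order)]
  resid <- d1@signalEnergy - cumsum(en)
  expect_true(all(diff(resid) < 0))
  expect_lt(resid[length(resid)], d1@signalEnergy)
  expect_lt(abs(sum(en) + residualEnergy(d1) - d1@signalEnergy) /
              d1@signalEnergy, 1e-6)
})

test_that("Wigner-Ville map peaks at the atom and integrates to its energy", {
  dt <- 0.001
  tt <- -0.3 + (0:1023) * dt
  g <- evalGabor(gaborAtom(0.085, 0.05, 16, amplitude = 4), tt)
  dec <- matchingPursuit(g, dt = dt, t0 = tt[1], meanSubtract = FALSE,
                         maxAtoms = 1)
  map <- wignerVilleMap(dec)
  pk <- which(map$power == max(map$power), arr.ind = TRUE)
  expect_lt(abs(map$t[pk[1]] - 0.085), 0.0011)
  expect_lt(abs(map$f[pk[2]] - 16), 0.51)
  integ <- sum(map$power) * dt * diff(map$f[1:2])
  expect_equal(integ, sum(atoms(dec)$energy), tolerance = 0.01)

  # the closed-form band/epoch mean matches the discrete map mean
  expect_equal(bandEpochPower(dec), bandEpochPower(map), tolerance = 0.02)

  empty <- matchingPursuit(rep(0, 256), dt = dt, maxAtoms = 5)
  expect_true(all(wignerVilleMap(empty)$power == 0))
  expect_error(wignerVilleMap(dec, fGrid = seq(0, 900, 10)), "Nyquist")
})

test_that("band/epoch power is band selective and offset invariant", {
  # a low-frequency transient long enough to be spectrally narrow
  # (a 4-5 cycle envelope; shorter transients necessarily smear in
  # frequency) shows up in the 4-11 Hz band, not in 12-20 Hz
  spkTheta <- simulateSpikeTrains(
    rateSpec(20, gaborAtom(0.18, 0.12, 6, amplitude = 25)), 500,
    seed = 35)
  spkBeta <- simulateSpikeTrains(dm49RateSpec(), 500, seed = 35)
  pw <- function(spk, band) {
    dec <- matchingPursuit(buildPsth(spk, 0.001))
    c(pre = bandEpochPower(dec, band, c(-0.09, 0)),
      post = bandEpochPower(dec, band, c(0.08, 0.28)))
  }
  b4 <- pw(spkTheta, c(4, 11))
  expect_gt(b4["post"] / max(b4["pre"], 1e-9), 10)
  b12 <- pw(spkTheta, c(12, 20))
  bref <- pw(spkBeta, c(12, 20))
  expect_lt(b12["post"], 0.2 * bref["post"])

  # offset invariance (mean subtraction)
  cfg <- fastPowerConfig()
  rs <- buildPsth(spkBeta, cfg$binWidth, window = cfg$window)
  rsOff <- rs
  rsOff$rate <- rs$rate + 50
  expect_equal(bandEpochPower(matchingPursuit(rs)),
               bandEpochPower(matchingPursuit(rsOff)), tolerance = 1e-9)
})

test_that("a windowed sinusoid concentrates power around its carrier", {
  # several carrier cycles inside the window keep the spectral spread
  # below the +-4 Hz concentration band
  dt <- 0.001
  tt <- -0.3 + (0:1023) * dt
  x <- ifelse(tt >= 0 & tt < 0.3, sin(2 * pi * 16 * tt), 0)
  dec <- matchingPursuit(x, dt = dt, t0 = tt[1], maxAtoms = 20)
  map <- wignerVilleMap(dec)
  ep <- map$t >= 0 & map$t < 0.3
  inBand <- map$f >= 12 & map$f <= 20
  expect_gt(sum(map$power[ep, inBand]) / sum(map$power[ep, ]), 0.8)
})

test_that("dominant-atom carrier recovery holds across the beta range", {
  for (f0 in c(13, 15, 17, 19)) {
    spec <- rateSpec(20, gaborAtom(0.085, 0.08, f0, amplitude = 25))
    spk <- simulateSpikeTrains(spec, 500, seed = 36 + f0)
    dec <- matchingPursuit(buildPsth(spk, 0.001))
    expect_lt(abs(atoms(dec)$freq[1] - f0), 1)
  }
})

test_that("waveforms classify by trough-to-peak interval", {
  sr <- 40000  # 25 us per sample
  mk <- function(gapSamples) {
    w <- rep(0, 60)
    w[20] <- -1
    w[20 + gapSamples] <- 0.5
    w + cumsum(rep(1e-6, 60))  # break monotone ties
  }
  expect_identical(classifyWaveform(mk(4), sr)$label, "inhibitory")
  expect_identical(classifyWaveform(mk(16), sr)$label, "excitatory")
  expect_identical(classifyWaveform(mk(10), sr)$label, "unclassified")
  expect_equal(classifyWaveform(mk(4), sr)$deltaMicro, 100)
  expect_error(classifyWaveform(seq(0, 1, length.out = 30), sr),
               "monotone")
})
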