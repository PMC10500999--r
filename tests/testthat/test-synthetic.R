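# Generators: truncated-exponential durations, trial conditions, path
# simulation, Poisson spike trains and LFP synthesis.

test_that("truncated-exponential sampler matches its closed-form CDF", {
  d <- durationDist(0.2, 0.2, 0.1)
  expect_equal(sampleTruncExp(d, 5, seed = 1), rep(0.2, 5))

  x <- sampleTruncExp(durationDist(0.2, 0.6, 0.1), 1e5, seed = 2)
  expect_true(all(x >= 0.2 & x <= 0.6))
  expect_lt(mean(x), 0.3)  # truncation pulls the mean below tMin + tau

  y <- sampleTruncExp(durationDist(0.1, 1.5, 0.35), 1e5, seed = 3)
  grid <- seq(0.1, 1.5, length.out = 400)
  emp <- ecdf(y)(grid)
  expect_lt(max(abs(emp - truncExpCDF(grid, 0.1, 1.5, 0.35))), 0.01)

  expect_identical(sampleTruncExp(durationDist(0.1, 1, 0.3), 100, seed = 9),
                   sampleTruncExp(durationDist(0.1, 1, 0.3), 100, seed = 9))
  expect_error(durationDist(0.5, 0.2, 0.1), "tMin")
  expect_error(durationDist(0.1, 0.2, -1), "tau")
})

test_that("trial conditions respect the stated probabilities", {
  des <- trialDesign("cued_attention")
  cond <- sampleTrialConditions(des, 3e4, seed = 4)
  pSame <- mean(cond$relation == "same")
  se <- sqrt((1 / 3) * (2 / 3) / 3e4)
  expect_lt(abs(pSame - 1 / 3), 3 * se)

  cond2 <- sampleTrialConditions(des, 6e4, seed = 5)
  tab <- table(abs(cond2$coherence))
  expect_setequal(names(tab),
                  as.character(c(0, 0.032, 0.064, 0.128, 0.256, 0.512)))
  se6 <- sqrt((1 / 6) * (5 / 6) / 6e4)
  expect_true(all(abs(tab / 6e4 - 1 / 6) < 3 * se6))

  des3 <- trialDesign("variable_location")
  cond3 <- sampleTrialConditions(des3, 1e4, seed = 6)
  expect_lt(abs(mean(cond3$cue_location == "upper") - 0.5),
            3 * sqrt(0.25 / 1e4))
  expect_true(all(cond3$relation == "single"))
  expect_error(trialDesign("no_such_task"))
})

test_that("path-simulated choices obey symmetry and the misrouting mixture", {
  # symmetric: zero drift -> chance
  des <- trialDesign("cued_attention",
                     durations = durationDist(0.4, 0.4, 0.1))
  p0 <- ddmParams(7.9, 0.74, C0 = 0)
  tr <- simulateChoices(des, p0, 8000, seed = 7)
  sub <- tr[tr$coherence == 0, ]
  expect_lt(abs(mean(sub$choice > 0) - 0.5),
            3 * sqrt(0.25 / nrow(sub)))

  # long-duration opposite-direction trials: closed-form asymptote with
  # the kappaOpp drift and the lambda outcome mixture
  pm <- referenceParams("Dm_cued")
  desL <- trialDesign("cued_attention", coherenceSet = 0.512, pSame = 0,
                      durations = durationDist(5, 5, 1))
  trL <- simulateChoices(desL, pm, 6000, seed = 8)
  pos <- trL$coherence > 0
  phi <- logisticAbsorption(pm@kappaOpp * (0.512 + pm@C0), pm@B)
  want <- (1 - pm@lambda) * phi + pm@lambda * (1 - phi)
  got <- mean(trL$choice[pos] > 0)
  expect_lt(abs(got - want), 3 * sqrt(want * (1 - want) / sum(pos)))

  # model collapse: lambda = 0, kappaOpp = kappa makes same and opposite
  # conditions indistinguishable
  pc <- ddmParams(7.9, 0.74, -0.047, kappaOpp = 7.9, lambda = 0)
  trC <- simulateChoices(trialDesign("cued_attention"), pc, 10000, seed = 9)
  strong <- trC[trC$coherence == 0.512, ]
  k <- table(strong$relation, strong$choice > 0)
  expect_gt(prop.test(k)$p.value, 0.01)

  expect_error(simulateChoices(des, p0, 10, dt = 5e-3), "1 ms")
  expect_error(ddmParams(7.9, 0.74, lambda = 1.4), "lambda")
})

test_that("free-response trials get absorption time plus the direction Tnd", {
  pz <- referenceParams("Dz_fr")
  des <- trialDesign("variable_location_FR")
  tr <- simulateChoices(des, pz, 4000, seed = 10)
  expect_true(all(is.na(tr$t_dur_s)))
  expect_true(all(tr$rt_s >= pmin(pz@TndPos, pz@TndNeg)))
  # strong positive coherence: nearly all positive choices, RT floor TndPos
  st <- tr[tr$coherence == 0.256, ]
  expect_gt(mean(st$choice > 0), 0.98)
  # 0% coherence rewarded at one half
  zero <- tr[tr$coherence == 0, ]
  expect_lt(abs(mean(zero$rewarded) - 0.5), 3 * sqrt(0.25 / nrow(zero)))
})

test_that("Poisson spike generator has the right mean, Fano and rate profile", {
  spec <- rateSpec(20)
  spk <- simulateSpikeTrains(spec, 2000, window = c(0, 1), seed = 11)
  counts <- lengths(spikeTimes(spk))
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 2000))
  expect_gt(var(counts) / mean(counts), 0.9)
  expect_lt(var(counts) / mean(counts), 1.1)

  # PSTH is an unbiased rate estimate; agreement grows with trial count
  spec2 <- dm49RateSpec()
  tr2000 <- simulateSpikeTrains(spec2, 2000, seed = 12)
  rs <- buildPsth(tr2000, binWidth = 0.005)
  rate <- lipbeta:::trialRate(spec2, rs$t)
  expect_gt(cor(rs$rate, rate), 0.9)
  rs200 <- buildPsth(spikeEnsemble(spikeTimes(tr2000)[1:200],
                                   window = trialWindow(tr2000)),
                     binWidth = 0.005)
  expect_gt(cor(rs$rate, rate), cor(rs200$rate, rate))

  expect_error(rateSpec(-1), "baseline")
})

test_that("temporal jitter dephases the trial-averaged oscillation", {
  aligned <- simulateSpikeTrains(dm49RateSpec(jitterSD = 0), 500, seed = 13)
  jittered <- simulateSpikeTrains(dm49RateSpec(jitterSD = 0.030), 500,
                                  seed = 13)
  pA <- bandPowerPrePost(aligned)
  pJ <- bandPowerPrePost(jittered)
  expect_lt(pJ["post"], pA["post"])
})

test_that("LFP synthesis: transient identity, coupling, reproducibility", {
  tr <- gaborAtom(0.085, 0.05, 16, amplitude = 2)
  noiseless <- simulateLfp(20, tr, noiseAmp = 0, seed = 14)
  avg <- rowMeans(lfpMatrix(noiseless$lfp))
  expect_equal(avg, evalGabor(tr, sampleTimes(noiseless$lfp)),
               tolerance = 1e-12)

  spec <- rateSpec(40)
  spk <- simulateSpikeTrains(spec, 150, seed = 15)
  sim1 <- simulateLfp(150, tr, noiseAmp = 0.5, coupling = 1, spikes = spk,
                      seed = 16)
  sim2 <- simulateLfp(150, tr, noiseAmp = 0.5, coupling = 1, spikes = spk,
                      seed = 16)
  expect_identical(lfpMatrix(sim1$lfp), lfpMatrix(sim2$lfp))
  expect_identical(spikeTimes(sim1$spikes), spikeTimes(sim2$spikes))
  expect_error(simulateLfp(5, tr, coupling = 2), "coupling")
  expect_error(simulateLfp(5, tr, samplingRate = 100), "samplingRate")
})
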