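# Fokker-Planck solution, choice/RT likelihoods, fitting and model
# comparison.

paramSets <- list(
  ddmParams(7.9, 0.74, -0.047),
  ddmParams(17.9, 0.44, -0.011),
  ddmParams(10.3, 0.64, 0.013),
  ddmParams(17.1, 0.74, -0.02),
  ddmParams(3.0, 1.2, 0.1),
  ddmParams(40, 0.3, 0))

test_that("every solve conserves probability and refinement tightens it", {
  for (p in paramSets) {
    sol <- solveBoundedDiffusion(p, C = 0.128, tDur = 0.8)
    expect_lt(conservationError(sol), 1e-3)
  }
  p <- paramSets[[1]]
  coarse <- solveBoundedDiffusion(p, C = 0.512, tDur = 0.5, dt = 2e-3,
                                  nv = 120, normTol = 0.1)
  fine <- solveBoundedDiffusion(p, C = 0.512, tDur = 0.5, dt = 5e-4,
                                nv = 500)
  expect_lt(conservationError(fine), conservationError(coarse))
  expect_error(solveBoundedDiffusion(p, C = 0.512, tDur = 0.5,
                                     dt = 5e-3, nv = 40, normTol = 1e-6),
               "refine")
})

test_that("zero drift gives a symmetric solution", {
  p <- ddmParams(5, 0.7, C0 = 0.05)
  sol <- solveBoundedDiffusion(p, C = -0.05, tDur = 0.5)
  n <- length(sol@t)
  expect_lt(abs(sol@FPlus[n] - sol@FMinus[n]), 1e-6)
  expect_lt(max(abs(sol@fUn - rev(sol@fUn))), 1e-6)
})

test_that("long-duration choice probability matches the logistic closed form", {
  cases <- list(c(2.0, 0.74), c(3.7, 0.74), c(7.9, 0.44), c(1.5, 1.0),
                c(5.5, 0.6))
  for (cs in cases) {
    a <- cs[1]; B <- cs[2]
    p <- ddmParams(kappa = a, B = B, C0 = 0)
    sol <- solveBoundedDiffusion(p, C = 1, tDur = 6)
    cp <- choiceProbability(sol, "single")
    expect_lt(abs(cp$pPlus - logisticAbsorption(a, B)), 1e-3)
  }
})

test_that("time-resolved absorption matches the spectral series oracle", {
  for (cs in list(c(2.5, 0.74), c(-1.2, 0.6), c(0, 0.5))) {
    a <- cs[1]; B <- cs[2]
    m <- lipbeta:::fp_march(a, B, 0.4, 5e-4, 500)
    n <- length(m$t)
    expect_lt(abs(m$FPlus[n] - seriesAbsorbed(0.4, a, B, TRUE)), 1e-3)
    expect_lt(abs(m$FMinus[n] - seriesAbsorbed(0.4, a, B, FALSE)), 1e-3)
  }
})

test_that("choice probability applies the wrong-patch mixture", {
  p <- referenceParams("Dm_cued")
  sol <- solveBoundedDiffusion(p, C = 0.512, condition = "opposite",
                               tDur = 2)
  pt <- choiceProbability(sol, "opposite", lambda = 0)$pTildePlus
  for (lam in c(0, 0.029, 1)) {
    cp <- choiceProbability(sol, "opposite", lambda = lam)
    expect_equal(cp$pPlus, (1 - lam) * pt + lam * (1 - pt),
                 tolerance = 1e-12)
  }
  expect_warning(choiceProbability(sol, "same", lambda = 0.3), "ignored")
})

test_that("RT densities shift by the direction-specific non-decision time", {
  p <- ddmParams(10, 0.6, C0 = 0, TndPos = 0, TndNeg = 0)
  d0 <- rtDensity(p, C = 0.2, tMax = 3)
  sol <- solveBoundedDiffusion(p, C = 0.2, tDur = 3)
  expect_equal(d0$pos$f, sol@fPlus, tolerance = 1e-12)
  expect_equal(d0$pos$t, sol@t, tolerance = 1e-12)

  # symmetric drift: the two choices have identical RT densities
  psym <- ddmParams(10, 0.6, C0 = -0.1, TndPos = 0.3, TndNeg = 0.3)
  ds <- rtDensity(psym, C = 0.1, tMax = 2)
  expect_lt(max(abs(ds$pos$f - ds$neg$f)), 1e-6)

  # deterministic-drift limit: mean RT near Tnd + B/drift (strong drift
  # needs a finer march for the conservation tolerance)
  pf <- ddmParams(17.1, 0.74, C0 = 0, TndPos = 0.33, TndNeg = 0.34)
  df <- rtDensity(pf, C = 0.9, tMax = 2, dt = 2e-4, nv = 800)
  dt <- diff(df$pos$t[1:2])
  m <- sum(df$pos$t * df$pos$f * dt) / sum(df$pos$f * dt)
  a <- 17.1 * 0.9
  expect_equal(m, 0.33 + meanAbsorptionTime(a, 0.74), tolerance = 0.02)
  expect_error(rtDensity(ddmParams(10, 0.6), C = 0.1), "Tnd")
})

test_that("negative log-likelihood has its analytic values and nesting", {
  # one chance-level trial contributes ln 2
  tr1 <- data.frame(coherence = 0, relation = "single", choice = 1,
                    t_dur_s = 0.5)
  expect_equal(negLogLikDDM(tr1, ddmParams(8, 0.7, C0 = 0), "base"),
               log(2), tolerance = 1e-4)

  # a block of identical trials reduces to binomial cross-entropy of the
  # condition's choice probability
  p <- ddmParams(7.9, 0.74, -0.047)
  trn <- data.frame(coherence = 0.128, relation = "single",
                    choice = rep(c(1, -1), c(70, 30)),
                    t_dur_s = 0.4)
  sol <- solveBoundedDiffusion(p, 0.128, "single", 0.4, dt = 1e-3)
  pp <- choiceProbability(sol, "single")$pPlus
  expect_equal(negLogLikDDM(trn, p, "base", dt = 1e-3),
               -(70 * log(pp) + 30 * log(1 - pp)), tolerance = 1e-6)

  # duplicated data doubles the likelihood
  expect_equal(negLogLikDDM(rbind(trn, trn), p, "base", dt = 1e-3),
               2 * negLogLikDDM(trn, p, "base", dt = 1e-3),
               tolerance = 1e-10)

  # nesting: full with lambda 0 and kappaOpp = kappa equals base, and a
  # table without relation labels is treated as same-direction
  des <- trialDesign("cued_attention")
  tr <- simulateChoices(des, referenceParams("Dm_cued"), 400, seed = 21)
  pFull <- ddmParams(7.9, 0.74, -0.047, kappaOpp = 7.9, lambda = 0)
  expect_equal(negLogLikDDM(tr, pFull, "full"),
               negLogLikDDM(tr, ddmParams(7.9, 0.74, -0.047), "base"))
  trNoRel <- tr[, setdiff(names(tr), "relation")]
  expect_equal(negLogLikDDM(trNoRel, pFull, "full"),
               negLogLikDDM(trNoRel, ddmParams(7.9, 0.74, -0.047), "base"))
  expect_error(negLogLikDDM(tr[, c("coherence", "choice")], p, "base"),
               "t_dur_s")
})

test_that("maximum likelihood recovers what choice-only data identify", {
  # in a controlled-duration design the drift gain and bias are well
  # identified from choices alone; the bound is only weakly constrained
  # (its recovery is exercised on response-time data below)
  des <- trialDesign("variable_location")
  truth <- referenceParams("Dm_var")
  tr <- simulateChoices(des, truth, 4000, seed = 22)
  fit <- fitDDM(tr, "base", starts = 3, seed = 23, dt = 2e-3, nv = 250)
  p <- fittedParams(fit)
  expect_lt(abs(p@kappa - truth@kappa) / truth@kappa, 0.15)
  expect_lt(abs(p@C0 - truth@C0), 0.02)
  # the optimum found is no worse than the generating parameters
  expect_lte(-fit@logLik,
             negLogLikDDM(tr, truth, "base", dt = 2e-3, nv = 250))
  expect_equal(bic(fit), 3 * log(4000) - 2 * fit@logLik, tolerance = 1e-8)
})

test_that("BIC comparison prefers the generating model class", {
  des <- trialDesign("cued_attention")
  # misrouting present: the full model should win despite its penalty
  gen <- ddmParams(10, 0.7, 0, kappaOpp = 6, lambda = 0.05)
  tr <- simulateChoices(des, gen, 6000, seed = 24)
  fb <- fitDDM(tr, "base", starts = 2, seed = 25, dt = 2e-3, nv = 250)
  ff <- fitDDM(tr, "full", starts = 2, seed = 25, dt = 2e-3, nv = 250)
  cmp <- compareDDM(fb, ff)
  expect_identical(attr(cmp, "preferred"), "full")
  expect_gt(cmp$deltaBIC[cmp$variant == "base"], 0)

  # no misrouting: the base model's penalty advantage should win
  gen0 <- ddmParams(10, 0.7, 0, kappaOpp = 10, lambda = 0)
  tr0 <- simulateChoices(des, gen0, 6000, seed = 26)
  fb0 <- fitDDM(tr0, "base", starts = 2, seed = 27, dt = 2e-3, nv = 250)
  ff0 <- fitDDM(tr0, "full", starts = 2, seed = 27, dt = 2e-3, nv = 250)
  cmp0 <- compareDDM(fb0, ff0)
  expect_identical(attr(cmp0, "preferred"), "base")

  # identical fits differ by zero
  expect_equal(compareDDM(fb, fb)$deltaBIC, c(0, 0))
  expect_error(compareDDM(fb, fitDDM(tr0[1:500, ], "base", starts = 1,
                                     seed = 1, dt = 2e-3, nv = 250)),
               "identical trial set")
})

test_that("path-simulated choice fractions agree with the Fokker-Planck solver", {
  # the two independent routes to choice probability - Euler paths and
  # the Crank-Nicolson densities - across all coherences and both
  # cued-task conditions at a fixed viewing duration
  p <- referenceParams("Dm_cued")
  nPer <- 5000
  tDur <- 0.4
  for (cond in c("same", "opposite")) {
    for (C in c(0, 0.032, 0.064, 0.128, 0.256, 0.512)) {
      des <- trialDesign("cued_attention", coherenceSet = C,
                        pSame = if (cond == "same") 1 else 0,
                        durations = durationDist(tDur, tDur, 0.1))
      tr <- simulateChoices(des, p, nPer,
                            seed = 9100 + round(1000 * C) +
                              (cond == "same"))
      pos <- tr$coherence > 0 | (C == 0)
      sol <- solveBoundedDiffusion(p, C, cond, tDur, dt = 1e-3)
      lam <- if (cond == "opposite") p@lambda else 0
      want <- choiceProbability(sol, cond, lambda = lam)$pPlus
      got <- mean(tr$choice[pos] > 0)
      se <- sqrt(want * (1 - want) / sum(pos))
      expect_lt(abs(got - want), 3 * se + 0.003)
    }
  }
})

test_that("free-response likelihood identifies kappa and the Tnds", {
  des <- trialDesign("variable_location_FR")
  truth <- referenceParams("Dz_fr")
  tr <- simulateChoices(des, truth, 3000, seed = 28)
  fit <- fitDDM(tr, starts = 3, seed = 29, dt = 2e-3, nv = 250)
  p <- fittedParams(fit)
  expect_identical(fit@variant, "fr")
  expect_lt(abs(p@kappa - truth@kappa) / truth@kappa, 0.15)
  expect_lt(abs(p@TndPos - truth@TndPos), 0.05)
  expect_lt(abs(p@TndNeg - truth@TndNeg), 0.05)
})
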