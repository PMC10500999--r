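# End-to-end synthetic experiment orchestration: generate behaviour,
# spikes and LFP; fit the diffusion model; quantify oscillations; run the
# statistics; and emit a self-contained report.

#' Configuration for a synthetic experiment run
#'
#' All stages are keyed to the master seed through [stageSeed()], so any
#' stage can be reproduced in isolation.  Defaults describe a small but
#' complete experiment: a cued-attention behavioural dataset generated at
#' the published Monkey Dm parameters, one strongly oscillating unit with
#' the canonical 16.7 Hz transient, and a matching LFP with spike-trough
#' coupling.
#'
#' @param seed master integer seed.
#' @param nTrials behavioural trials to simulate.
#' @param params generating [DDMParams-class].
#' @param design a [trialDesign()].
#' @param fit logical: fit the diffusion model?
#' @param fitVariant,fitStarts fitting controls (see [fitDDM()]).
#' @param fitDt,fitNv likelihood grid controls.
#' @param nOscTrials spike/LFP trials for the oscillation stages.
#' @param rate a [rateSpec()] for the simulated unit.
#' @param lfpNoise pink-noise RMS amplitude of the LFP.
#' @param coupling spike-LFP coupling in \[0, 1\].
#' @param powerConfig an [mpPowerConfig()] for the oscillation analyses.
#' @return list of class `"runConfig"`.
#' @export
runConfig <- function(seed = 1, nTrials = 2000,
                      params = referenceParams("Dm_cued"),
                      design = trialDesign("cued_attention"),
                      fit = TRUE, fitVariant = "full", fitStarts = 2,
                      fitDt = 2e-3, fitNv = 200,
                      nOscTrials = 150, rate = dm49RateSpec(),
                      lfpNoise = 0.3, coupling = 0.6,
                      powerConfig = fastPowerConfig()) {
  structure(list(seed = seed, nTrials = nTrials, params = params,
                 design = design, fit = fit, fitVariant = fitVariant,
                 fitStarts = fitStarts, fitDt = fitDt, fitNv = fitNv,
                 nOscTrials = nOscTrials, rate = rate,
                 lfpNoise = lfpNoise, coupling = coupling,
                 powerConfig = powerConfig),
            class = "runConfig")
}

# stable FNV-1a style hash of the deparsed configuration, so reports can
# be matched to the exact configuration that produced them
configHash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (k in utf8ToInt(txt)) h <- (h * 131 + k) %% 2147483647
  sprintf("%08x", as.integer(h))
}

paramsToList <- function(p) {
  list(kappa = p@kappa, B = p@B, C0 = p@C0, kappaOpp = p@kappaOpp,
       lambda = p@lambda, TndPos = p@TndPos, TndNeg = p@TndNeg)
}

#' Run a synthetic experiment end to end
#'
#' Stages: behaviour generation, diffusion-model fit, spike and LFP
#' generation, Matching-Pursuit band power, pre/post statistics and
#' spike-field alignment.  Each stage draws its seed from the master seed
#' by name, and a rerun with the same configuration reproduces the same
#' numbers.  With `outDir` set, the trial table, spike and LFP ensembles
#' and the JSON report are written there.
#'
#' @param config a [runConfig()].
#' @param outDir optional output directory (created if needed).
#' @return list of class `"runReport"`.
#' @export
runExperiment <- function(config = runConfig(), outDir = NULL) {
  stopifnot(inherits(config, "runConfig"))
  report <- list(seed = config$seed,
                 configHash = configHash(config),
                 generating = paramsToList(config$params))

  trials <- simulateChoices(config$design, config$params, config$nTrials,
                            seed = stageSeed(config$seed, "behavior"))
  report$behavior <- list(
    nTrials = nrow(trials),
    pPositiveByCoherence = tapply(trials$choice > 0, trials$coherence,
                                  mean))

  if (config$fit) {
    fitObj <- fitDDM(trials, variant = config$fitVariant,
                     starts = config$fitStarts,
                     seed = stageSeed(config$seed, "fit"),
                     dt = config$fitDt, nv = config$fitNv)
    report$fit <- list(params = paramsToList(fitObj@params),
                       logLik = fitObj@logLik, bic = fitObj@bic,
                       variant = fitObj@variant)
  }

  spk <- simulateSpikeTrains(config$rate, config$nOscTrials,
                             window = config$powerConfig$window,
                             seed = stageSeed(config$seed, "spikes"))
  pw <- bandPowerPrePost(spk, config$powerConfig)
  nb <- max(2L, floor(config$nOscTrials / 50))
  blocks <- perUnitBlockTest(spk, blockSize = floor(length(spk@spikes) / nb),
                             config = config$powerConfig)
  report$oscillation <- list(pre = unname(pw["pre"]),
                             post = unname(pw["post"]),
                             postPreRatio = unname(pw["post"] / pw["pre"]),
                             blockTestP = blocks$p)

  lfpTransient <- config$rate$transient
  if (is.null(lfpTransient))
    lfpTransient <- gaborAtom(0.085, 0.08, 16.7, amplitude = 0)
  lfpSim <- simulateLfp(config$nOscTrials, lfpTransient,
                        noiseAmp = config$lfpNoise,
                        window = config$powerConfig$window,
                        coupling = config$coupling, spikes = spk,
                        seed = stageSeed(config$seed, "lfp"))
  dec <- matchingPursuit(lfpSim$lfp)
  sel <- selectOscillatoryLfp(dec, band = config$powerConfig$band,
                              epoch = config$powerConfig$epochPost)
  report$spikeField <- list(lfpSelected = sel$selected)
  if (sel$selected) {
    epoch <- config$powerConfig$epochPost
    st <- unlist(spikeTimes(lfpSim$spikes), use.names = FALSE)
    st <- st[inHalfOpen(st, epoch)]
    if (length(st) >= 100) {
      ph <- assignSpikePhases(st, sel$atom)
      hist <- correctedPhaseHistogram(ph, sel$atom, epoch = epoch,
                                      samplingRate =
                                        lfpSim$lfp@samplingRate)
      report$spikeField$nSpikes <- length(st)
      report$spikeField$modalPhaseDeg <-
        hist$edges[which.max(hist$ratio)] + 5
      report$spikeField$ksP <- hist$ks$p
    }
  }

  report$versions <- list(lipbeta = as.character(
    utils::packageVersion("lipbeta")))
  class(report) <- "runReport"

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTrialTable(trials, file.path(outDir, "trials.csv"))
    writeSpikeEnsemble(spk, file.path(outDir, "spikes.csv"))
    writeLfpEnsemble(lfpSim$lfp, file.path(outDir, "lfp.csv"))
    writeReport(report, outDir)
  }
  report
}

#' Write a run report
#'
#' JSON (machine-readable, re-runnable: the seed and generating parameters
#' are embedded) and optionally a short markdown summary.
#'
#' @param report a `"runReport"` from [runExperiment()].
#' @param dir output directory.
#' @param format `"json"`, `"markdown"`, or both.
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, dir, format = c("json", "markdown")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(unclass(report), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("markdown" %in% format) {
    p <- file.path(dir, "report.md")
    lines <- c("# Synthetic experiment report", "",
               sprintf("Master seed: %d", report$seed), "")
    if (!is.null(report$fit)) {
      f <- report$fit$params
      g <- report$generating
      lines <- c(lines, "## Diffusion-model fit", "",
                 sprintf("- kappa: fitted %.3f (generating %.3f)",
                         f$kappa, g$kappa),
                 sprintf("- B: fitted %.3f (generating %.3f)", f$B, g$B),
                 sprintf("- C0: fitted %.4f (generating %.4f)",
                         f$C0, g$C0), "")
    } else {
      lines <- c(lines, "## Diffusion-model fit", "", "- not run", "")
    }
    if (!is.null(report$oscillation)) {
      o <- report$oscillation
      lines <- c(lines, "## Oscillation band power", "",
                 sprintf("- pre %.4g, post %.4g (ratio %.3g)",
                         o$pre, o$post, o$postPreRatio),
                 sprintf("- per-unit block test p = %.3g", o$blockTestP),
                 "")
    }
    if (!is.null(report$spikeField)) {
      s <- report$spikeField
      lines <- c(lines, "## Spike-field alignment", "",
                 sprintf("- LFP selected: %s", s$lfpSelected),
                 if (!is.null(s$modalPhaseDeg))
                   sprintf("- modal corrected phase: %g deg (KS p = %.3g)",
                           s$modalPhaseDeg, s$ksP), "")
    }
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
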