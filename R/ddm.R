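# Bounded drift-diffusion model: Fokker-Planck solution, choice and RT
# likelihoods, maximum-likelihood fitting and BIC model comparison.

driftGain <- function(params, condition) {
  if (condition == "opposite" && !is.na(params@kappaOpp))
    params@kappaOpp else params@kappa
}

# variant -> effective misrouting parameters used by the likelihood
effectiveParams <- function(params, variant) {
  p <- params
  if (variant %in% c("base", "kopp_only") || is.na(p@lambda))
    p@lambda <- 0
  if (variant %in% c("base", "lambda_only") || is.na(p@kappaOpp))
    p@kappaOpp <- p@kappa
  p
}

#' Solve the Fokker-Planck equation for the bounded diffusion
#'
#' Crank-Nicolson finite differences with absorbing Dirichlet boundaries at
#' \eqn{\pm B}, a delta initial condition at V = 0 and unit diffusion
#' coefficient.  The drift is `kappa * (C + C0)` for same-direction and
#' single-patch trials and `kappaOpp * (C + C0)` for opposite-direction
#' trials.  The returned solution carries the upper/lower absorption-time
#' densities and the unabsorbed density at `tDur`; the three components
#' sum to one (checked to the stated tolerance).
#'
#' @param params a [DDMParams-class] object.
#' @param C signed coherence of the cued patch.
#' @param condition `"same"`, `"single"` or `"opposite"`.
#' @param tDur viewing duration (s), positive.
#' @param dt marching time step (s); 0.5 ms by default.
#' @param nv number of evidence-grid intervals over (-B, B); 500 by default
#'   (grid step B/250).
#' @param normTol tolerance for the probability-conservation check.
#' @return an [FPSolution-class] object.
#' @examples
#' sol <- solveBoundedDiffusion(ddmParams(7.9, 0.74), C = 0.128,
#'                              tDur = 0.5)
#' choiceProbability(sol, "same")
#' @export
solveBoundedDiffusion <- function(params, C, condition = c("same", "single",
                                                           "opposite"),
                                  tDur, dt = 5e-4, nv = 500,
                                  normTol = 1e-3) {
  stopifnot(is(params, "DDMParams"))
  validObject(params)
  condition <- match.arg(condition)
  if (tDur <= 0) stop("tDur must be positive")
  a <- driftGain(params, condition) * (C + params@C0)
  m <- fp_march(a, params@B, tDur, dt, as.integer(nv))
  n <- length(m$t)
  err <- abs(m$FPlus[n] + m$FMinus[n] + m$survTot[n] - 1)
  if (err > normTol)
    stop(sprintf(paste("probability conservation violated (|error| = %.2e);",
                       "refine the grid (smaller dt or larger nv)"), err))
  new("FPSolution", t = m$t, v = m$v, fPlus = m$fPlus, fMinus = m$fMinus,
      FPlus = m$FPlus, FMinus = m$FMinus, survPos = m$survPos,
      survTot = m$survTot, fUn = pmax(m$pFinal, 0), drift = a,
      B = m$B, h = m$h)
}

#' Choice probability from a Fokker-Planck solution
#'
#' The model probability of a positive choice at viewing duration `tDur`
#' is the probability absorbed at the upper bound plus the unabsorbed mass
#' with positive integrated evidence.  On opposite-direction trials the
#' wrong-patch mixture applies:
#' \eqn{P_+ = (1-\lambda)\tilde P_+ + \lambda \tilde P_-}.
#'
#' @param sol an [FPSolution-class] object.
#' @param condition `"same"`, `"single"` or `"opposite"`.
#' @param lambda wrong-patch fraction (used only for `"opposite"`; a
#'   non-zero value for other conditions is ignored with a warning).
#' @param tDur read-out time (s); defaults to the end of the solution grid.
#' @return list with `pTildePlus` (pre-misrouting), `pPlus` (observed) and
#'   `condition`.
#' @export
choiceProbability <- function(sol, condition = c("same", "single",
                                                 "opposite"),
                              lambda = 0, tDur = NULL) {
  stopifnot(is(sol, "FPSolution"))
  condition <- match.arg(condition)
  n <- length(sol@t)
  pt <- if (is.null(tDur)) sol@FPlus[n] + sol@survPos[n]
  else stats::approx(sol@t, sol@FPlus + sol@survPos, tDur, rule = 2)$y
  pt <- min(max(pt, 0), 1)
  if (condition != "opposite") {
    if (!identical(lambda, 0) && !is.na(lambda) && lambda != 0)
      warning("lambda is ignored for non-opposite conditions")
    pp <- pt
  } else {
    if (is.na(lambda)) lambda <- 0
    pp <- (1 - lambda) * pt + lambda * (1 - pt)
  }
  list(pTildePlus = pt, pPlus = pp, condition = condition)
}

#' Response-time densities for the free-response task
#'
#' The RT density for each choice is the corresponding bound
#' absorption-time density shifted by that direction's non-decision time
#' expectation (modeled as a deterministic shift).
#'
#' @param params a [DDMParams-class] with `TndPos`/`TndNeg` set (0 allowed).
#' @param C signed coherence.
#' @param tMax decision-time horizon for the solve (s).
#' @param dt,nv grid controls as in [solveBoundedDiffusion()].
#' @return list with components `pos` and `neg`, each `list(t, f)` giving
#'   the RT grid (s) and density, plus `pChoice` with the two choice
#'   probabilities at the horizon.
#' @export
rtDensity <- function(params, C, tMax = 5, dt = 5e-4, nv = 500) {
  stopifnot(is(params, "DDMParams"))
  if (is.na(params@TndPos) || is.na(params@TndNeg))
    stop("rtDensity needs TndPos and TndNeg (free-response parameters)")
  sol <- solveBoundedDiffusion(params, C, "single", tDur = tMax,
                               dt = dt, nv = nv)
  n <- length(sol@t)
  list(pos = list(t = sol@t + params@TndPos, f = sol@fPlus),
       neg = list(t = sol@t + params@TndNeg, f = sol@fMinus),
       pChoice = c(pos = sol@FPlus[n], neg = sol@FMinus[n]))
}

#' Negative log-likelihood of a trial table under the diffusion model
#'
#' Controlled-duration trials contribute the Bernoulli likelihood of the
#' observed choice at the trial's exact viewing duration (one
#' Fokker-Planck march per coherence-by-condition group caches the
#' read-outs for all durations).  Free-response trials (detected by a
#' non-missing `rt_s` column) contribute the probability of the observed
#' choice and of the RT falling in its 10 ms bin after removing the
#' direction-specific non-decision time.  A probability floor keeps the
#' objective finite everywhere in the legal parameter domain.
#'
#' @param trials trial table as produced by [simulateChoices()] (columns
#'   coherence, relation, choice, and t_dur_s or rt_s).
#' @param params a [DDMParams-class] object.
#' @param variant `"base"`, `"lambda_only"`, `"kopp_only"` or `"full"`;
#'   the variant fixes the unused misrouting parameters at their nested
#'   values (lambda = 0, kappaOpp = kappa).
#' @param dt marching step (s) for the likelihood solves.
#' @param nv evidence-grid intervals.
#' @param rtBin RT bin width (s) for free-response density evaluation.
#' @param probFloor per-trial probability floor.
#' @return the scalar negative log-likelihood.
#' @export
negLogLikDDM <- function(trials, params, variant = c("full", "base",
                                                     "lambda_only",
                                                     "kopp_only"),
                         dt = 1e-3, nv = 500, rtBin = 0.01,
                         probFloor = 1e-6) {
  variant <- match.arg(variant)
  stopifnot(is(params, "DDMParams"))
  p <- effectiveParams(params, variant)
  fr <- "rt_s" %in% names(trials) && all(!is.na(trials$rt_s))
  if (!fr && (!"t_dur_s" %in% names(trials) || anyNA(trials$t_dur_s)))
    stop("trials must supply t_dur_s (controlled duration) or rt_s (FR)")
  relation <- if ("relation" %in% names(trials)) trials$relation
  else rep("same", nrow(trials))
  pos <- trials$choice > 0

  if (fr) {
    if (is.na(p@TndPos) || is.na(p@TndNeg))
      stop("free-response likelihood needs TndPos and TndNeg")
    nll <- 0
    for (C in unique(trials$coherence)) {
      idx <- trials$coherence == C
      rt <- trials$rt_s[idx]
      posi <- pos[idx]
      td <- rt - ifelse(posi, p@TndPos, p@TndNeg)
      tMax <- max(max(td, 0.02) + rtBin, 0.05)
      a <- p@kappa * (C + p@C0)
      m <- fp_march(a, p@B, tMax, dt, as.integer(nv))
      kLo <- pmax(floor(td / rtBin), 0) * rtBin
      Fp <- function(tq) stats::approx(m$t, m$FPlus, pmin(pmax(tq, 0),
                                       max(m$t)), rule = 2)$y
      Fm <- function(tq) stats::approx(m$t, m$FMinus, pmin(pmax(tq, 0),
                                       max(m$t)), rule = 2)$y
      pr <- ifelse(posi, Fp(kLo + rtBin) - Fp(kLo),
                   Fm(kLo + rtBin) - Fm(kLo))
      pr[td < 0] <- 0
      nll <- nll - sum(log(pmax(pr, probFloor)))
    }
    return(nll)
  }

  grpGain <- ifelse(relation == "opposite", "opp", "cued")
  key <- paste(grpGain, trials$coherence)
  nll <- 0
  for (k in unique(key)) {
    idx <- key == k
    C <- trials$coherence[idx][1]
    opp <- grpGain[idx][1] == "opp"
    gain <- if (opp) p@kappaOpp else p@kappa
    a <- gain * (C + p@C0)
    tdur <- trials$t_dur_s[idx]
    m <- fp_march(a, p@B, max(tdur) + dt, dt, as.integer(nv))
    pt <- stats::approx(m$t, m$FPlus + m$survPos, tdur, rule = 2)$y
    pt <- pmin(pmax(pt, 0), 1)
    pp <- if (opp) (1 - p@lambda) * pt + p@lambda * (1 - pt) else pt
    pr <- ifelse(pos[idx], pp, 1 - pp)
    nll <- nll - sum(log(pmax(pr, probFloor)))
  }
  nll
}

# parameter transforms: unconstrained optimizer coordinates <-> box bounds
# kappa, kappaOpp in (0, 100]; B in (0, 5]; C0 in [-0.3, 0.3];
# lambda in [0, 0.5]; Tnd in [0, 1]
ddmTransforms <- function(variant, fr) {
  tr <- list(
    kappa = list(fwd = function(x) log(x), inv = function(z)
      pmin(exp(z), 100)),
    B = list(fwd = function(x) log(x), inv = function(z) pmin(exp(z), 5)),
    C0 = list(fwd = function(x) atanh(pmin(pmax(x / 0.3, -0.999), 0.999)),
              inv = function(z) 0.3 * tanh(z)),
    kappaOpp = list(fwd = function(x) log(x), inv = function(z)
      pmin(exp(z), 100)),
    lambda = list(fwd = function(x) stats::qlogis(pmin(pmax(x / 0.5, 1e-6),
                                                       1 - 1e-6)),
                  inv = function(z) 0.5 * stats::plogis(z)),
    TndPos = list(fwd = function(x) stats::qlogis(pmin(pmax(x, 1e-6),
                                                       1 - 1e-6)),
                  inv = function(z) stats::plogis(z)),
    TndNeg = list(fwd = function(x) stats::qlogis(pmin(pmax(x, 1e-6),
                                                       1 - 1e-6)),
                  inv = function(z) stats::plogis(z)))
  names <- if (fr) c("kappa", "B", "C0", "TndPos", "TndNeg")
  else switch(variant,
              base = c("kappa", "B", "C0"),
              lambda_only = c("kappa", "B", "C0", "lambda"),
              kopp_only = c("kappa", "B", "C0", "kappaOpp"),
              full = c("kappa", "B", "C0", "kappaOpp", "lambda"))
  tr[names]
}

vecToParams <- function(theta, tr) {
  vals <- mapply(function(t, z) t$inv(z), tr, theta)
  do.call(ddmParams, as.list(vals))
}

#' Fit the diffusion model by maximum likelihood
#'
#' Derivative-free simplex search (Nelder-Mead on transformed coordinates
#' respecting the box bounds) from multiple random starts; the best start
#' is polished with a longer run and reported.  Free-response data
#' (non-missing `rt_s`) are fitted with the choice-and-RT likelihood and
#' direction-specific non-decision times instead of the misrouting
#' parameters.
#'
#' @param trials trial table (see [negLogLikDDM()]); at least 200 trials
#'   recommended.
#' @param variant model variant, as in [negLogLikDDM()].
#' @param starts number of random starts.
#' @param seed integer seed for the starts.
#' @param dt,nv likelihood grid controls; the 1 ms default marching step
#'   halves fit time relative to the solver default with negligible bias.
#' @param coarseMaxit,polishMaxit simplex iteration budgets for the
#'   exploratory starts and the final polish.
#' @return a [DDMFit-class] object.
#' @export
fitDDM <- function(trials, variant = c("full", "base", "lambda_only",
                                       "kopp_only"),
                   starts = 8, seed = 1, dt = 1e-3, nv = 500,
                   coarseMaxit = 200, polishMaxit = 600) {
  variant <- match.arg(variant)
  fr <- "rt_s" %in% names(trials) && all(!is.na(trials$rt_s))
  tr <- ddmTransforms(variant, fr)
  objAt <- function(dtUse, nvUse) function(theta) {
    p <- vecToParams(theta, tr)
    negLogLikDDM(trials, p, variant = if (fr) "base" else variant,
                 dt = dtUse, nv = nvUse)
  }
  # exploratory starts run on a half-resolution grid; the winner is
  # polished (and all starts re-scored) at the full likelihood grid
  objCoarse <- objAt(2 * dt, max(100, floor(nv / 2)))
  obj <- objAt(dt, nv)
  drawStart <- function() {
    s <- c(kappa = exp(runif(1, log(2), log(40))),
           B = runif(1, 0.3, 1.5), C0 = runif(1, -0.1, 0.1),
           kappaOpp = exp(runif(1, log(2), log(40))),
           lambda = runif(1, 0.005, 0.2),
           TndPos = runif(1, 0.15, 0.6), TndNeg = runif(1, 0.15, 0.6))
    mapply(function(t, v) t$fwd(v), tr, s[names(tr)])
  }
  withSeed(seed, {
    runs <- vector("list", starts)
    for (i in seq_len(starts)) {
      th0 <- drawStart()
      o <- stats::optim(th0, objCoarse, method = "Nelder-Mead",
                        control = list(maxit = coarseMaxit,
                                       reltol = 1e-7))
      runs[[i]] <- o
    }
    nlls <- vapply(runs, `[[`, numeric(1), "value")
    win <- which.min(nlls)
    best <- stats::optim(runs[[win]]$par, obj, method = "Nelder-Mead",
                         control = list(maxit = polishMaxit,
                                        reltol = 1e-9))
    pars <- vecToParams(best$par, tr)
    n <- nrow(trials)
    k <- length(tr)
    ll <- -best$value
    new("DDMFit", params = pars, variant = if (fr) "fr" else variant,
        logLik = ll, nTrials = as.integer(n), nParams = as.integer(k),
        bic = k * log(n) - 2 * ll,
        convergence = list(startNLL = nlls, winner = win, seed = seed,
                           counts = best$counts,
                           convergence = best$convergence))
  })
}

#' Compare fitted models by BIC
#'
#' Reports each fit's BIC and the difference from the best (preferred)
#' model; the absolute difference is the conventional strength of support
#' (Bayes factor greater than one).
#'
#' @param ... two or more [DDMFit-class] objects fitted on the identical
#'   trial set.
#' @return data.frame with variant, nParams, logLik, BIC and deltaBIC
#'   (relative to the preferred model), with the preferred variant in
#'   attribute `"preferred"`.
#' @export
compareDDM <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !is(fits[[1]], "DDMFit"))
    fits <- fits[[1]]
  stopifnot(length(fits) >= 2, all(vapply(fits, is, logical(1), "DDMFit")))
  ns <- vapply(fits, function(f) f@nTrials, integer(1))
  if (length(unique(ns)) != 1L)
    stop("fits must be computed on the identical trial set")
  tab <- data.frame(
    variant = vapply(fits, function(f) f@variant, character(1)),
    nParams = vapply(fits, function(f) f@nParams, integer(1)),
    logLik = vapply(fits, function(f) f@logLik, numeric(1)),
    BIC = vapply(fits, function(f) f@bic, numeric(1)))
  tab$deltaBIC <- tab$BIC - min(tab$BIC)
  attr(tab, "preferred") <- tab$variant[which.min(tab$BIC)]
  tab
}
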