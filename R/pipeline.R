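## Orchestration: a validated run configuration, the staged analysis
## pipeline (simulate/ingest -> tICA -> cluster -> MSM -> validate -> lump
## -> TPT/MFPT -> report), and A/B run comparison. All stochastic stages
## derive their seeds from the master seed and the stage name.

#' Build a validated pipeline run configuration
#'
#' Scale-free defaults mirror the published analysis protocol (5 GMRQ
#' splits at 1:1, 12-state residence test, 10 MCMC chains of 1e5 steps with
#' 20% burn-in, 35 degree kink threshold, 0.35 nm / 30 degree hydrogen-bond
#' criterion, 1000 bootstrap resamples). The time-scaled parameters default
#' per input mode: external trajectories get the published MD-scale values
#' (tICA lag 2 time units, MSM lag 45 time units, 800 microstates), while
#' synthetic mode defaults to values matched to the diffusive time unit of
#' the default landscape (tICA lag 0.1, MSM lag 0.25, 150 microstates; see
#' the methods vignette for the calibration). Times are physical units,
#' converted to frames via the trajectory frame interval (rounded to the
#' nearest frame with a warning above 1% error).
#'
#' @param inputMode `"synthetic"` or `"external"`.
#' @param landscape a [Landscape-class] for synthetic mode (default
#'   triple-well).
#' @param nTrajectories,nSteps,dt,D,kT,stride Langevin settings for
#'   synthetic mode.
#' @param trajectories list of [FeatureTrajectory-class] for external mode.
#' @param ticaLag,msmLag lags in time units.
#' @param nClusters number of k-centers microstates.
#' @param nMacro macrostate count, or `NULL` to choose by eigenvalue gap.
#' @param nComponents tICs kept for clustering.
#' @param gmrq logical: run GMRQ cross-validation over `gmrqGrid`.
#' @param gmrqGrid grid for [gmrqCrossValidate()] (default: the configured
#'   cluster count versus a quarter of it).
#' @param residence logical: run the residence-probability test.
#' @param nTop,residenceMultiples residence test settings.
#' @param nChains,nStepsMCMC,burnInFraction MCMC observable settings.
#' @param minCounts ergodic-trimming count floor per microstate (see
#'   [trimToConnected()]).
#' @param kinkThreshold degrees; `hbondMaxDistance` nm, `hbondMaxAngle`
#'   degrees; `nResamples` bootstrap resamples.
#' @param seed master seed.
#' @param outputDir artifact directory or `NULL` for in-memory only.
#' @return a validated config (list, class `msmhelixConfig`).
#' @export
runConfig <- function(inputMode = c("synthetic", "external"),
                      landscape = makeLandscape("triple-well-2d"),
                      nTrajectories = 20L, nSteps = 100000L, dt = 0.001,
                      D = 1, kT = 1, stride = 10L,
                      trajectories = NULL,
                      ticaLag = NULL, msmLag = NULL, nClusters = NULL,
                      nMacro = NULL, nComponents = 2L,
                      gmrq = FALSE, gmrqGrid = NULL,
                      residence = FALSE, nTop = 12L,
                      residenceMultiples = 0:2,
                      nChains = 10L, nStepsMCMC = 100000L,
                      burnInFraction = 0.2,
                      minCounts = 100,
                      kinkThreshold = 35, hbondMaxDistance = 0.35,
                      hbondMaxAngle = 30, nResamples = 1000L,
                      seed = 1L, outputDir = NULL) {
  inputMode <- match.arg(inputMode)
  if (is.null(ticaLag)) ticaLag <- if (inputMode == "synthetic") 0.1 else 2
  if (is.null(msmLag)) msmLag <- if (inputMode == "synthetic") 0.25 else 45
  if (is.null(nClusters))
    nClusters <- if (inputMode == "synthetic") 150L else 800L
  stopifnot(ticaLag > 0, msmLag > 0, nClusters >= 2L, nComponents >= 1L,
            nChains >= 2L, burnInFraction >= 0, burnInFraction < 1,
            kinkThreshold > 0, hbondMaxDistance > 0, hbondMaxAngle > 0)
  if (inputMode == "external" && is.null(trajectories))
    stop("external mode requires trajectories")
  cfg <- list(inputMode = inputMode, landscape = landscape,
              nTrajectories = as.integer(nTrajectories),
              nSteps = as.integer(nSteps), dt = dt, D = D, kT = kT,
              stride = as.integer(stride), trajectories = trajectories,
              ticaLag = ticaLag, msmLag = msmLag,
              nClusters = as.integer(nClusters), nMacro = nMacro,
              nComponents = as.integer(nComponents), gmrq = gmrq,
              gmrqGrid = gmrqGrid, residence = residence,
              nTop = as.integer(nTop),
              residenceMultiples = residenceMultiples,
              nChains = as.integer(nChains),
              nStepsMCMC = as.integer(nStepsMCMC),
              burnInFraction = burnInFraction,
              minCounts = minCounts,
              kinkThreshold = kinkThreshold,
              hbondMaxDistance = hbondMaxDistance,
              hbondMaxAngle = hbondMaxAngle,
              nResamples = as.integer(nResamples),
              seed = as.integer(seed), outputDir = outputDir)
  class(cfg) <- "msmhelixConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map 1:1 onto [runConfig()] arguments; `landscape` may be a
#' mapping with a `family` key and family parameters.
#'
#' @param path YAML file.
#' @return a validated config.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$landscape) && is.list(y$landscape)) {
    y$landscape <- do.call(makeLandscape, y$landscape)
  }
  do.call(runConfig, y)
}

.toFrames <- function(time, frameInterval, what) {
  f <- time / frameInterval
  fr <- max(1L, as.integer(round(f)))
  if (abs(fr - f) / f > 0.01)
    warning(what, ": ", time, " time units is not close to a whole number ",
            "of frames (interval ", frameInterval, "); rounded to ", fr)
  fr
}

#' Run the full MSM analysis pipeline
#'
#' Executes simulate/ingest -> tICA -> k-centers -> MSM (trimmed,
#' reversible) -> optional GMRQ / residence validation -> spectral lumping
#' (macrostate count by eigenvalue gap unless fixed) -> TPT committor /
#' reactive flux / 95%-coverage pathways between the terminal macrostates
#' (ordered along tIC1) -> MFPTs (MCMC protocol primary, linear solve as
#' ground truth) -> macrostate populations with MCMC spreads. Artifacts are
#' written under `outputDir` when set (tables CSV, report JSON); reruns
#' with the same config and seed reproduce all stochastic outputs exactly.
#'
#' @param config from [runConfig()] / [readRunConfig()].
#' @return report list (class `msmhelixReport`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "msmhelixConfig"))
  seed <- config$seed
  ## stage: trajectories
  trajs <- if (config$inputMode == "synthetic") {
    simulateOverdamped(config$landscape, nSteps = config$nSteps,
                       nTrajectories = config$nTrajectories,
                       dt = config$dt, D = config$D, kT = config$kT,
                       seed = deriveSeed(seed, "simulate"),
                       x0 = "boltzmann", stride = config$stride)
  } else .as_traj_list(config$trajectories)
  dtau <- trajs[[1L]]@frameInterval
  ## stage: tICA
  ticaLagF <- .toFrames(config$ticaLag, dtau, "tICA lag")
  tica <- fitTICA(trajs, lag = ticaLagF * dtau)
  projected <- projectTICA(tica, trajs, nComponents = config$nComponents)
  ## stage: clustering
  pooled <- do.call(rbind, projected)
  km <- kCenters(pooled, k = min(config$nClusters, nrow(pooled)))
  dtrajs <- lapply(projected, function(x) assignMicrostates(km, x))
  ## stage: MSM
  msmLagF <- .toFrames(config$msmLag, dtau, "MSM lag")
  Cm <- trimToConnected(countTransitions(dtrajs, msmLagF, nStates = km@k),
                        minCounts = config$minCounts)
  model <- estimateMarkovModel(Cm, frameInterval = dtau)
  ## stage: validation (optional)
  gmrqReport <- NULL
  if (isTRUE(config$gmrq)) {
    grid <- config$gmrqGrid
    if (is.null(grid))
      grid <- list(full = list(nClusters = km@k),
                   coarse = list(nClusters = max(2L, km@k %/% 4L)))
    gmrqReport <- gmrqCrossValidate(projected, grid, lag = msmLagF,
                                    seed = deriveSeed(seed, "gmrq"))
  }
  residenceReport <- NULL
  if (isTRUE(config$residence))
    residenceReport <- residenceProbabilityTest(
      model, dtrajs, nTop = config$nTop,
      lagMultiples = config$residenceMultiples,
      seed = deriveSeed(seed, "residence"))
  ## stage: lumping
  nMacro <- config$nMacro
  gap <- macrostateCountByGap(model, maxK = min(6L, nStates(model) - 1L))
  if (is.null(nMacro)) nMacro <- as.integer(gap)
  macro <- spectralLump(model, nMacro, seed = deriveSeed(seed, "lump"))
  ## order macrostates along tIC1 (pi-weighted mean of member centers)
  centerProj <- km@centers[Cm@activeSet, 1L]
  macroOrder <- order(vapply(seq_len(nMacro), function(m) {
    w <- model@pi[macro@assignment == m]
    sum(w * centerProj[macro@assignment == m]) / sum(w)
  }, numeric(1L)))
  relabel <- integer(nMacro); relabel[macroOrder] <- seq_len(nMacro)
  assignment <- relabel[macro@assignment]
  pops <- vapply(seq_len(nMacro), function(m)
    sum(model@pi[assignment == m]), numeric(1L))
  ## stage: MCMC populations
  popMCMC <- sampleObservableMCMC(
    model, as.integer(assignment), nChains = config$nChains,
    nSteps = config$nStepsMCMC, burnInFraction = config$burnInFraction,
    seed = deriveSeed(seed, "mcmc"), bootstrap = TRUE,
    nResamples = config$nResamples)
  ## stage: TPT between terminal macrostates + MFPT matrix
  tpt <- NULL
  if (nMacro >= 2L) {
    A <- which(assignment == 1L)
    B <- which(assignment == nMacro)
    flux <- reactiveFlux(model, A, B)
    macroObj <- new("MacroModel", nMacro = as.integer(nMacro),
                    assignment = as.integer(assignment), populations = pops,
                    eigenvalues = model@eigenvalues,
                    gapRatios = attr(gap, "ratios"))
    macroFlux <- aggregateFlux(flux, macroObj)
    paths <- decomposePathways(macroFlux, coverage = 0.95)
    tpt <- list(flux = flux, macroFlux = macroFlux, pathways = paths,
                macro = macroObj)
  }
  mfpt <- matrix(0, nMacro, nMacro)
  mfptMCMC <- matrix(0, nMacro, nMacro)
  mfptSD <- matrix(0, nMacro, nMacro)
  for (i in seq_len(nMacro)) for (j in seq_len(nMacro)) if (i != j) {
    src <- which(assignment == i); tgt <- which(assignment == j)
    mfpt[i, j] <- mfptLinear(model, src, tgt)
    mc <- mcmcMFPT(model, src, tgt, nChains = config$nChains,
                   nSteps = config$nStepsMCMC,
                   seed = deriveSeed(seed, paste0("mfpt", i, "_", j)))
    mfptMCMC[i, j] <- mc$mfpt
    mfptSD[i, j] <- sd(mc$perChain, na.rm = TRUE)
  }
  report <- list(
    schema = "msmhelix-report/1",
    seed = seed,
    nTrajectories = length(trajs),
    nFrames = vapply(trajs, nFrames, 1L),
    frameInterval = dtau,
    ticaEigenvalues = tica@eigenvalues[seq_len(min(
      5L, length(tica@eigenvalues)))],
    nMicrostates = km@k,
    nActive = nStates(model),
    impliedTimescales = impliedTimescales(model)[seq_len(min(
      5L, nStates(model) - 1L))],
    nMacro = nMacro,
    gapRatios = attr(gap, "ratios"),
    macroPopulations = pops,
    macroPopulationsMCMC = list(mean = popMCMC$mean, sd = popMCMC$sd,
                                lower = popMCMC$lower,
                                upper = popMCMC$upper),
    mfptLinear = mfpt,
    mfptMCMC = mfptMCMC,
    mfptMCMCsd = mfptSD,
    pathways = if (!is.null(tpt)) list(
      sequences = tpt$pathways@pathways,
      fluxes = tpt$pathways@fluxes,
      coverage = tpt$pathways@coverage,
      totalFlux = tpt$pathways@totalFlux) else NULL,
    gmrq = if (!is.null(gmrqReport)) list(
      summary = gmrqReport@summary, best = gmrqReport@best) else NULL,
    residence = if (!is.null(residenceReport)) list(
      pass = residenceReport@pass,
      states = residenceReport@states) else NULL)
  result <- list(report = report, trajs = trajs, tica = tica, km = km,
                 dtrajs = dtrajs, model = model,
                 assignment = assignment, tpt = tpt,
                 gmrqReport = gmrqReport,
                 residenceReport = residenceReport, config = config)
  class(result) <- "msmhelixReport"
  if (!is.null(config$outputDir)) .write_report(result, config$outputDir)
  result
}

.write_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rep <- result$report
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write.csv(data.frame(macro = seq_len(rep$nMacro),
                       population = rep$macroPopulations,
                       mcmcMean = rep$macroPopulationsMCMC$mean,
                       mcmcSD = rep$macroPopulationsMCMC$sd),
            file.path(dir, "populations.csv"), row.names = FALSE)
  write.csv(as.data.frame(rep$mfptMCMC),
            file.path(dir, "mfpt_mcmc.csv"), row.names = FALSE)
  write.csv(as.data.frame(rep$mfptLinear),
            file.path(dir, "mfpt_linear.csv"), row.names = FALSE)
  write.csv(data.frame(micro = activeSet(result$model),
                       macro = result$assignment),
            file.path(dir, "macro_map.csv"), row.names = FALSE)
  summaryLines <- c(
    sprintf("msmhelix pipeline report (seed %d)", rep$seed),
    sprintf("%d trajectories, %d microstates (%d active), %d macrostates",
            rep$nTrajectories, rep$nMicrostates, rep$nActive, rep$nMacro),
    sprintf("macro populations: %s",
            paste(sprintf("%.1f%%", 100 * rep$macroPopulations),
                  collapse = ", ")),
    sprintf("MFPT 1 -> %d (MCMC): %.4g time units", rep$nMacro,
            rep$mfptMCMC[1L, rep$nMacro]))
  writeLines(summaryLines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Compare two pipeline reports
#'
#' Aligns macrostates (by population rank when the counts differ, flagged)
#' and tabulates population, MFPT and validation differences with combined
#' MCMC uncertainty.
#'
#' @param a,b results from [runPipeline()].
#' @return list with `populations` (data.frame), `mfpt` difference matrix,
#'   `countMismatch` flag.
#' @export
compareRuns <- function(a, b) {
  ra <- a$report; rb <- b$report
  na <- ra$nMacro; nb <- rb$nMacro
  mismatch <- na != nb
  if (mismatch)
    warning("macrostate counts differ (", na, " vs ", nb,
            "); aligning by population rank")
  n <- min(na, nb)
  ordA <- order(ra$macroPopulations, decreasing = TRUE)[seq_len(n)]
  ordB <- order(rb$macroPopulations, decreasing = TRUE)[seq_len(n)]
  pops <- data.frame(
    rank = seq_len(n),
    macroA = ordA, macroB = ordB,
    popA = ra$macroPopulations[ordA],
    popB = rb$macroPopulations[ordB])
  pops$difference <- pops$popA - pops$popB
  pops$combinedSD <- sqrt(ra$macroPopulationsMCMC$sd[ordA]^2 +
                            rb$macroPopulationsMCMC$sd[ordB]^2)
  mf <- ra$mfptMCMC[ordA, ordA, drop = FALSE] -
    rb$mfptMCMC[ordB, ordB, drop = FALSE]
  list(populations = pops, mfpt = mf, countMismatch = mismatch)
}
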