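#' @include AllClasses.R circuit.R dynamics.R analysis.R config-io.R
NULL

# Registry of named experiment presets. Each entry: a description, config
# deltas applied on top of defaultConfig(), one or more stimulus targets
# with amplitudes, the probe population whose STI is reported, and (where a
# figure defines one) the baseline preset for the similarity angle.
# trnGainFactor: the "increased TRN inhibition" conditions multiply the
# TRN_C -> PV+ gain by this preset constant.
.trnGainFactor <- 2

.presetTable <- function() {
  sp <- function(target, amplitude = 1)
    list(target = target, kind = "spindle_burst", amplitude = amplitude)
  core <- list()                     # default flags are the core baseline
  list(
    fig2b = list(
      desc = "0.5 s tonic square input to PV+ in the default core network",
      deltas = core,
      stimuli = list(list(target = "PV+", kind = "tonic_square",
                          amplitude = 0.05)),
      probe = "PV+", baseline = NA_character_),
    fig3a = list(
      desc = "matrix loop, no L5->TRN_M projection",
      deltas = list(l5TrnFraction = 0),
      stimuli = list(sp("TRN_M")), probe = "CB+",
      baseline = NA_character_),
    fig3b = list(
      desc = "matrix loop, L5->TRN_M at 5% of the L6->TRN_C gain",
      deltas = list(l5TrnFraction = 0.05),
      stimuli = list(sp("TRN_M")), probe = "CB+",
      baseline = NA_character_),
    fig3c = list(
      desc = "matrix loop, L5->TRN_M at 10% of the L6->TRN_C gain",
      deltas = list(l5TrnFraction = 0.10),
      stimuli = list(sp("TRN_M")), probe = "CB+",
      baseline = NA_character_),
    fig4 = list(
      desc = "50-50 thalamoreticular mix for spindle wave propagation",
      deltas = list(mixingMode = "thalamoreticular", mixingRatio = 0.5,
                    mixingEfficacy = 1),
      stimuli = list(sp("TRN_C"), sp("TRN_M")), probe = "PV+",
      baseline = NA_character_),
    fig5a = list(
      desc = "core loop without local thalamic inhibition",
      deltas = core,
      stimuli = list(sp("TRN_C")), probe = "PV+",
      baseline = NA_character_),
    fig5b = list(
      desc = "core loop with local thalamic inhibition (PV- pathway)",
      deltas = list(localInhibition = c(core = TRUE)),
      stimuli = list(sp("TRN_C")), probe = "PV+",
      baseline = NA_character_),
    fig6a = list(
      desc = "core loop, no corticothalamic feedback",
      deltas = core,
      stimuli = list(sp("TRN_C")), probe = "PV+",
      baseline = NA_character_),
    fig6b = list(
      desc = "core loop with L6->PV+ corticothalamic feedback",
      deltas = list(corticalFeedbackTC = TRUE),
      stimuli = list(sp("TRN_C")), probe = "PV+",
      baseline = NA_character_),
    fig6c = list(
      desc = "core loop with raised TRN_C->PV+ inhibitory gain",
      deltas = list(trnGain = .trnGainFactor),
      stimuli = list(sp("TRN_C")), probe = "PV+",
      baseline = NA_character_),
    fig6d = list(
      desc = "raised TRN_C->PV+ gain plus corticothalamic feedback",
      deltas = list(trnGain = .trnGainFactor, corticalFeedbackTC = TRUE),
      stimuli = list(sp("TRN_C")), probe = "PV+",
      baseline = NA_character_),
    fig7a = list(
      desc = "pure core loop spindle entrainment",
      deltas = core,
      stimuli = list(sp("TRN_C")), probe = "PV+", baseline = "fig7b"),
    fig7b = list(
      desc = "50-50 thalamoreticular mix (the similarity baseline)",
      deltas = list(mixingMode = "thalamoreticular", mixingRatio = 0.5,
                    mixingEfficacy = 1),
      stimuli = list(sp("TRN_C"), sp("TRN_M")), probe = "PV+",
      baseline = NA_character_),
    fig7c = list(
      desc = "pure matrix loop spindle entrainment",
      deltas = core,
      stimuli = list(sp("TRN_M")), probe = "CB+", baseline = "fig7b"),
    fig8a = .corticalMixPreset(0.8), fig8b = .corticalMixPreset(0.6),
    fig8base = .corticalMixPreset(0.5, baseline = NA_character_),
    fig8c = .corticalMixPreset(0.4), fig8d = .corticalMixPreset(0.2),
    fig9a = .efficacyPreset(0.3, baseline = NA_character_),
    fig9b = .efficacyPreset(0.6), fig9c = .efficacyPreset(0.9))
}

.corticalMixPreset <- function(ratio, baseline = "fig8base") {
  list(desc = sprintf("cortical mixing, %d/%d core/matrix ratio",
                      round(100 * ratio), round(100 * (1 - ratio))),
       deltas = list(mixingMode = "cortical", mixingRatio = ratio,
                     mixingEfficacy = 0.6),
       stimuli = list(
         list(target = "TRN_C", kind = "spindle_burst",
              amplitude = min(1, 2 * ratio)),
         list(target = "TRN_M", kind = "spindle_burst",
              amplitude = min(1, 2 * (1 - ratio)))),
       probe = "PV+", baseline = baseline)
}

.efficacyPreset <- function(efficacy, baseline = "fig9a") {
  list(desc = sprintf("cortical mixing at 50-50, %d%% plateau efficacy",
                      round(100 * efficacy)),
       deltas = list(mixingMode = "cortical", mixingRatio = 0.5,
                     mixingEfficacy = efficacy),
       stimuli = list(
         list(target = "TRN_C", kind = "spindle_burst", amplitude = 1),
         list(target = "TRN_M", kind = "spindle_burst", amplitude = 1)),
       probe = "PV+", baseline = baseline)
}

#' List the shipped experiment presets
#'
#' @return Data frame with preset \code{name}, \code{description}, probe
#'   population and similarity baseline.
#' @examples
#' listPresets()
#' @export
listPresets <- function() {
  tab <- .presetTable()
  data.frame(name = names(tab),
             description = vapply(tab, function(x) x$desc, ""),
             probe = vapply(tab, function(x) x$probe, ""),
             baseline = vapply(tab, function(x) x$baseline, ""),
             row.names = NULL)
}

#' Circuit configuration and stimulus protocol of a preset
#'
#' \code{presetConfig} applies a preset's declarative deltas to the
#' calibrated default configuration; \code{presetProtocol} builds its
#' stimulus list (spindle-like input centred on \code{centerIndex}).
#'
#' @param name Preset name (see [listPresets()]).
#' @param N Optional population-size override.
#' @param centerIndex Stimulated array index (default 100, scaled
#'   proportionally when \code{N} is overridden).
#' @return \code{presetConfig}: a [CircuitConfig-class];
#'   \code{presetProtocol}: a list of [StimulusProtocol-class].
#' @export
presetConfig <- function(name, N = NULL) {
  tab <- .presetTable()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  deltas <- tab[[name]]$deltas
  trnGain <- deltas$trnGain
  deltas$trnGain <- NULL
  if (!is.null(N)) deltas$N <- N
  cfg <- do.call(defaultConfig, deltas)
  if (!is.null(trnGain))
    cfg@gains["trnc_pv"] <- trnGain * cfg@gains["trnc_pv"]
  cfg
}

#' @rdname presetConfig
#' @export
presetProtocol <- function(name, N = NULL, centerIndex = 100) {
  tab <- .presetTable()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  if (!is.null(N)) centerIndex <- round(centerIndex * N / 200)
  lapply(tab[[name]]$stimuli, function(s)
    stimulusProtocol(s$target, s$kind, amplitude = s$amplitude,
                     centerIndex = centerIndex))
}

# stack all population maps into one matrix for the similarity angle
.stackedMap <- function(result) {
  do.call(rbind, lapply(circuitPopulations(),
                        function(p) traces(result, p)))
}

#' Similarity angle between the spatiotemporal patterns of two runs
#'
#' Concatenates the activity maps of all ten populations of each run and
#' returns the arc-cosine similarity angle between the two stacked maps.
#'
#' @param resultA,resultB \linkS4class{SpindleSimResult} objects of equal
#'   dimensions.
#' @return Angle in degrees.
#' @export
resultAngle <- function(resultA, resultB)
  similarityAngle(.stackedMap(resultA), .stackedMap(resultB))

#' Run a named experiment preset
#'
#' Wires the preset circuit, integrates it under the preset stimulus
#' protocol and measures the analysis quantities: STI of the probe
#' population at the stimulated index, propagation onsets at the probe
#' sites, and (for presets with a declared baseline) the similarity angle
#' against the baseline run.
#'
#' @param name Preset name (see [listPresets()]).
#' @param T Total simulated time, s (default 2: 0.5 s stimulus + 1.5 s free
#'   evolution).
#' @param dt Integration step, s.
#' @param N Optional population-size override (probe indices scale).
#' @param baselineResult Optional precomputed baseline
#'   \linkS4class{SpindleSimResult} to avoid re-running it.
#' @param keepResult Keep the full trace container in the returned list?
#' @return List with \code{report} (a [SpindleReport-class]) and, when
#'   \code{keepResult = TRUE}, \code{result}.
#' @examples
#' \donttest{
#' out <- runPreset("fig5a")
#' out$report
#' }
#' @export
runPreset <- function(name, T = 2, dt = 5e-4, N = NULL,
                      baselineResult = NULL, keepResult = FALSE) {
  tab <- .presetTable()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  entry <- tab[[name]]
  cfg <- presetConfig(name, N = N)
  center <- if (is.null(N)) 100 else round(100 * N / 200)
  protocol <- presetProtocol(name, N = N)
  result <- integrateCircuit(buildCircuit(cfg), protocol, T = T, dt = dt)

  tOff <- max(vapply(protocol, function(p) p@onset + p@duration, 0))
  probe <- entry$probe
  sti <- data.frame(population = probe, neuron = center,
                    sti = computeSTI(neuronTrace(result, probe, center),
                                     tOff, dt))
  sites <- round(c(100, 113, 128, 147) * cfg@N / 200)
  lat <- propagationLatencies(result, probe, sites = sites)

  theta <- NA_real_
  if (!is.na(entry$baseline)) {
    if (is.null(baselineResult))
      baselineResult <- integrateCircuit(
        buildCircuit(presetConfig(entry$baseline, N = N)),
        presetProtocol(entry$baseline, N = N), T = T, dt = dt)
    theta <- resultAngle(result, baselineResult)
  }
  report <- new("SpindleReport", sti = sti, thetaDeg = theta,
                baseline = if (is.na(entry$baseline)) NA_character_
                           else entry$baseline,
                latencies = lat, condition = name)
  out <- list(report = report)
  if (keepResult) out$result <- result
  out
}

#' Calibrate unprinted default gains against STI anchors
#'
#' The absolute synaptic gains of the circuit are free constants bounded
#' only by the published ratio constraints (L5->CB+ = 20 x L6->PV+;
#' L5->TRN_M at 0-10\% of L6->TRN_C). This routine fixes a chosen set of
#' free gains by coarse-to-fine grid search so that the named presets
#' reproduce their anchor STI values; the winning configuration is intended
#' to be written to the packaged default-config file once (calibration is
#' not re-run at test time).
#'
#' @param anchors Named numeric: preset name -> target STI in seconds. An
#'   empty vector returns \code{config} unchanged.
#' @param free Character vector of gain names to search (default the two
#'   reticulo-thalamic inhibitory gains).
#' @param lower,upper Numeric bounds per free gain (recycled).
#' @param gridSize Points per dimension of the first (coarse) grid.
#' @param refine Number of successive local refinements (each shrinks the
#'   bracket threefold around the incumbent).
#' @param config Starting [CircuitConfig-class].
#' @param T,dt,N Simulation size used during the search.
#' @return The calibrated [CircuitConfig-class], version-stamped; the best
#'   residuals are attached as attribute \code{"residuals"}.
#' @export
calibrateDefaults <- function(anchors, free = c("trnc_pv", "trnm_cb"),
                              lower = 0.25, upper = 4, gridSize = 10,
                              refine = 1, config = defaultConfig(),
                              T = 2, dt = 5e-4, N = config@N) {
  if (!length(anchors)) return(config)
  if (is.null(names(anchors)) || any(!names(anchors) %in%
                                     listPresets()$name))
    stop("anchors must be named by preset", call. = FALSE)
  lower <- rep_len(lower, length(free))
  upper <- rep_len(upper, length(free))
  base <- config@gains[free]

  residual <- function(mult) {
    sum(vapply(names(anchors), function(ps) {
      entry <- .presetTable()[[ps]]
      pcfg <- presetConfig(ps, N = N)
      pcfg@gains[free] <- pcfg@gains[free] * mult
      res <- tryCatch(
        integrateCircuit(buildCircuit(pcfg), presetProtocol(ps, N = N),
                         T = T, dt = dt),
        error = function(e) NULL)
      if (is.null(res)) return(10)
      center <- round(100 * N / 200)
      (computeSTI(neuronTrace(res, entry$probe, center), 0.5, dt) -
         anchors[[ps]])^2
    }, 0))
  }

  lo <- lower; hi <- upper
  bestMult <- rep(1, length(free)); bestRes <- residual(bestMult)
  for (lvl in seq_len(refine + 1)) {
    axes <- lapply(seq_along(free), function(i)
      exp(seq(log(lo[i]), log(hi[i]), length.out = gridSize)))
    grid <- as.matrix(expand.grid(axes))
    for (r in seq_len(nrow(grid))) {
      res <- residual(grid[r, ])
      if (res < bestRes) { bestRes <- res; bestMult <- grid[r, ] }
    }
    span <- (hi / lo)^(1 / 3)
    lo <- pmax(lower, bestMult / span)
    hi <- pmin(upper, bestMult * span)
  }
  out <- config
  out@gains[free] <- base * bestMult
  out@version <- paste0(config@version, "+cal", format(Sys.Date()))
  attr(out, "residuals") <- bestRes
  out
}
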