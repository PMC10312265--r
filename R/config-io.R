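#' @include AllClasses.R
NULL

.pkgEnv <- new.env(parent = emptyenv())

.configFromList <- function(x) {
  new("CircuitConfig",
      N = as.integer(x$nNeurons),
      decayA = if (is.list(x$decayA)) unlist(x$decayA)
               else as.numeric(x$decayA),
      eExt = as.numeric(x$eExt), eInh = as.numeric(x$eInh),
      gains = unlist(x$gains),
      sigmas = unlist(x$sigmas),
      centerOffsets = vapply(x$centerOffsets, as.integer, 0L),
      l5TrnFraction = as.numeric(x$l5TrnFraction),
      l5CbOverL6Pv = as.numeric(x$l5CbOverL6Pv),
      localInhibition = vapply(x$localInhibition, as.logical, NA),
      corticalFeedbackTC = as.logical(x$corticalFeedbackTC),
      corticalFeedbackTRN = as.logical(x$corticalFeedbackTRN),
      mixingMode = x$mixingMode,
      mixingRatio = as.numeric(x$mixingRatio),
      mixingEfficacy = as.numeric(x$mixingEfficacy),
      transfer = x$transfer,
      stimGain = as.numeric(x$stimGain),
      version = as.character(x$version))
}

.configToList <- function(config) {
  list(version = config@version, nNeurons = config@N, decayA = config@decayA,
       eExt = config@eExt, eInh = config@eInh,
       gains = as.list(config@gains), sigmas = as.list(config@sigmas),
       centerOffsets = as.list(config@centerOffsets),
       l5TrnFraction = config@l5TrnFraction,
       l5CbOverL6Pv = config@l5CbOverL6Pv,
       localInhibition = as.list(config@localInhibition),
       corticalFeedbackTC = config@corticalFeedbackTC,
       corticalFeedbackTRN = config@corticalFeedbackTRN,
       mixingMode = config@mixingMode, mixingRatio = config@mixingRatio,
       mixingEfficacy = config@mixingEfficacy, transfer = config@transfer,
       stimGain = config@stimGain)
}

#' Read / write a circuit configuration file
#'
#' Circuit configurations are stored as YAML (key/value plus named lists of
#' gains, kernel widths and flags) and validated on read.
#'
#' @param path File path.
#' @param config A [CircuitConfig-class].
#' @return \code{readCircuitConfig} returns a validated
#'   [CircuitConfig-class]; \code{writeCircuitConfig} returns \code{path}
#'   invisibly.
#' @export
readCircuitConfig <- function(path) {
  cfg <- .configFromList(yaml::read_yaml(path))
  validObject(cfg)
  cfg
}

#' @rdname readCircuitConfig
#' @export
writeCircuitConfig <- function(config, path) {
  stopifnot(is(config, "CircuitConfig"))
  yaml::write_yaml(.configToList(config), path)
  invisible(path)
}

#' The calibrated default circuit configuration
#'
#' Returns the shipped, version-stamped default configuration. The absolute
#' synaptic gains are calibration constants fixed once by
#' [calibrateDefaults()] under the anatomical ratio constraints (the
#' L5->CB+ drive is 20 times the L6->PV+ feedback gain; the L5->TRN_M gain
#' is a 0-10\% fraction of the L6->TRN_C gain); see the package vignette
#' for the calibration procedure. Any argument overrides the corresponding
#' slot; \code{gains}, \code{sigmas}, \code{localInhibition} and
#' \code{centerOffsets} overrides are merged by name, so partial vectors
#' such as \code{gains = c(trnc_pv = 120)} work.
#'
#' @param ... Named overrides of [CircuitConfig-class] slots.
#' @return A validated [CircuitConfig-class].
#' @examples
#' cfg <- defaultConfig(localInhibition = c(core = TRUE))
#' cfg@localInhibition
#' @export
defaultConfig <- function(...) {
  if (is.null(.pkgEnv$default)) {
    path <- system.file("extdata", "default-config.yaml",
                        package = "spindleloop", mustWork = TRUE)
    .pkgEnv$default <- readCircuitConfig(path)
  }
  cfg <- .pkgEnv$default
  dots <- list(...)
  merged <- c("gains", "sigmas", "localInhibition", "centerOffsets")
  for (nm in names(dots)) {
    if (!nm %in% slotNames(cfg))
      stop(sprintf("unknown configuration field '%s'", nm), call. = FALSE)
    if (nm %in% merged) {
      cur <- slot(cfg, nm)
      ov <- dots[[nm]]
      if (is.null(names(ov)) || any(!names(ov) %in% names(cur)))
        stop(sprintf("override of '%s' must use known names", nm),
             call. = FALSE)
      cur[names(ov)] <- ov
      slot(cfg, nm) <- cur
    } else {
      tgt <- slot(cfg, nm)
      slot(cfg, nm) <- if (is.integer(tgt)) as.integer(dots[[nm]])
                       else dots[[nm]]
    }
  }
  validObject(cfg)
  cfg
}
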