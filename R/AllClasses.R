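#' @import methods
#' @importFrom stats dnorm
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Population names of the ten-unit thalamocortical circuit
#'
#' The circuit is built from ten index-aligned populations on a shared
#' one-dimensional array: matrix and core excitatory thalamic relay neurons
#' (\code{CB+}, \code{PV+}), local thalamic inhibitory interneurons
#' (\code{CB-}, \code{PV-}), the matrix and core sectors of the thalamic
#' reticular nucleus (\code{TRN_M}, \code{TRN_C}), and four cortical layer
#' populations (\code{L1-3a}, \code{L3b-4}, \code{L5}, \code{L6}).
#'
#' @return Character vector of the ten population names, in canonical order.
#' @examples
#' circuitPopulations()
#' @export
circuitPopulations <- function() {
  c("CB+", "PV+", "CB-", "PV-", "TRN_M", "TRN_C",
    "L1-3a", "L3b-4", "L5", "L6")
}

.popRoles <- c(
  "CB+"   = "thalamic-excitatory",
  "PV+"   = "thalamic-excitatory",
  "CB-"   = "thalamic-inhibitory",
  "PV-"   = "thalamic-inhibitory",
  "TRN_M" = "reticular",
  "TRN_C" = "reticular",
  "L1-3a" = "cortical",
  "L3b-4" = "cortical",
  "L5"    = "cortical",
  "L6"    = "cortical")

# populations whose outgoing projections are inhibitory
.inhibitorySources <- c("CB-", "PV-", "TRN_M", "TRN_C")

#' ProjectionKernel: one Gaussian pre-to-post connection profile
#'
#' A single projection between two populations, described by a Gaussian
#' connectivity profile over the one-dimensional neuron array: synaptic
#' strength (\code{gain}), spatial width (\code{sigma}, in neuron-index
#' units), an integer \code{centerOffset} (the open-loop shift eta; 0 gives
#' the balanced hybrid loop whose symmetric profile is functionally
#' equivalent to a closed loop), and the projection \code{sign}
#' (\code{"excitatory"} or \code{"inhibitory"}), which decides whether the
#' summed drive feeds the excitatory or the inhibitory conductance of the
#' postsynaptic population.
#'
#' @slot pre,post Population names (see [circuitPopulations()]).
#' @slot gain Non-negative synaptic strength multiplying the unit-mass
#'   Gaussian profile.
#' @slot sigma Positive Gaussian width in neuron-index units.
#' @slot centerOffset Integer index shift of the kernel center.
#' @slot sign \code{"excitatory"} or \code{"inhibitory"}.
#' @export
setClass("ProjectionKernel",
  representation(pre = "character", post = "character", gain = "numeric",
                 sigma = "numeric", centerOffset = "integer",
                 sign = "character"))

setValidity("ProjectionKernel", function(object) {
  msg <- character()
  if (!object@pre %in% circuitPopulations())
    msg <- c(msg, sprintf("unknown presynaptic population '%s'", object@pre))
  if (!object@post %in% circuitPopulations())
    msg <- c(msg, sprintf("unknown postsynaptic population '%s'", object@post))
  if (length(object@gain) != 1L || is.na(object@gain) || object@gain < 0)
    msg <- c(msg, "gain must be a single non-negative number")
  if (length(object@sigma) != 1L || is.na(object@sigma) || object@sigma <= 0)
    msg <- c(msg, "sigma must be a single positive number")
  if (!object@sign %in% c("excitatory", "inhibitory"))
    msg <- c(msg, "sign must be 'excitatory' or 'inhibitory'")
  if (length(msg)) msg else TRUE
})

#' Construct a ProjectionKernel
#'
#' @param pre,post Population names.
#' @param gain Non-negative synaptic strength.
#' @param sigma Positive Gaussian width (neuron-index units).
#' @param centerOffset Integer center shift (eta); default 0 (balanced
#'   hybrid loop).
#' @param sign \code{"excitatory"} or \code{"inhibitory"}.
#' @return A [ProjectionKernel-class] object.
#' @examples
#' projectionKernel("TRN_C", "PV+", gain = 60, sigma = 3, sign = "inhibitory")
#' @export
projectionKernel <- function(pre, post, gain, sigma, centerOffset = 0L,
                             sign = c("excitatory", "inhibitory")) {
  sign <- match.arg(sign)
  if (length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("configuration error: sigma must be positive", call. = FALSE)
  new("ProjectionKernel", pre = as.character(pre), post = as.character(post),
      gain = as.numeric(gain), sigma = as.numeric(sigma),
      centerOffset = as.integer(centerOffset), sign = sign)
}

setMethod("show", "ProjectionKernel", function(object) {
  cat(sprintf("ProjectionKernel %s -> %s (%s)\n", object@pre, object@post,
              object@sign))
  cat(sprintf("  gain %.4g, sigma %.4g, center offset %+d\n",
              object@gain, object@sigma, object@centerOffset))
})

#' WeightMatrix: a realised N x N connectivity matrix
#'
#' The Gaussian profile of a [ProjectionKernel-class] evaluated on an
#' N-neuron array. Entry (i, j) is the strength of presynaptic neuron j onto
#' postsynaptic neuron i; all entries are non-negative (the sign lives on
#' the kernel). Gaussians are truncated at the array edges: no wraparound
#' and no renormalisation.
#'
#' @slot values N x N non-negative numeric matrix (rows = postsynaptic).
#' @slot pre,post Population names.
#' @export
setClass("WeightMatrix",
  representation(values = "matrix", pre = "character", post = "character"))

setValidity("WeightMatrix", function(object) {
  if (any(object@values < 0)) "weight entries must be non-negative" else TRUE
})

setMethod("show", "WeightMatrix", function(object) {
  cat(sprintf("WeightMatrix %s -> %s: %d x %d, max %.4g\n", object@pre,
              object@post, nrow(object@values), ncol(object@values),
              max(object@values)))
})

#' CircuitConfig: declarative description of a core/matrix/mix circuit
#'
#' Holds every constant needed to wire and integrate the ten-population
#' circuit: population size \code{N}, the leak rate \code{decayA} (1/s) and
#' reversal potentials of the shunting equation, the named synaptic
#' \code{gains} and kernel widths, the printed ratio constraints
#' (\code{l5CbOverL6Pv}, \code{l5TrnFraction}), feature flags (local
#' thalamic inhibition per loop, corticothalamic and corticoreticular
#' feedback), the loop-offset parameters \code{centerOffsets} (eta), the
#' mixing mode/ratio/efficacy, the signal \code{transfer} rule and the
#' external drive scale \code{stimGain}.
#'
#' Use [defaultConfig()] for the calibrated shipped configuration.
#'
#' @slot N Shared population size (neurons on the 1-D array).
#' @slot decayA Leak (decay) rate A of the shunting equation, 1/s; a
#'   single rate shared by all populations or a named per-population
#'   vector (thalamic and reticular populations integrate more slowly than
#'   cortical ones in the shipped defaults).
#' @slot eExt,eInh Excitatory/inhibitory reversal potentials (+1 / -1).
#' @slot gains Named non-negative numeric vector of synaptic gains.
#' @slot sigmas Named positive numeric vector: kernel widths per spatial
#'   class (\code{core}, \code{matrix}), index units.
#' @slot centerOffsets Named integer vector of eta offsets
#'   (\code{trn_tc}, \code{tc_trn}, \code{tc_cortex}).
#' @slot l5TrnFraction L5->TRN_M gain as a fraction of the L6->TRN_C gain.
#' @slot l5CbOverL6Pv Ratio of the L5->CB+ gain to the L6->PV+ gain
#'   (default 20; rejected above 1000).
#' @slot localInhibition Named logical, \code{core} and \code{matrix}.
#' @slot corticalFeedbackTC Logical: L6->PV+ corticothalamic feedback.
#' @slot corticalFeedbackTRN Logical: L6->TRN_C and L5->TRN_M
#'   corticoreticular drive.
#' @slot mixingMode One of \code{none}, \code{thalamoreticular},
#'   \code{corticoreticular}, \code{cortical}.
#' @slot mixingRatio Core fraction r in [0, 1].
#' @slot mixingEfficacy Fraction of plateau synaptic efficacy in [0, 1].
#' @slot transfer Presynaptic transmission rule: \code{"signed"}
#'   (default: every projection transmits signed deviations around the
#'   tonic operating point, the negative part routing to the opposite
#'   conductance), \code{"rectified"} (half-wave: \eqn{[v]_+} only), or
#'   \code{"mixed"} (descending corticothalamic feedback rectified,
#'   everything else signed).
#' @slot stimGain Conductance scale of external stimuli.
#' @slot version Character stamp of the calibrated default set.
#' @export
setClass("CircuitConfig",
  representation(N = "integer", decayA = "numeric", eExt = "numeric",
                 eInh = "numeric", gains = "numeric", sigmas = "numeric",
                 centerOffsets = "integer", l5TrnFraction = "numeric",
                 l5CbOverL6Pv = "numeric", localInhibition = "logical",
                 corticalFeedbackTC = "logical",
                 corticalFeedbackTRN = "logical", mixingMode = "character",
                 mixingRatio = "numeric", mixingEfficacy = "numeric",
                 transfer = "character", stimGain = "numeric",
                 version = "character"))

.gainKeys <- c("l6_pv", "pv_trnc", "l6_trnc", "trnc_pv", "trnc_trnc",
               "pv_l3b4", "l3b4_l6", "pv_pvm", "pvm_pv", "trnc_pvm",
               "cb_trnm", "trnm_cb", "trnm_trnm", "cb_l13a", "l13a_l5",
               "cb_cbm", "cbm_cb", "trnm_cbm",
               "mix_cortical", "mix_thal", "mix_cr")

setValidity("CircuitConfig", function(object) {
  msg <- character()
  if (object@N < 1L) msg <- c(msg, "N must be >= 1")
  if (any(object@decayA <= 0)) msg <- c(msg, "decayA must be positive")
  if (!length(object@decayA) %in% c(1L, 10L))
    msg <- c(msg, "decayA must be a single rate or one rate per population")
  if (length(object@decayA) == 10L &&
      !all(circuitPopulations() %in% names(object@decayA)))
    msg <- c(msg, "per-population decayA must be named by population")
  if (object@eInh >= object@eExt) msg <- c(msg, "eInh must be below eExt")
  missing <- setdiff(.gainKeys, names(object@gains))
  if (length(missing))
    msg <- c(msg, paste("missing gains:", paste(missing, collapse = ", ")))
  if (any(object@gains < 0)) msg <- c(msg, "gains must be non-negative")
  if (any(object@sigmas <= 0)) msg <- c(msg, "kernel widths must be positive")
  if (!all(c("core", "matrix") %in% names(object@sigmas)))
    msg <- c(msg, "sigmas must name 'core' and 'matrix' widths")
  if (object@l5TrnFraction < 0 || object@l5TrnFraction > 1)
    msg <- c(msg, "l5TrnFraction must lie in [0, 1]")
  if (object@l5CbOverL6Pv > 1000)
    msg <- c(msg, paste("l5CbOverL6Pv above 1000 rejected: beyond three",
                        "orders of magnitude the matrix loop loses its",
                        "rebound oscillation"))
  if (object@l5CbOverL6Pv < 0) msg <- c(msg, "l5CbOverL6Pv must be >= 0")
  if (!all(c("core", "matrix") %in% names(object@localInhibition)))
    msg <- c(msg, "localInhibition must name 'core' and 'matrix' flags")
  if (!object@mixingMode %in% c("none", "thalamoreticular",
                                "corticoreticular", "cortical"))
    msg <- c(msg, "unknown mixingMode")
  if (object@mixingRatio < 0 || object@mixingRatio > 1)
    msg <- c(msg, "mixingRatio must lie in [0, 1]")
  if (object@mixingEfficacy < 0 || object@mixingEfficacy > 1)
    msg <- c(msg, "mixingEfficacy must lie in [0, 1]")
  if (!object@transfer %in% c("signed", "rectified", "mixed"))
    msg <- c(msg, "transfer must be 'signed', 'rectified' or 'mixed'")
  if (object@stimGain < 0) msg <- c(msg, "stimGain must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CircuitConfig", function(object) {
  cat(sprintf("CircuitConfig (version %s)\n", object@version))
  cat(sprintf("  N = %d, decay A in [%.3g, %.3g] /s, E_ext = %+g, E_inh = %+g\n",
              object@N, min(object@decayA), max(object@decayA), object@eExt,
              object@eInh))
  cat(sprintf("  kernel widths: core %.3g, matrix %.3g (index units)\n",
              object@sigmas["core"], object@sigmas["matrix"]))
  cat(sprintf("  L5->CB+ / L6->PV+ ratio = %g; L5->TRN_M fraction = %g\n",
              object@l5CbOverL6Pv, object@l5TrnFraction))
  cat(sprintf("  local inhibition: core %s, matrix %s\n",
              object@localInhibition["core"], object@localInhibition["matrix"]))
  cat(sprintf("  cortical feedback: TC %s, TRN %s\n",
              object@corticalFeedbackTC, object@corticalFeedbackTRN))
  cat(sprintf("  mixing: %s (ratio %.2f, efficacy %.2f); transfer: %s\n",
              object@mixingMode, object@mixingRatio, object@mixingEfficacy,
              object@transfer))
})

#' WiredCircuit: the assembled network
#'
#' The fully wired network produced by [buildCircuit()]: one realised
#' [WeightMatrix-class] per active projection, together with the
#' configuration that produced it. Use [incomingProjections()] to audit the
#' signed projection set of a population.
#'
#' @slot config The [CircuitConfig-class] that was wired.
#' @slot kernels List of [ProjectionKernel-class] objects.
#' @slot weights List of N x N matrices, parallel to \code{kernels}.
#' @export
setClass("WiredCircuit",
  representation(config = "CircuitConfig", kernels = "list",
                 weights = "list"))

setMethod("show", "WiredCircuit", function(object) {
  cat(sprintf("WiredCircuit: %d populations of %d neurons, %d projections\n",
              length(circuitPopulations()), object@config@N,
              length(object@kernels)))
  for (k in object@kernels)
    cat(sprintf("  %-6s -> %-6s %-10s gain %.4g sigma %.3g eta %+d\n",
                k@pre, k@post, k@sign, k@gain, k@sigma, k@centerOffset))
})

#' StimulusProtocol: time-resolved external input to one population
#'
#' External drive delivered to one population, centred on one array index
#' with a Gaussian spatial profile. Three waveform kinds are supported:
#' \code{spindle_burst} (the spindle-like T-current-ramp-plus-burst train),
#' \code{tonic_square} and \code{pulse}. A positive \code{amplitude} feeds
#' the excitatory conductance of the target, a negative one the inhibitory
#' conductance.
#'
#' @slot target Population name.
#' @slot kind One of \code{spindle_burst}, \code{tonic_square}, \code{pulse}.
#' @slot onset Stimulus onset time, s.
#' @slot duration Stimulus duration, s (default 0.5).
#' @slot burstRate Burst rate in Hz for \code{spindle_burst} (default 10,
#'   i.e. 100 ms interburst interval).
#' @slot amplitude Peak amplitude in [-1, 1].
#' @slot centerIndex Stimulated array index (default 100).
#' @slot spatialSigma Gaussian spatial width of the delivery, index units.
#' @export
setClass("StimulusProtocol",
  representation(target = "character", kind = "character", onset = "numeric",
                 duration = "numeric", burstRate = "numeric",
                 amplitude = "numeric", centerIndex = "numeric",
                 spatialSigma = "numeric"))

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  if (!object@target %in% circuitPopulations())
    msg <- c(msg, sprintf("unknown target population '%s'", object@target))
  if (!object@kind %in% c("spindle_burst", "tonic_square", "pulse"))
    msg <- c(msg, "kind must be spindle_burst, tonic_square or pulse")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@burstRate <= 0) msg <- c(msg, "burstRate must be positive")
  if (abs(object@amplitude) > 1)
    msg <- c(msg, "amplitude must lie within [-1, 1]")
  if (object@spatialSigma <= 0) msg <- c(msg, "spatialSigma must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a StimulusProtocol
#'
#' @param target Population receiving the drive.
#' @param kind \code{"spindle_burst"}, \code{"tonic_square"} or
#'   \code{"pulse"}.
#' @param onset Onset time in seconds.
#' @param duration Duration in seconds (default 0.5 s).
#' @param burstRate Burst rate, Hz (default 10 Hz: 100 ms interburst
#'   interval, five bursts in 0.5 s).
#' @param amplitude Peak amplitude in [-1, 1]; negative values deliver the
#'   drive to the inhibitory conductance.
#' @param centerIndex Stimulated neuron index (default 100).
#' @param spatialSigma Spatial Gaussian width of delivery, index units.
#' @return A [StimulusProtocol-class] object.
#' @examples
#' stimulusProtocol("TRN_C", "spindle_burst")
#' @export
stimulusProtocol <- function(target, kind = c("spindle_burst", "tonic_square",
                                              "pulse"),
                             onset = 0, duration = 0.5, burstRate = 10,
                             amplitude = 1, centerIndex = 100,
                             spatialSigma = 3) {
  kind <- match.arg(kind)
  new("StimulusProtocol", target = target, kind = kind, onset = onset,
      duration = duration, burstRate = burstRate, amplitude = amplitude,
      centerIndex = centerIndex, spatialSigma = spatialSigma)
}

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf("StimulusProtocol: %s to %s, onset %g s, duration %g s,\n",
              object@kind, object@target, object@onset, object@duration))
  cat(sprintf("  amplitude %g at index %g (spatial sigma %g)", object@amplitude,
              object@centerIndex, object@spatialSigma))
  if (object@kind == "spindle_burst")
    cat(sprintf(", burst rate %g Hz", object@burstRate))
  cat("\n")
})

#' SpindleSimResult: voltage traces of one simulation
#'
#' Extends \linkS4class{SummarizedExperiment}: one assay per population,
#' each an N x (timesteps + 1) matrix of dimensionless activities bounded in
#' [-1, 1]; \code{colData} carries the uniform time axis and
#' \code{metadata()} the [CircuitConfig-class] and the stimulus protocols
#' that produced the run.
#'
#' @export
setClass("SpindleSimResult", contains = "SummarizedExperiment")

setMethod("show", "SpindleSimResult", function(object) {
  tt <- simTime(object)
  cat(sprintf("SpindleSimResult: %d populations x %d neurons x %d samples\n",
              length(SummarizedExperiment::assayNames(object)), nrow(object),
              ncol(object)))
  cat(sprintf("  t = [0, %g] s at dt = %g s; activity range [%.3g, %.3g]\n",
              max(tt), timeStep(object),
              min(vapply(SummarizedExperiment::assays(object), min, 0)),
              max(vapply(SummarizedExperiment::assays(object), max, 0))))
})

#' SpindleReport: the analysis layer's summary of one condition
#'
#' @slot sti Data frame of spindle tendency indices (population, neuron
#'   index, STI seconds).
#' @slot thetaDeg Similarity angle against a named baseline (degrees), or
#'   \code{NA} when no baseline applies.
#' @slot baseline Name of the baseline condition the angle refers to.
#' @slot latencies Named numeric of onset times per probe site (s).
#' @slot condition Preset or condition label.
#' @export
setClass("SpindleReport",
  representation(sti = "data.frame", thetaDeg = "numeric",
                 baseline = "character", latencies = "numeric",
                 condition = "character"))

setMethod("show", "SpindleReport", function(object) {
  cat(sprintf("SpindleReport: condition '%s'\n", object@condition))
  for (i in seq_len(nrow(object@sti)))
    cat(sprintf("  STI[%s @ %d] = %.3g s\n", object@sti$population[i],
                object@sti$neuron[i], object@sti$sti[i]))
  if (!is.na(object@thetaDeg))
    cat(sprintf("  theta = %.2f deg vs baseline '%s'\n", object@thetaDeg,
                object@baseline))
  if (length(object@latencies))
    cat("  onsets (s):", paste(sprintf("%s=%.3g", names(object@latencies),
                                       object@latencies), collapse = ", "),
        "\n")
})
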