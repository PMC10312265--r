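#' @include AllClasses.R circuit.R stimuli.R
#' @useDynLib spindleloop, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Which projections transmit half-wave rectified rates. Under the default
# "mixed" rule only the descending corticothalamic feedback onto relay
# neurons (L6 -> PV+, L5 -> CB+) is half-wave rectified: cortical
# pyramidal cells are near-silent at rest, so their feedback is purely
# phasic-excitatory. Every within-loop interaction rides on the tonic
# activity of thalamic and reticular populations and transmits signed
# deviations from that operating point (the negative part routes to the
# opposite conductance: disinhibitory rebound drive).
.projectionRectified <- function(config, preNames, postNames) {
  cortical <- names(.popRoles)[.popRoles == "cortical"]
  relay <- c("CB+", "PV+")
  switch(config@transfer,
         signed = rep(FALSE, length(preNames)),
         rectified = rep(TRUE, length(preNames)),
         mixed = preNames %in% cortical & postNames %in% relay)
}

#' Right-hand side of the shunting membrane equation
#'
#' The single-compartment shunting (on-center, off-surround) rate equation
#' \deqn{\frac{dv}{dt} = -A v - (v - E_{ext})\,I_{ext} - (v - E_{inh})\,I_{inh}}
#' The leak \eqn{-Av} returns the activity to rest when no input is
#' present; the two conductance terms multiplicatively gate the distance to
#' the reversal potentials, so with non-negative drives every trajectory
#' started inside \eqn{[E_{inh}, E_{ext}]} stays there.
#'
#' @param v Activity (vectorised).
#' @param iExt,iInh Non-negative excitatory / inhibitory drives.
#' @param A Leak rate, 1/s.
#' @param eExt,eInh Reversal potentials (defaults +1 / -1).
#' @return The rate of change \eqn{dv/dt}.
#' @examples
#' shuntingDerivative(0, 0, 0, A = 10)                  # rest is fixed
#' # fixed point: v* = (Eext Iext + Einh Iinh) / (A + Iext + Iinh)
#' shuntingDerivative(0.5, 1, 0, A = 1)                 # 0 at v* = 0.5
#' @export
shuntingDerivative <- function(v, iExt, iInh, A, eExt = 1, eInh = -1) {
  -A * v - (v - eExt) * iExt - (v - eInh) * iInh
}

#' Summed synaptic drives onto every population
#'
#' Applies every wired projection to a full set of population states and
#' accumulates the excitatory and inhibitory conductances per the
#' circuit's connectivity table. Under the default \code{"signed"} transfer
#' rule each projection's Gaussian-summed drive is signed: its positive
#' part gates the conductance matching the projection sign and its negative
#' part the opposite one (so a reticular pool falling below rest
#' disinhibits, i.e. excites, its thalamic targets -- the rebound drive).
#' Under \code{"rectified"} transfer presynaptic activities enter as
#' \eqn{[v]_+} and negative activities transmit nothing. Both rules return
#' non-negative conductances.
#'
#' @param circuit A [WiredCircuit-class].
#' @param states N x 10 numeric matrix of activities, columns in
#'   [circuitPopulations()] order (a named list of length-N vectors is also
#'   accepted).
#' @return List with N x 10 matrices \code{iExt} and \code{iInh}.
#' @export
populationInputs <- function(circuit, states) {
  stopifnot(is(circuit, "WiredCircuit"))
  pops <- circuitPopulations()
  if (is.list(states))
    states <- do.call(cbind, states[pops])
  if (!is.matrix(states) || ncol(states) != length(pops) ||
      nrow(states) != circuit@config@N)
    stop("internal error: states must be an N x 10 matrix", call. = FALSE)
  colnames(states) <- pops
  iExt <- matrix(0, nrow(states), ncol(states), dimnames = dimnames(states))
  iInh <- iExt
  rectified <- .projectionRectified(circuit@config,
                                    vapply(circuit@kernels,
                                           function(k) k@pre, ""),
                                    vapply(circuit@kernels,
                                           function(k) k@post, ""))
  for (k in seq_along(circuit@kernels)) {
    kern <- circuit@kernels[[k]]
    vpre <- states[, kern@pre]
    d <- if (rectified[k]) circuit@weights[[k]] %*% pmax(vpre, 0)
         else circuit@weights[[k]] %*% vpre
    d <- drop(d)
    if (kern@sign == "excitatory") {
      iExt[, kern@post] <- iExt[, kern@post] + pmax(d, 0)
      if (!rectified[k]) iInh[, kern@post] <- iInh[, kern@post] + pmax(-d, 0)
    } else {
      iInh[, kern@post] <- iInh[, kern@post] + pmax(d, 0)
      if (!rectified[k]) iExt[, kern@post] <- iExt[, kern@post] + pmax(-d, 0)
    }
  }
  list(iExt = iExt, iInh = iInh)
}

#' Integrate the circuit under a stimulus protocol
#'
#' Deterministic fixed-step integration (Heun's explicit trapezoid rule) of
#' the shunting equation for all ten populations from rest. External
#' stimuli are rendered onto the time grid, spread spatially with a
#' Gaussian profile around their center index, scaled by the config's
#' \code{stimGain}, and fed into the excitatory (positive amplitude) or
#' inhibitory (negative amplitude) conductance of the target population.
#'
#' @param circuit A [WiredCircuit-class].
#' @param protocol A [StimulusProtocol-class] or a list of them; an empty
#'   list simulates the free network.
#' @param T Total simulated time, s; must exceed every stimulus window.
#' @param dt Step size, s (default 0.5 ms; must be <= 1 ms).
#' @return A \linkS4class{SpindleSimResult}.
#' @examples
#' wc <- buildCircuit(defaultConfig(N = 40))
#' res <- integrateCircuit(wc, list(), T = 0.1)
#' max(abs(traces(res, "PV+")))   # no input: stays at rest
#' @export
integrateCircuit <- function(circuit, protocol, T = 2, dt = 5e-4) {
  stopifnot(is(circuit, "WiredCircuit"))
  if (is(protocol, "StimulusProtocol")) protocol <- list(protocol)
  if (dt > 1e-3)
    stop("configuration error: dt must be <= 1 ms", call. = FALSE)
  for (p in protocol) {
    validObject(p)
    if (T <= p@onset + p@duration)
      stop("T must exceed the stimulus window (onset + duration)",
           call. = FALSE)
  }
  config <- circuit@config
  N <- config@N
  pops <- circuitPopulations()
  nsteps <- round(T / dt)

  stimDrive <- list()
  stimTarget <- integer()
  for (p in protocol) {
    w <- .protocolWaveform(p, nsteps, dt)
    idx <- seq_len(N)
    sp <- exp(-0.5 * ((idx - p@centerIndex) / p@spatialSigma)^2)
    stimDrive[[length(stimDrive) + 1L]] <-
      outer(sp, w) * (config@stimGain * p@amplitude)
    stimTarget <- c(stimTarget, match(p@target, pops) - 1L)
  }

  preIdx <- vapply(circuit@kernels, function(k) match(k@pre, pops), 0L) - 1L
  postIdx <- vapply(circuit@kernels, function(k) match(k@post, pops), 0L) - 1L
  sgn <- vapply(circuit@kernels,
                function(k) if (k@sign == "excitatory") 1L else -1L, 0L)
  # Toeplitz structure: each Gaussian weight matrix acts as a 1-D
  # convolution with this kernel vector (support truncated at 6 sigma)
  kernelVecs <- lapply(circuit@kernels, function(k) {
    K <- ceiling(6 * k@sigma)
    k@gain * stats::dnorm(seq(-K, K), 0, k@sigma)
  })
  offsets <- vapply(circuit@kernels, function(k) k@centerOffset, 0L)
  rectified <- .projectionRectified(config,
                                    vapply(circuit@kernels,
                                           function(k) k@pre, ""),
                                    vapply(circuit@kernels,
                                           function(k) k@post, ""))

  decay <- if (length(config@decayA) == 1L)
    rep(config@decayA, length(pops)) else unname(config@decayA[pops])

  out <- integrate_heun_cpp(kernelVecs, offsets, preIdx, postIdx, sgn,
                            rectified, decay, config@eExt, config@eInh,
                            stimDrive, stimTarget, N, length(pops), nsteps,
                            dt)

  assays <- lapply(seq_along(pops), function(p) out[, p, ])
  names(assays) <- pops
  tt <- seq(0, by = dt, length.out = nsteps + 1)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(time = tt),
    metadata = list(config = config, protocol = protocol, dt = dt))
  new("SpindleSimResult", se)
}
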