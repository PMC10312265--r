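#' @include AllClasses.R
NULL

#' Spindle-like burst input waveform
#'
#' Builds the spindle-pattern drive used to entrain the model TRN: one cycle
#' per burst period (100 ms at the default 10 Hz rate), each cycle composed
#' of a slow-then-sharp sixth-power ramp (the T-current analogue occupying
#' \code{rampFraction} of the cycle) followed by a densely packed spike-like
#' burst of five triangular peaks with heights decreasing 1.00, 0.98, 0.96,
#' 0.94, 0.92. All values lie in [0, 1]; the per-spike peak detail is
#' cosmetic and has no effect on the circuit dynamics, only the 100 ms
#' envelope timing is functionally relevant.
#'
#' @param burstRate Bursts per second (default 10: 100 ms interburst
#'   interval, five bursts in the default 0.5 s).
#' @param duration Total waveform duration, s.
#' @param dt Sample step, s; must be <= 2 ms to render the spikes.
#' @param rampFraction Fraction of each cycle occupied by the polynomial
#'   ramp (default 0.6).
#' @param rampPeak Ramp level reached just before the burst (default 0.3).
#' @return Numeric vector of length \code{round(duration / dt)} sampled at
#'   \code{t = 0, dt, 2 dt, ...} from stimulus onset.
#' @examples
#' w <- makeSpindleInput(dt = 5e-4)
#' length(w)   # 1000 samples: 0.5 s at 0.5 ms
#' range(w)
#' @export
makeSpindleInput <- function(burstRate = 10, duration = 0.5, dt = 5e-4,
                             rampFraction = 0.6, rampPeak = 0.3) {
  if (burstRate <= 0) stop("burstRate must be positive", call. = FALSE)
  if (dt > 2e-3)
    stop("configuration error: dt too coarse to render burst spikes ",
         "(needs dt <= 2 ms)", call. = FALSE)
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  cycle <- 1 / burstRate
  # time within the current cycle, guarded against floating-point wobble
  # at the cycle boundaries
  tc <- t - floor(t / cycle + 1e-9) * cycle
  tc[tc < 0] <- 0
  rampLen <- rampFraction * cycle
  peaks <- c(1.00, 0.98, 0.96, 0.94, 0.92)
  spikeLen <- (cycle - rampLen) / length(peaks)
  w <- numeric(n)
  inRamp <- tc < rampLen
  w[inRamp] <- rampPeak * (tc[inRamp] / rampLen)^6
  tb <- tc[!inRamp] - rampLen           # time within the burst window
  spike <- pmin(floor(tb / spikeLen) + 1, length(peaks))
  phase <- (tb - (spike - 1) * spikeLen) / spikeLen   # 0..1 across a spike
  w[!inRamp] <- peaks[spike] * (1 - abs(2 * phase - 1))
  w
}

#' Tonic square and pulse input waveforms
#'
#' Square waveforms: \code{amplitude} inside the window, 0 outside (the
#' window is the whole returned vector; placement on the time axis is done
#' by the stimulus onset).
#'
#' @param duration,width Window length, s.
#' @param amplitude Constant value inside the window.
#' @param dt Sample step, s.
#' @return Numeric vector of length \code{round(duration / dt)}.
#' @examples
#' sum(makeTonicInput(0.5, 1, dt = 5e-4) != 0)   # 1000 nonzero samples
#' @export
makeTonicInput <- function(duration, amplitude = 1, dt = 5e-4) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  rep(amplitude, round(duration / dt))
}

#' @rdname makeTonicInput
#' @export
makePulseInput <- function(width, amplitude = 1, dt = 5e-4) {
  if (width <= 0) stop("width must be positive", call. = FALSE)
  rep(amplitude, max(round(width / dt), 0))
}

# Render a protocol onto the full simulation grid (nsteps + 1 samples):
# returns the temporal waveform w(t), unit peak, zero outside the window.
.protocolWaveform <- function(protocol, nsteps, dt) {
  w <- numeric(nsteps + 1)
  startIdx <- round(protocol@onset / dt) + 1
  inner <- switch(protocol@kind,
    spindle_burst = makeSpindleInput(protocol@burstRate, protocol@duration,
                                     dt),
    tonic_square = makeTonicInput(protocol@duration, 1, dt),
    pulse = makePulseInput(protocol@duration, 1, dt))
  idx <- seq(startIdx, length.out = length(inner))
  idx <- idx[idx <= nsteps + 1]
  w[idx] <- inner[seq_along(idx)]
  w
}
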