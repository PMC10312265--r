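#' @include AllClasses.R
#' @importFrom stats rnorm
NULL

#' Synthetic single-neuron traces for testing the analysis layer
#'
#' Deterministic (seeded) generator of voltage-like test traces with known
#' closed forms, used to validate the analysis operations independently of
#' the circuit simulator: \code{damped_cosine}
#' \eqn{a\,e^{-(t - t_0)/\tau}\cos(2\pi f (t - t_0))} after \code{tOff}
#' (constant \code{a} before it, so the driven-epoch maximum is known),
#' \code{pure_tone}, \code{step}, and white \code{noise}.
#'
#' @param kind One of \code{damped_cosine}, \code{pure_tone}, \code{step},
#'   \code{noise}.
#' @param T Total duration, s.
#' @param dt Sample step, s.
#' @param freq Oscillation frequency, Hz.
#' @param tau Envelope decay constant, s.
#' @param amplitude Peak amplitude.
#' @param tOff Shutdown time for \code{damped_cosine} / \code{step}, s.
#' @param seed Integer seed for \code{noise}.
#' @return Numeric trace of length \code{round(T / dt) + 1} sampled from
#'   t = 0.
#' @examples
#' v <- makeFixture("damped_cosine", freq = 10, tau = 0.15)
#' @export
makeFixture <- function(kind = c("damped_cosine", "pure_tone", "step",
                                 "noise"),
                        T = 2, dt = 5e-4, freq = 10, tau = 0.15,
                        amplitude = 0.5, tOff = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  t <- seq(0, T, by = dt)
  switch(kind,
    damped_cosine = ifelse(t <= tOff, amplitude,
                           amplitude * exp(-(t - tOff) / tau) *
                             cos(2 * pi * freq * (t - tOff))),
    pure_tone = amplitude * sin(2 * pi * freq * t),
    step = ifelse(t <= tOff, amplitude, 0),
    noise = {
      set.seed(as.integer(seed))
      stats::rnorm(length(t), sd = amplitude)
    })
}
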