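#' @include AllClasses.R
NULL

#' Gaussian connection weight between two array positions
#'
#' Weight of presynaptic neuron \code{j} onto postsynaptic neuron \code{i}:
#' a unit-mass Gaussian in the index distance, centred at \code{i +
#' centerOffset},
#' \deqn{w_{ji} = \frac{1}{\sigma\sqrt{2\pi}}
#'       \exp\!\left(-\tfrac12\Big(\frac{j - (i + \eta)}{\sigma}\Big)^2\right)}
#' With \code{centerOffset = 0} the profile is symmetric about the
#' postsynaptic index and the reticulo-thalamic loop is the balanced hybrid
#' (closed-equivalent) loop; a nonzero offset shifts the peak and opens the
#' loop.
#'
#' @param j Presynaptic index (vectorised).
#' @param i Postsynaptic index.
#' @param sigma Positive Gaussian width, index units.
#' @param centerOffset Integer center shift (eta).
#' @return Non-negative weight(s); the peak value is
#'   \eqn{1/(\sigma\sqrt{2\pi})}.
#' @examples
#' gaussianWeight(10, 10, sigma = 1)          # 1/sqrt(2*pi)
#' gaussianWeight(13, 10, sigma = 2, centerOffset = 3)  # shifted peak
#' @export
gaussianWeight <- function(j, i, sigma, centerOffset = 0L) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("configuration error: sigma must be positive", call. = FALSE)
  z <- (j - (i + centerOffset)) / sigma
  exp(-0.5 * z^2) / (sigma * sqrt(2 * pi))
}

#' Realise a projection kernel as an N x N weight matrix
#'
#' Evaluates the Gaussian profile of a [ProjectionKernel-class] on an
#' N-neuron array, scaled by the kernel gain. Row i holds the weights onto
#' postsynaptic neuron i; its interior maximum sits at column
#' \code{i + centerOffset}. Profiles are truncated at the array edges (no
#' wraparound, no renormalisation).
#'
#' @param kernel A [ProjectionKernel-class].
#' @param N Population size (>= 1).
#' @return A [WeightMatrix-class].
#' @examples
#' k <- projectionKernel("PV+", "TRN_C", gain = 1, sigma = 1,
#'                       sign = "excitatory")
#' W <- buildWeightMatrix(k, 5)
#' @export
buildWeightMatrix <- function(kernel, N) {
  stopifnot(is(kernel, "ProjectionKernel"))
  N <- as.integer(N)
  if (is.na(N) || N < 1L)
    stop("configuration error: N must be >= 1", call. = FALSE)
  j <- seq_len(N)
  vals <- vapply(seq_len(N), function(i)
    kernel@gain * gaussianWeight(j, i, kernel@sigma, kernel@centerOffset),
    numeric(N))
  # vapply fills columns by postsynaptic index: transpose to rows = post
  new("WeightMatrix", values = t(vals), pre = kernel@pre, post = kernel@post)
}

#' Classify a reticulo-thalamic kernel as closed-equivalent or open
#'
#' A reticulo-thalamic projection with a symmetric profile
#' (\code{centerOffset == 0}) is the balanced hybrid loop: two open loops in
#' opposite directions whose summed drive is functionally equivalent to a
#' closed loop. Any nonzero center shift makes it an open loop.
#'
#' @param kernel A [ProjectionKernel-class] between a TRN population and a
#'   thalamic population (either direction).
#' @return \code{"closed_equivalent"} or \code{"open"}.
#' @examples
#' loopCharacter(projectionKernel("TRN_C", "PV+", 60, 3,
#'                                sign = "inhibitory"))
#' @export
loopCharacter <- function(kernel) {
  stopifnot(is(kernel, "ProjectionKernel"))
  trn <- c("TRN_M", "TRN_C")
  thal <- c("CB+", "PV+", "CB-", "PV-")
  isLoop <- (kernel@pre %in% trn && kernel@post %in% thal) ||
    (kernel@pre %in% thal && kernel@post %in% trn)
  if (!isLoop)
    stop("loopCharacter applies to TRN <-> thalamus projections",
         call. = FALSE)
  if (kernel@centerOffset == 0L) "closed_equivalent" else "open"
}
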