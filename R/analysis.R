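#' @include AllClasses.R AllGenerics.R
#' @importFrom stats filter
NULL

#' Spindle tendency index (STI)
#'
#' Total duration, in seconds, of the above-threshold sequence of
#' hyperpolarization / rebound-depolarization events after input shutdown.
#' Local depolarization maxima after \code{tOff} are detected by three-point
#' comparison on a lightly smoothed copy of the trace (5-sample moving
#' average); a maximum counts as a rebound iff its peak reaches
#' \code{thresholdFrac} (default 1\%) of the neuron's maximum activity level
#' (\code{max(abs(trace))} over the whole trace, driven epoch included, or
#' the externally supplied \code{refMax}). The index runs from the
#' shutdown-adjacent hyperpolarization onset (first drop below rest after
#' \code{tOff}) to the last counted rebound's return below threshold, and is
#' 0 when no rebound qualifies.
#'
#' @param trace Single-neuron activity series on a uniform grid starting at
#'   t = 0.
#' @param tOff Input shutdown time, s.
#' @param dt Sample step of the trace, s.
#' @param thresholdFrac Rebound threshold as a fraction of the maximum
#'   activity level, in (0, 1); default 0.01.
#' @param refMax Optional externally fixed maximum activity level (e.g. a
#'   global maximum across populations); default is the per-neuron maximum.
#' @param smoothWidth Moving-average width (samples) for peak detection.
#' @return STI in seconds (>= 0).
#' @examples
#' t <- seq(0, 2, by = 5e-4)
#' v <- ifelse(t > 0.5, 0.5 * exp(-(t - 0.5)/0.15) * cos(2*pi*10*(t - 0.5)), 0.5)
#' computeSTI(v, tOff = 0.5, dt = 5e-4)
#' @export
computeSTI <- function(trace, tOff, dt, thresholdFrac = 0.01, refMax = NULL,
                       smoothWidth = 5) {
  n <- length(trace)
  if (tOff >= (n - 1) * dt)
    stop("argument error: trace does not extend beyond tOff", call. = FALSE)
  if (thresholdFrac <= 0 || thresholdFrac >= 1)
    stop("argument error: thresholdFrac must lie in (0, 1)", call. = FALSE)
  vmax <- if (is.null(refMax)) max(abs(trace)) else refMax
  if (vmax == 0) return(0)
  thr <- thresholdFrac * vmax

  sm <- as.numeric(stats::filter(trace, rep(1 / smoothWidth, smoothWidth),
                                 sides = 2))
  sm[is.na(sm)] <- trace[is.na(sm)]

  iOff <- floor(tOff / dt) + 1L
  idx <- seq(iOff + 1L, n - 1L)
  isPeak <- sm[idx] >= sm[idx - 1L] & sm[idx] > sm[idx + 1L]
  peaks <- idx[isPeak & sm[idx] >= thr]
  if (!length(peaks)) return(0)

  neg <- which(trace[(iOff + 1L):n] < 0)
  tStart <- if (length(neg)) (iOff + neg[1L] - 1L) * dt else tOff

  last <- peaks[length(peaks)]
  below <- which(sm[(last + 1L):n] < thr)
  tEnd <- if (length(below)) (last + below[1L] - 1L) * dt else (n - 1L) * dt
  max(tEnd - tStart, 0)
}

#' Sigma-band (5-15 Hz) band-pass check
#'
#' Zero-phase 4th-order Butterworth band-pass of a trace, used to confirm
#' that post-shutdown activity is genuine spindle-band oscillation: ordinal
#' STI comparisons on the filtered traces agree with the raw-trace
#' comparisons across conditions.
#'
#' @param trace Activity series.
#' @param fs Sampling rate, Hz; must exceed twice the upper band edge.
#' @param low,high Band edges, Hz (defaults 5 and 15).
#' @param order Butterworth order (default 4).
#' @return List with \code{filtered} (zero-phase filtered series) and
#'   \code{power} (its mean square).
#' @examples
#' t <- seq(0, 2, by = 5e-4)
#' out <- bandpassCheck(sin(2 * pi * 10 * t), fs = 2000)
#' out$power        # ~0.5: a 10 Hz tone passes at unit gain
#' @export
bandpassCheck <- function(trace, fs, low = 5, high = 15, order = 4) {
  if (fs <= 2 * high)
    stop("argument error: sampling rate violates the Nyquist criterion ",
         "for the upper band edge", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filtered <- as.numeric(signal::filtfilt(bf, trace))
  list(filtered = filtered, power = mean(filtered^2))
}

#' Spatiotemporal activity map of one population
#'
#' The raw neuron-by-time activity matrix of one population (the quantity
#' rendered as a heat map); no normalisation is applied.
#'
#' @param result A \linkS4class{SpindleSimResult}.
#' @param population Population name.
#' @return Numeric matrix, rows = array neurons, columns = time samples.
#' @export
activityMap <- function(result, population) {
  stopifnot(is(result, "SpindleSimResult"))
  traces(result, population)
}

#' Similarity angle between two spatiotemporal maps
#'
#' Both maps are vectorised (neuron-major) and compared by the arc-cosine
#' of their cosine similarity:
#' \deqn{\theta = \arccos\frac{\vec A \cdot \vec B}{\|A\|\,\|B\|}}
#' in degrees. \eqn{\theta = 0} means the same spatiotemporal pattern up to
#' positive rescaling; 90 degrees orthogonal patterns; 180 degrees
#' sign-inverted ones.
#'
#' @param mapA,mapB Numeric matrices of identical shape, each with at least
#'   one nonzero entry.
#' @return The angle in degrees.
#' @examples
#' similarityAngle(diag(2), diag(2))                     # 0
#' similarityAngle(matrix(c(1,0,0,0), 2), matrix(c(1,0,1,0), 2))  # 45
#' @export
similarityAngle <- function(mapA, mapB) {
  if (!all(dim(mapA) == dim(mapB)))
    stop("argument error: maps must have the same shape", call. = FALSE)
  a <- as.numeric(mapA)
  b <- as.numeric(mapB)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("undefined-angle error: zero-norm map", call. = FALSE)
  acos(min(max(sum(a * b) / (na * nb), -1), 1)) * 180 / pi
}

#' Spindle onset latency at probe sites
#'
#' Onset is the first time the absolute activity of a probe neuron exceeds
#' \code{thresholdFrac} of the population's maximum activity (so all probe
#' sites share one threshold; \code{reference = "site"} uses each neuron's
#' own maximum instead). For a centred stimulus, onsets are non-decreasing
#' with distance from the stimulated index as the spindle tendency
#' propagates along the array; a site that never crosses threshold is
#' reported as \code{NA}, not an error.
#'
#' @param result A \linkS4class{SpindleSimResult}.
#' @param population Population name.
#' @param sites Probe neuron indices (defaults 100, 113, 128, 147).
#' @param thresholdFrac Onset threshold fraction (default 0.01).
#' @param reference \code{"population"} (default) or \code{"site"}:
#'   whether the threshold refers to the population-wide or the per-site
#'   maximum activity.
#' @return Named numeric vector of onset times (s), \code{NA} for silent
#'   sites.
#' @export
propagationLatencies <- function(result, population,
                                 sites = c(100, 113, 128, 147),
                                 thresholdFrac = 0.01,
                                 reference = c("population", "site")) {
  reference <- match.arg(reference)
  tr <- traces(result, population)
  if (any(sites < 1 | sites > nrow(tr)))
    stop("argument error: sites must lie within the array", call. = FALSE)
  tt <- simTime(result)
  popMax <- max(abs(tr))
  out <- vapply(sites, function(s) {
    v <- abs(tr[s, ])
    m <- if (reference == "population") popMax else max(v)
    if (m == 0) return(NA_real_)
    hit <- which(v > thresholdFrac * m)
    if (length(hit)) tt[hit[1L]] else NA_real_
  }, numeric(1))
  names(out) <- as.character(sites)
  out
}

#' Spatial spread (FWHM) of activity at one time
#'
#' Full width at half maximum of the absolute activity profile across the
#' neuron axis at the given time, in index units, with the half-maximum
#' crossings linearly interpolated between array positions (a single active
#' neuron therefore has FWHM 1).
#'
#' @param map Neuron-by-time activity matrix (see [activityMap()]).
#' @param atTime Time at which to evaluate, s.
#' @param dt Sample step of the map's time axis, s.
#' @return FWHM in index units, or \code{NA} for an all-zero column.
#' @export
spatialSpread <- function(map, atTime, dt) {
  col <- round(atTime / dt) + 1L
  if (col < 1L || col > ncol(map))
    stop("argument error: atTime outside the simulated window",
         call. = FALSE)
  p <- abs(map[, col])
  if (all(p == 0)) return(NA_real_)
  pk <- which.max(p)
  half <- p[pk] / 2

  crossing <- function(iOut, iIn) {
    # linear interpolation of the half-max crossing between two samples
    iOut + (half - p[iOut]) / (p[iIn] - p[iOut]) * (iIn - iOut)
  }
  leftBelow <- which(p[seq_len(pk - 1L)] < half)
  left <- if (length(leftBelow)) {
    i <- max(leftBelow)
    crossing(i, i + 1L)
  } else 1
  rightBelow <- which(p[seq(pk + 1L, length(p))] < half) + pk
  right <- if (pk < length(p) && length(rightBelow)) {
    i <- min(rightBelow)
    crossing(i, i - 1L)
  } else length(p)
  right - left
}
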