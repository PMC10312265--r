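dtA <- 5e-4

# independent STI oracle: literal peak scan on the raw trace, no smoothing
stiOracle <- function(v, tOff, dt, frac = 0.01) {
  thr <- frac * max(abs(v))
  iOff <- floor(tOff / dt) + 1
  idx <- seq(iOff + 1, length(v) - 1)
  peaks <- idx[v[idx] >= v[idx - 1] & v[idx] > v[idx + 1] &
                 v[idx] >= thr]
  if (!length(peaks)) return(0)
  neg <- which(v[(iOff + 1):length(v)] < 0)
  tStart <- if (length(neg)) (iOff + neg[1] - 1) * dt else tOff
  last <- max(peaks)
  below <- which(v[(last + 1):length(v)] < thr)
  tEnd <- if (length(below)) (last + below[1] - 1) * dt
          else (length(v) - 1) * dt
  tEnd - tStart
}

test_that("STI agrees with the peak-scan oracle on damped cosines", {
  for (tau in c(0.1, 0.15, 0.25)) {
    v <- makeFixture("damped_cosine", T = 2, dt = dtA, freq = 10,
                     tau = tau, amplitude = 0.5, tOff = 0.5)
    expect_equal(computeSTI(v, 0.5, dtA), stiOracle(v, 0.5, dtA),
                 tolerance = 0.02 / stiOracle(v, 0.5, dtA),
                 info = sprintf("tau = %g", tau))
  }

  # analytic cross-check: with threshold 1% of 0.5, rebound peaks at
  # multiples of 0.1 s qualify while 0.5 exp(-k/ (10 tau)) >= 0.005
  tau <- 0.15
  v <- makeFixture("damped_cosine", T = 2, dt = dtA, freq = 10,
                   tau = tau, amplitude = 0.5, tOff = 0.5)
  lastPeak <- 0.1 * floor(tau * log(100) / 0.1)
  sti <- computeSTI(v, 0.5, dtA)
  expect_gt(sti, lastPeak - 0.05)
  expect_lt(sti, lastPeak + 0.1)
})

test_that("STI handles degenerate traces and bad arguments", {
  flat <- rep(0, 4001)
  expect_equal(computeSTI(flat, 0.5, dtA), 0)

  # a trace that never rebounds above threshold after shutdown
  v <- makeFixture("step", T = 2, dt = dtA, amplitude = 0.8, tOff = 0.5)
  expect_equal(computeSTI(v, 0.5, dtA), 0)

  expect_error(computeSTI(rep(0, 100), 0.5, dtA), "tOff")
  expect_error(computeSTI(flat, 0.5, dtA, thresholdFrac = 0), "threshold")
  expect_error(computeSTI(flat, 0.5, dtA, thresholdFrac = 1), "threshold")
})

test_that("STI ranking is robust to the threshold fraction", {
  # faster-decaying envelopes must rank below slower ones at thresholds
  # anywhere between 0.5% and 2%
  taus <- c(0.08, 0.15, 0.3)
  for (frac in c(0.005, 0.01, 0.02)) {
    stis <- vapply(taus, function(tau)
      computeSTI(makeFixture("damped_cosine", T = 2, dt = dtA, freq = 10,
                             tau = tau, amplitude = 0.5, tOff = 0.5),
                 0.5, dtA, thresholdFrac = frac), 0)
    expect_true(all(diff(stis) > 0),
                info = sprintf("thresholdFrac = %g", frac))
  }
})

test_that("the sigma band-pass has the specified frequency response", {
  fs <- 1 / dtA
  t <- seq(0, 4, by = dtA)

  tone10 <- bandpassCheck(sin(2 * pi * 10 * t), fs = fs)
  mid <- seq(length(t) %/% 4, 3 * length(t) %/% 4)
  expect_equal(max(abs(tone10$filtered[mid])), 1, tolerance = 0.01)

  drift <- bandpassCheck(sin(2 * pi * 1 * t), fs = fs)
  atten <- 20 * log10(max(abs(drift$filtered[mid])))
  expect_lt(atten, -20)

  const <- bandpassCheck(rep(0.7, length(t)), fs = fs)
  expect_lt(abs(mean(const$filtered[mid])), 1e-6)

  expect_error(bandpassCheck(sin(t), fs = 25), "Nyquist")
})

test_that("similarity angle satisfies its identities", {
  set.seed(3)
  A <- matrix(rnorm(60), 6, 10)
  B <- matrix(rnorm(60), 6, 10)

  expect_equal(similarityAngle(A, A), 0, tolerance = 1e-5)
  expect_equal(similarityAngle(A, -A), 180, tolerance = 1e-5)
  expect_equal(similarityAngle(A, B), similarityAngle(B, A))
  # invariance to positive rescaling of either operand
  expect_equal(similarityAngle(A, B), similarityAngle(2.5 * A, 0.3 * B))

  # orthogonal patterns meet at 90 degrees
  E1 <- matrix(c(1, 0, 0, 0), 2)
  E2 <- matrix(c(0, 1, 0, 0), 2)
  expect_equal(similarityAngle(E1, E2), 90)

  # hand-computed example: dot product 1, norms 1 and sqrt(2)
  expect_equal(similarityAngle(matrix(c(1, 0, 0, 0), 2),
                               matrix(c(1, 1, 0, 0), 2)), 45)

  expect_error(similarityAngle(A, matrix(0, 6, 10)), "zero-norm")
  expect_error(similarityAngle(A, matrix(1, 3, 3)), "shape")
})

test_that("activity maps are raw traces with the contract shape", {
  wc <- buildCircuit(smallConfig(N = 40))
  res <- integrateCircuit(wc, list(), T = 0.2)
  m <- activityMap(res, "PV+")
  expect_identical(dim(m), c(40L, as.integer(0.2 / dtA) + 1L))
  expect_true(all(m == 0))
  expect_error(activityMap(res, "L9"), "population")

  # locality: the stimulated row reaches an extremum before distant rows
  stim <- integrateCircuit(
    wc, stimulusProtocol("TRN_C", "pulse", duration = 0.05,
                         centerIndex = 20), T = 0.5)
  mm <- abs(activityMap(stim, "PV+"))
  onset <- apply(mm, 1, function(r) {
    hit <- which(r > 0.01 * max(mm))
    if (length(hit)) hit[1] else NA_integer_
  })
  expect_equal(unname(onset[20]), min(onset, na.rm = TRUE))
})

test_that("propagation onsets order by distance and translate", {
  wc <- buildCircuit(defaultConfig(N = 120,
                                   mixingMode = "thalamoreticular"))
  prot <- list(
    stimulusProtocol("TRN_C", "spindle_burst", centerIndex = 60),
    stimulusProtocol("TRN_M", "spindle_burst", centerIndex = 60))
  res <- integrateCircuit(wc, prot, T = 1.2)
  sites <- c(60, 68, 76, 88)
  lat <- propagationLatencies(res, "PV+", sites = sites)
  expect_false(anyNA(lat))
  expect_true(all(diff(lat) >= 0))
  expect_equal(unname(which.min(lat)), 1L)

  # translation equivariance away from the edges
  prot2 <- list(
    stimulusProtocol("TRN_C", "spindle_burst", centerIndex = 50),
    stimulusProtocol("TRN_M", "spindle_burst", centerIndex = 50))
  res2 <- integrateCircuit(wc, prot2, T = 1.2)
  lat2 <- propagationLatencies(res2, "PV+", sites = sites - 10)
  expect_equal(unname(lat2), unname(lat), tolerance = 0.05)

  # a silent site reports NA rather than an error
  silent <- resultFromTraces(list("PV+" = matrix(0, 10, 100)))
  expect_true(is.na(propagationLatencies(silent, "PV+", sites = 5)))
  expect_error(propagationLatencies(res, "PV+", sites = 500), "sites")
})

test_that("spatial spread recovers closed-form widths", {
  # single active neuron: FWHM is one index unit
  m <- matrix(0, 21, 3)
  m[11, 2] <- 0.8
  expect_equal(spatialSpread(m, atTime = dtA, dt = dtA), 1)

  # Gaussian profile of known sigma: FWHM = 2 sqrt(2 ln 2) sigma
  sigma <- 5
  prof <- exp(-0.5 * ((1:101 - 51) / sigma)^2)
  mg <- cbind(prof, prof)
  expect_equal(spatialSpread(mg, atTime = 0, dt = dtA),
               2 * sqrt(2 * log(2)) * sigma, tolerance = 0.02)

  expect_true(is.na(spatialSpread(matrix(0, 5, 2), 0, dtA)))
  expect_error(spatialSpread(mg, atTime = 1, dt = dtA), "atTime")
})
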