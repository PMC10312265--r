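test_that("shunting derivative has the closed-form fixed point", {
  # rest is a fixed point with no input
  expect_equal(shuntingDerivative(0, 0, 0, A = 10), 0)

  # at the excitatory reversal potential the derivative cannot be positive
  expect_equal(shuntingDerivative(1, iExt = 5, iInh = 0, A = 2), -2)
  expect_lt(shuntingDerivative(1, iExt = 100, iInh = 0, A = 2), 0)

  # v* = (Eext Iext + Einh Iinh) / (A + Iext + Iinh)
  expect_equal(shuntingDerivative(0.5, 1, 0, A = 1), 0)
  for (case in list(c(A = 2, ie = 3, ii = 1), c(A = 8, ie = 0.5, ii = 2))) {
    vstar <- (case["ie"] - case["ii"]) / (case["A"] + case["ie"] +
                                            case["ii"])
    expect_equal(shuntingDerivative(vstar, case["ie"], case["ii"],
                                    case["A"]),
                 unname(c(A = 0)), ignore_attr = TRUE)
  }
})

test_that("population inputs match brute-force summation on a toy array", {
  cfg <- smallConfig(N = 3, localInhibition = c(core = TRUE, matrix = TRUE),
                     corticalFeedbackTC = TRUE)
  wc <- buildCircuit(cfg)
  set.seed(5)
  states <- matrix(runif(30, -0.5, 0.5), 3, 10,
                   dimnames = list(NULL, circuitPopulations()))

  inputs <- populationInputs(wc, states)
  expect_true(all(inputs$iExt >= 0) && all(inputs$iInh >= 0))

  # independent oracle: accumulate dnorm-weighted sums per kernel with
  # the same routing rules, written out longhand
  rect <- spindleloop:::.projectionRectified(
    cfg, vapply(wc@kernels, function(k) k@pre, ""),
    vapply(wc@kernels, function(k) k@post, ""))
  ie <- matrix(0, 3, 10, dimnames = list(NULL, circuitPopulations()))
  ii <- ie
  for (q in seq_along(wc@kernels)) {
    k <- wc@kernels[[q]]
    for (i in 1:3) {
      d <- 0
      for (j in 1:3) {
        vj <- states[j, k@pre]
        if (rect[q]) vj <- max(vj, 0)
        d <- d + bruteWeight(j, i, k@sigma, k@centerOffset, k@gain) * vj
      }
      if (k@sign == "excitatory") {
        ie[i, k@post] <- ie[i, k@post] + max(d, 0)
        if (!rect[q]) ii[i, k@post] <- ii[i, k@post] + max(-d, 0)
      } else {
        ii[i, k@post] <- ii[i, k@post] + max(d, 0)
        if (!rect[q]) ie[i, k@post] <- ie[i, k@post] + max(-d, 0)
      }
    }
  }
  expect_equal(inputs$iExt, ie)
  expect_equal(inputs$iInh, ii)

  # all-zero states give zero drive
  zero <- populationInputs(wc, matrix(0, 3, 10))
  expect_true(all(zero$iExt == 0) && all(zero$iInh == 0))
})

test_that("spindle input renders 10 Hz bursts over 0.5 s", {
  dt <- 5e-4
  w <- makeSpindleInput(burstRate = 10, duration = 0.5, dt = dt)
  expect_length(w, 1000)
  expect_gte(min(w), -1)
  expect_lte(max(w), 1)
  expect_gte(min(w), 0)

  # burst-onset detector on the generated waveform: a cycle onset is a
  # zero followed by the slow polynomial ramp (still near zero 12 ms
  # later), unlike the spike-boundary zeros inside the burst
  cand <- which(w[-length(w)] == 0 & w[-1] > 0)
  onsets <- cand[w[pmin(cand + 25, length(w))] < 0.01]
  expect_length(onsets, 5)
  expect_true(all(abs(diff(onsets) * dt - 0.1) <= 2 * dt))

  # the per-cycle ramp rises slowly then sharply before the burst
  ramp <- w[1:120]
  expect_true(all(diff(ramp) >= 0))
  expect_lt(mean(ramp[1:60]), 0.01)

  expect_error(makeSpindleInput(dt = 5e-3), "dt")
})

test_that("square waveforms cover exactly their window", {
  expect_equal(sum(makeTonicInput(0.5, 1, dt = 5e-4) != 0), 1000)
  expect_equal(makePulseInput(0.01, 0.7, dt = 1e-3), rep(0.7, 10))
  # zero-width limit carries no energy
  expect_length(makePulseInput(1e-9, 1, dt = 1e-3), 0)
  expect_error(makeTonicInput(0), "positive")
})

test_that("the free network stays at rest and stimulated runs are bounded", {
  wc <- buildCircuit(smallConfig(N = 40))
  free <- integrateCircuit(wc, list(), T = 0.5)
  for (p in circuitPopulations())
    expect_identical(max(abs(traces(free, p))), 0)

  # boundedness across randomised configurations (fixed seed)
  set.seed(42)
  for (rep in 1:5) {
    g <- defaultConfig()@gains
    g[] <- g * exp(runif(length(g), -0.7, 0.7))
    cfg <- smallConfig(N = 30, gains = g,
                       localInhibition = c(core = rep %% 2 == 0),
                       stimGain = runif(1, 5, 60))
    res <- integrateCircuit(
      buildCircuit(cfg),
      stimulusProtocol("TRN_C", "spindle_burst", centerIndex = 15),
      T = 1.2)
    for (p in circuitPopulations()) {
      tr <- traces(res, p)
      expect_true(all(tr >= -1 - 1e-9 & tr <= 1 + 1e-9))
    }
  }
})

test_that("activity decays back to rest after input ceases", {
  wc <- buildCircuit(smallConfig(N = 60))
  res <- integrateCircuit(
    wc, stimulusProtocol("TRN_C", "spindle_burst", centerIndex = 30),
    T = 3)
  lastQuarter <- simTime(res) > 2.5
  for (p in c("PV+", "TRN_C", "L6"))
    expect_lt(max(abs(traces(res, p)[, lastQuarter])), 1e-3)
})

test_that("tonic and spindle routes produce the same rebound signature", {
  # after shutdown: sharp drop, hyperpolarization, rebound depolarization
  wc <- buildCircuit(smallConfig(N = 60))
  dt <- 5e-4
  reboundSigns <- function(res) {
    v <- neuronTrace(res, "PV+", 30)
    sm <- stats::filter(v, rep(0.2, 5), sides = 2)
    sm[is.na(sm)] <- v[is.na(sm)]
    i <- seq(1002, length(sm) - 1)
    ext <- i[(sm[i] - sm[i - 1]) * (sm[i + 1] - sm[i]) < 0 &
               abs(sm[i]) > 1e-4]
    sign(sm[ext[1:2]])
  }
  tonic <- integrateCircuit(
    wc, stimulusProtocol("PV+", "tonic_square", amplitude = 0.5,
                         centerIndex = 30), T = 2, dt = dt)
  spindle <- integrateCircuit(
    wc, stimulusProtocol("TRN_C", "spindle_burst", centerIndex = 30),
    T = 2, dt = dt)
  # first post-shutdown extremum is hyperpolarized, second is a rebound
  expect_identical(reboundSigns(tonic), c(-1, 1))
  expect_identical(reboundSigns(spindle), c(-1, 1))

  # a brief pulse to the TRN hyperpolarizes PV+ first, then it rebounds
  pulse <- integrateCircuit(
    wc, stimulusProtocol("TRN_C", "pulse", duration = 0.05,
                         centerIndex = 30), T = 1, dt = dt)
  v <- neuronTrace(pulse, "PV+", 30)
  firstMove <- v[which(abs(v) > 1e-5)[1]]
  expect_lt(firstMove, 0)
  expect_gt(max(v), 0)
})

test_that("unstable gain settings raise an integration error naming dt", {
  cfg <- smallConfig(N = 30, gains = c(trnc_pv = 5e4, pv_trnc = 5e4))
  expect_error(
    integrateCircuit(buildCircuit(cfg),
                     stimulusProtocol("TRN_C", "spindle_burst",
                                      centerIndex = 15), T = 1),
    "dt")
  expect_error(
    integrateCircuit(buildCircuit(smallConfig(N = 20)), list(), T = 1,
                     dt = 5e-3),
    "dt")
})
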