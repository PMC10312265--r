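# expected incoming projections per population, as a function of the
# feature flags -- an independent rendering of the circuit's connectivity
# table used to audit buildCircuit()
expectedIncoming <- function(pop, localCore, localMatrix, fbTC, fbTRN,
                             mixing) {
  inc <- switch(pop,
    "CB+" = {
      x <- list(c("TRN_M", "inhibitory"))
      if (fbTC) x <- c(x, list(c("L5", "excitatory")))
      if (localMatrix) x <- c(x, list(c("CB-", "inhibitory")))
      x
    },
    "PV+" = {
      x <- list(c("TRN_C", "inhibitory"))
      if (fbTC) x <- c(x, list(c("L6", "excitatory")))
      if (localCore) x <- c(x, list(c("PV-", "inhibitory")))
      x
    },
    "CB-" = if (localMatrix)
      list(c("CB+", "excitatory"), c("TRN_M", "inhibitory")) else list(),
    "PV-" = if (localCore)
      list(c("PV+", "excitatory"), c("TRN_C", "inhibitory")) else list(),
    "TRN_M" = {
      x <- list(c("CB+", "excitatory"), c("TRN_M", "inhibitory"))
      if (fbTRN) x <- c(x, list(c("L5", "excitatory")))
      if (mixing == "thalamoreticular")
        x <- c(x, list(c("PV+", "excitatory")))
      if (mixing == "corticoreticular")
        x <- c(x, list(c("L6", "excitatory")))
      x
    },
    "TRN_C" = {
      x <- list(c("PV+", "excitatory"), c("TRN_C", "inhibitory"))
      if (fbTRN) x <- c(x, list(c("L6", "excitatory")))
      if (mixing == "thalamoreticular")
        x <- c(x, list(c("CB+", "excitatory")))
      if (mixing == "corticoreticular")
        x <- c(x, list(c("L5", "excitatory")))
      x
    },
    "L1-3a" = list(c("CB+", "excitatory")),
    "L3b-4" = list(c("PV+", "excitatory")),
    "L5" = {
      x <- list(c("L1-3a", "excitatory"))
      if (mixing == "cortical") x <- c(x, list(c("L6", "excitatory")))
      x
    },
    "L6" = {
      x <- list(c("L3b-4", "excitatory"))
      if (mixing == "cortical") x <- c(x, list(c("L5", "excitatory")))
      x
    })
  if (!length(inc)) return(character())
  sort(vapply(inc, paste, "", collapse = "/"))
}

test_that("wiring matches the connectivity table under all flags", {
  flags <- expand.grid(localCore = c(FALSE, TRUE),
                       localMatrix = c(FALSE, TRUE),
                       fbTC = c(FALSE, TRUE), fbTRN = c(FALSE, TRUE),
                       mixing = c("none", "thalamoreticular",
                                  "corticoreticular", "cortical"),
                       stringsAsFactors = FALSE)
  for (r in seq_len(nrow(flags))) {
    f <- flags[r, ]
    cfg <- defaultConfig(
      N = 20,
      localInhibition = c(core = f$localCore, matrix = f$localMatrix),
      corticalFeedbackTC = f$fbTC, corticalFeedbackTRN = f$fbTRN,
      mixingMode = f$mixing)
    wc <- buildCircuit(cfg)
    for (pop in circuitPopulations()) {
      got <- incomingProjections(wc, pop)
      got <- sort(paste(got$pre, got$sign, sep = "/"))
      expect_identical(
        got, expectedIncoming(pop, f$localCore, f$localMatrix, f$fbTC,
                              f$fbTRN, f$mixing),
        info = sprintf("pop %s under %s", pop,
                       paste(names(f), unlist(f), collapse = " ")))
    }
  }
})

test_that("inhibitory populations only source inhibitory projections", {
  wc <- buildCircuit(defaultConfig(
    N = 20, localInhibition = c(core = TRUE, matrix = TRUE),
    corticalFeedbackTC = TRUE, mixingMode = "cortical"))
  inhibSources <- c("CB-", "PV-", "TRN_M", "TRN_C")
  for (k in wc@kernels) {
    expect_identical(k@sign,
                     if (k@pre %in% inhibSources) "inhibitory"
                     else "excitatory")
    expect_true(all(buildWeightMatrix(k, 20)@values >= 0))
  }
})

test_that("unmixed loops are dynamically isolated", {
  # a core stimulus leaves every matrix population identically at rest
  wc <- buildCircuit(smallConfig(N = 60))
  res <- integrateCircuit(
    wc, stimulusProtocol("TRN_C", "spindle_burst", centerIndex = 30),
    T = 0.8)
  for (p in c("CB+", "CB-", "TRN_M", "L1-3a", "L5"))
    expect_identical(max(abs(traces(res, p))), 0)
  for (p in c("PV+", "TRN_C"))
    expect_gt(max(abs(traces(res, p))), 0)

  # and vice versa
  res2 <- integrateCircuit(
    wc, stimulusProtocol("TRN_M", "spindle_burst", centerIndex = 30),
    T = 0.8)
  for (p in c("PV+", "PV-", "TRN_C", "L3b-4", "L6"))
    expect_identical(max(abs(traces(res2, p))), 0)
  expect_gt(max(abs(traces(res2, "CB+"))), 0)
})

test_that("configuration invariants are enforced", {
  expect_equal(defaultConfig()@eExt, 1)
  expect_equal(defaultConfig()@eInh, -1)
  expect_equal(defaultConfig()@l5CbOverL6Pv, 20)

  # ratios beyond three orders of magnitude are rejected with a message
  # about the matrix loop losing its oscillation
  expect_error(defaultConfig(l5CbOverL6Pv = 1500), "matrix")
  expect_error(defaultConfig(l5TrnFraction = -0.1), "l5TrnFraction")
  expect_error(defaultConfig(mixingRatio = 1.4), "mixingRatio")
  expect_error(projectionKernel("PV+", "nonsense", 1, 1,
                                sign = "excitatory"), "population")
  expect_error(defaultConfig(nonsense = 1), "unknown")
})

test_that("mixing scales cross-coupling by ratio and efficacy", {
  wc <- buildCircuit(smallConfig(N = 30))

  # efficacy 0 reproduces the unmixed circuit exactly
  mixed0 <- applyMixing(wc, "cortical", ratio = 0.5, efficacy = 0)
  cross0 <- vapply(mixed0@kernels,
                   function(k) paste(k@pre, k@post) %in%
                     c("L6 L5", "L5 L6") && k@gain > 0, logical(1))
  expect_false(any(cross0))

  # ratio 0.8: core-side over matrix-side coupling gain = 4
  mixed <- applyMixing(wc, "cortical", ratio = 0.8, efficacy = 0.6)
  gL6L5 <- Filter(function(k) k@pre == "L6" && k@post == "L5",
                  mixed@kernels)[[1]]@gain
  gL5L6 <- Filter(function(k) k@pre == "L5" && k@post == "L6",
                  mixed@kernels)[[1]]@gain
  expect_equal(gL6L5 / gL5L6, 0.8 / 0.2)

  # thalamoreticular mixing adds the two thalamic cross-projections
  thal <- applyMixing(wc, "thalamoreticular", ratio = 0.5, efficacy = 1)
  pairs <- vapply(thal@kernels, function(k) paste(k@pre, k@post), "")
  expect_true(all(c("PV+ TRN_M", "CB+ TRN_C") %in% pairs))

  expect_warning(applyMixing(wc, "none", ratio = 0.3), "ignored")
  expect_error(applyMixing(wc, "cortical", ratio = 2), "ratio")
})
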