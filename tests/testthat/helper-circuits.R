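# Small circuits and synthetic result containers shared across tests.

smallConfig <- function(N = 40, ...) defaultConfig(N = N, ...)

# wrap plain trace matrices into the simulation result container
resultFromTraces <- function(traceList, dt = 5e-4) {
  n <- ncol(traceList[[1]])
  pops <- spindleloop::circuitPopulations()
  assays <- lapply(pops, function(p) {
    if (!is.null(traceList[[p]])) traceList[[p]]
    else matrix(0, nrow(traceList[[1]]), n)
  })
  names(assays) <- pops
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(time = seq(0, by = dt,
                                              length.out = n)),
    metadata = list(config = NULL, protocol = list(), dt = dt))
  new("SpindleSimResult", se)
}

# brute-force evaluation of Gaussian projection sums used as the
# independent oracle for populationInputs / buildWeightMatrix
bruteWeight <- function(j, i, sigma, offset = 0, gain = 1)
  gain * stats::dnorm(j, mean = i + offset, sd = sigma)
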