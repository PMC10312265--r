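#' @include AllClasses.R
NULL

#' Accessors for simulation results
#'
#' \code{simTime} returns the uniform time axis (seconds), \code{timeStep}
#' the integration step dt, \code{traces} the N x time activity matrix of
#' one population, and \code{neuronTrace} the time series of one neuron.
#'
#' @param x A \linkS4class{SpindleSimResult}.
#' @param population Population name (see [circuitPopulations()]).
#' @param index Neuron index on the one-dimensional array.
#' @return \code{simTime}: numeric vector of times; \code{timeStep}: a
#'   single numeric; \code{traces}: a numeric matrix (neurons x time);
#'   \code{neuronTrace}: a numeric vector.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setGeneric("simTime", function(x) standardGeneric("simTime"))

#' @rdname result-accessors
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))

#' @rdname result-accessors
#' @export
setGeneric("traces", function(x, population) standardGeneric("traces"))

#' @rdname result-accessors
#' @export
setGeneric("neuronTrace", function(x, population, index)
  standardGeneric("neuronTrace"))

#' @rdname result-accessors
#' @export
setMethod("simTime", "SpindleSimResult", function(x)
  SummarizedExperiment::colData(x)$time)

#' @rdname result-accessors
#' @export
setMethod("timeStep", "SpindleSimResult", function(x)
  S4Vectors::metadata(x)$dt)

#' @rdname result-accessors
#' @export
setMethod("traces", "SpindleSimResult", function(x, population) {
  if (!population %in% SummarizedExperiment::assayNames(x))
    stop(sprintf("unknown population '%s'", population), call. = FALSE)
  SummarizedExperiment::assay(x, population)
})

#' @rdname result-accessors
#' @export
setMethod("neuronTrace", "SpindleSimResult", function(x, population, index) {
  tr <- traces(x, population)
  if (index < 1 || index > nrow(tr))
    stop("neuron index outside the array", call. = FALSE)
  tr[index, ]
})

#' Configuration of a wired circuit or simulation result
#'
#' @param x A \linkS4class{WiredCircuit} or \linkS4class{SpindleSimResult}.
#' @return The underlying [CircuitConfig-class].
#' @export
setGeneric("circuitConfig", function(x) standardGeneric("circuitConfig"))

#' @rdname circuitConfig
#' @export
setMethod("circuitConfig", "WiredCircuit", function(x) x@config)

#' @rdname circuitConfig
#' @export
setMethod("circuitConfig", "SpindleSimResult", function(x)
  S4Vectors::metadata(x)$config)

#' Spindle tendency indices stored in a report
#'
#' @param x A \linkS4class{SpindleReport}.
#' @return Data frame with columns \code{population}, \code{neuron},
#'   \code{sti}.
#' @export
setGeneric("stiTable", function(x) standardGeneric("stiTable"))

#' @rdname stiTable
#' @export
setMethod("stiTable", "SpindleReport", function(x) x@sti)
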