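#' @include AllClasses.R kernels.R
NULL

# Resolve the active projection table from a configuration. Each row is one
# projection; gains are looked up in config@gains except for the two
# ratio-constrained connections (L5->CB+ = l5CbOverL6Pv x L6->PV+ and
# L5->TRN_M = l5TrnFraction x L6->TRN_C) and the mixing cross-connections.
.projectionTable <- function(config) {
  g <- config@gains
  eta <- config@centerOffsets
  sM <- unname(config@sigmas["matrix"])
  sC <- unname(config@sigmas["core"])
  rows <- list()
  add <- function(pre, post, sign, gain, sigma, offset = 0L)
    rows[[length(rows) + 1L]] <<- list(pre = pre, post = post, sign = sign,
                                       gain = gain, sigma = sigma,
                                       offset = as.integer(offset))

  ## --- constitutive drives -------------------------------------------------
  # thalamocortical and intracortical chains
  add("CB+", "L1-3a", "excitatory", g["cb_l13a"], sM, eta["tc_cortex"])
  add("PV+", "L3b-4", "excitatory", g["pv_l3b4"], sC, eta["tc_cortex"])
  add("L1-3a", "L5", "excitatory", g["l13a_l5"], sM)
  add("L3b-4", "L6", "excitatory", g["l3b4_l6"], sC)
  # thalamoreticular drives
  add("CB+", "TRN_M", "excitatory", g["cb_trnm"], sM, eta["tc_trn"])
  add("PV+", "TRN_C", "excitatory", g["pv_trnc"], sC, eta["tc_trn"])
  # reticulo-thalamic inhibition (the hybrid loop)
  add("TRN_M", "CB+", "inhibitory", g["trnm_cb"], sM, -eta["trn_tc"])
  add("TRN_C", "PV+", "inhibitory", g["trnc_pv"], sC, -eta["trn_tc"])
  # within-pool TRN inhibition
  add("TRN_M", "TRN_M", "inhibitory", g["trnm_trnm"], sM)
  add("TRN_C", "TRN_C", "inhibitory", g["trnc_trnc"], sC)

  ## --- corticothalamic feedback --------------------------------------------
  # the matrix-side driver L5 -> CB+ is held at l5CbOverL6Pv times the
  # core L6 -> PV+ feedback gain
  if (config@corticalFeedbackTC) {
    add("L6", "PV+", "excitatory", g["l6_pv"], sC)
    add("L5", "CB+", "excitatory", config@l5CbOverL6Pv * g["l6_pv"], sM)
  }

  ## --- corticoreticular drive ----------------------------------------------
  if (config@corticalFeedbackTRN) {
    add("L6", "TRN_C", "excitatory", g["l6_trnc"], sC)
    if (config@l5TrnFraction > 0)
      add("L5", "TRN_M", "excitatory",
          config@l5TrnFraction * g["l6_trnc"], sM)
  }

  ## --- local thalamic inhibitory interneurons ------------------------------
  if (config@localInhibition["core"]) {
    add("PV+", "PV-", "excitatory", g["pv_pvm"], sC)
    add("PV-", "PV+", "inhibitory", g["pvm_pv"], sC)
    add("TRN_C", "PV-", "inhibitory", g["trnc_pvm"], sC)
  }
  if (config@localInhibition["matrix"]) {
    add("CB+", "CB-", "excitatory", g["cb_cbm"], sM)
    add("CB-", "CB+", "inhibitory", g["cbm_cb"], sM)
    add("TRN_M", "CB-", "inhibitory", g["trnm_cbm"], sM)
  }

  ## --- mixing cross-connections --------------------------------------------
  r <- config@mixingRatio
  e <- config@mixingEfficacy
  if (config@mixingMode == "thalamoreticular") {
    add("PV+", "TRN_M", "excitatory", 2 * r * e * g["mix_thal"], sM,
        eta["tc_trn"])
    add("CB+", "TRN_C", "excitatory", 2 * (1 - r) * e * g["mix_thal"], sM,
        eta["tc_trn"])
  } else if (config@mixingMode == "corticoreticular") {
    add("L6", "TRN_M", "excitatory", 2 * r * e * g["mix_cr"], sM)
    add("L5", "TRN_C", "excitatory", 2 * (1 - r) * e * g["mix_cr"], sM)
  } else if (config@mixingMode == "cortical") {
    add("L6", "L5", "excitatory", 2 * r * e * g["mix_cortical"], sM)
    add("L5", "L6", "excitatory", 2 * (1 - r) * e * g["mix_cortical"], sM)
  }

  do.call(rbind, lapply(rows, as.data.frame))
}

#' Wire the full core/matrix/mix network
#'
#' Assembles the ten-population circuit from a [CircuitConfig-class]: every
#' projection active under the configuration's feature flags and mixing mode
#' is realised as a Gaussian [WeightMatrix-class]. The incoming projection
#' set of each population follows its connectivity table row: thalamic relay
#' neurons are driven by their cortical layer and inhibited by their TRN
#' sector (and, when local inhibition is on, by their local interneurons);
#' TRN sectors are driven by their relay neurons and cortical layers and
#' inhibited within-pool; cortical layers form the
#' relay -> middle/superficial -> deep chain.
#'
#' @param config A [CircuitConfig-class]; see [defaultConfig()].
#' @return A [WiredCircuit-class].
#' @examples
#' wc <- buildCircuit(defaultConfig(N = 40))
#' incomingProjections(wc, "PV+")
#' @seealso [applyMixing()], [integrateCircuit()]
#' @export
buildCircuit <- function(config) {
  stopifnot(is(config, "CircuitConfig"))
  validObject(config)
  tab <- .projectionTable(config)
  kernels <- vector("list", nrow(tab))
  weights <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    kern <- projectionKernel(tab$pre[k], tab$post[k], gain = tab$gain[k],
                             sigma = tab$sigma[k],
                             centerOffset = tab$offset[k],
                             sign = tab$sign[k])
    kernels[[k]] <- kern
    weights[[k]] <- buildWeightMatrix(kern, config@N)@values
  }
  new("WiredCircuit", config = config, kernels = kernels, weights = weights)
}

#' Audit the incoming projections of one population
#'
#' @param circuit A [WiredCircuit-class].
#' @param population Population name.
#' @return Data frame with one row per incoming projection: \code{pre},
#'   \code{sign}, \code{gain}.
#' @export
incomingProjections <- function(circuit, population) {
  stopifnot(is(circuit, "WiredCircuit"))
  if (!population %in% circuitPopulations())
    stop(sprintf("unknown population '%s'", population), call. = FALSE)
  keep <- vapply(circuit@kernels, function(k) k@post == population,
                 logical(1))
  ks <- circuit@kernels[keep]
  data.frame(pre = vapply(ks, function(k) k@pre, ""),
             sign = vapply(ks, function(k) k@sign, ""),
             gain = vapply(ks, function(k) k@gain, 0))
}

#' Re-wire a circuit under a different core/matrix mixing regime
#'
#' Cross-connects the two parallel loops: \code{cortical} mixing couples L5
#' and L6 bidirectionally (the core-side coupling scaled by the core
#' fraction \code{ratio}, the matrix side by \code{1 - ratio}, both by the
#' plateau synaptic \code{efficacy}); \code{corticoreticular} mixing sends
#' L6 to TRN_M and L5 to TRN_C; \code{thalamoreticular} mixing sends PV+ to
#' TRN_M and CB+ to TRN_C. \code{efficacy = 0} reproduces the unmixed
#' circuit exactly.
#'
#' @param circuit A [WiredCircuit-class].
#' @param mode \code{"none"}, \code{"thalamoreticular"},
#'   \code{"corticoreticular"} or \code{"cortical"}.
#' @param ratio Core fraction in [0, 1]; 0.5 is the symmetric baseline.
#' @param efficacy Fraction of plateau synaptic efficacy in [0, 1].
#' @return A re-wired [WiredCircuit-class].
#' @export
applyMixing <- function(circuit, mode = c("none", "thalamoreticular",
                                          "corticoreticular", "cortical"),
                        ratio = 0.5, efficacy = 1) {
  stopifnot(is(circuit, "WiredCircuit"))
  mode <- match.arg(mode)
  if (ratio < 0 || ratio > 1 || efficacy < 0 || efficacy > 1)
    stop("configuration error: ratio and efficacy must lie in [0, 1]",
         call. = FALSE)
  if (mode == "none" && ratio != 0.5)
    warning("mixingMode 'none': ratio is ignored")
  config <- circuit@config
  config@mixingMode <- mode
  config@mixingRatio <- ratio
  config@mixingEfficacy <- efficacy
  buildCircuit(config)
}
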