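## Generics, accessors and show() methods.

#' Number of channels / neurons represented by an object
#' @param x a SpikeEvents, BinnedRaster, MomentSet, KPairwiseModel or
#'   NetworkTopology object.
#' @return integer(1)
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname nChannels
#' @export
setMethod("nChannels", "SpikeEvents", function(x) x@nChannels)
#' @rdname nChannels
#' @export
setMethod("nChannels", "BinnedRaster", function(x) nrow(x@sigma))
#' @rdname nChannels
#' @export
setMethod("nChannels", "MomentSet", function(x) length(x@mean))
#' @rdname nChannels
#' @export
setMethod("nChannels", "KPairwiseModel", function(x) length(x@h))
#' @rdname nChannels
#' @export
setMethod("nChannels", "NetworkTopology", function(x) x@nNeurons)

#' Number of time bins of a raster
#' @param x a BinnedRaster or MomentSet.
#' @return numeric(1)
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname nBins
#' @export
setMethod("nBins", "BinnedRaster", function(x) ncol(x@sigma))
#' @rdname nBins
#' @export
setMethod("nBins", "MomentSet", function(x) x@nBins)

#' Bin width of a raster, on the event clock
#' @param x a BinnedRaster.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname binWidth
#' @export
setMethod("binWidth", "BinnedRaster", function(x) x@binWidth)

#' Raster matrix accessor
#' @param x a BinnedRaster.
#' @return integer matrix (channels x bins) of +/-1 entries.
#' @export
setGeneric("sigmaMatrix", function(x) standardGeneric("sigmaMatrix"))
#' @rdname sigmaMatrix
#' @export
setMethod("sigmaMatrix", "BinnedRaster", function(x) x@sigma)

#' Accessors for MomentSet statistics
#'
#' \code{meanSigma} returns the per-channel activities
#' \eqn{\langle\sigma_i\rangle}; \code{pairSigma} the symmetric matrix of
#' \eqn{\langle\sigma_i\sigma_j\rangle}; \code{synchronyPK} the
#' distribution \eqn{P(K)}, K = 0..N; \code{correlationMatrix} the
#' covariances \eqn{C_{ij} = \langle\sigma_i\sigma_j\rangle -
#' \langle\sigma_i\rangle\langle\sigma_j\rangle}; \code{standardErrors}
#' the block-resampling standard errors.
#'
#' @param x a MomentSet.
#' @name moment-accessors
NULL

#' @rdname moment-accessors
#' @export
setGeneric("meanSigma", function(x) standardGeneric("meanSigma"))
#' @rdname moment-accessors
#' @export
setMethod("meanSigma", "MomentSet", function(x) x@mean)
#' @rdname moment-accessors
#' @export
setGeneric("pairSigma", function(x) standardGeneric("pairSigma"))
#' @rdname moment-accessors
#' @export
setMethod("pairSigma", "MomentSet", function(x) x@pair)
#' @rdname moment-accessors
#' @export
setGeneric("synchronyPK", function(x) standardGeneric("synchronyPK"))
#' @rdname moment-accessors
#' @export
setMethod("synchronyPK", "MomentSet", function(x) x@pk)
#' @rdname moment-accessors
#' @export
setGeneric("correlationMatrix", function(x) standardGeneric("correlationMatrix"))
#' @rdname moment-accessors
#' @export
setMethod("correlationMatrix", "MomentSet", function(x) {
  C <- x@pair - outer(x@mean, x@mean)
  diag(C) <- 1 - x@mean^2
  C
})
#' @rdname moment-accessors
#' @export
setGeneric("standardErrors", function(x) standardGeneric("standardErrors"))
#' @rdname moment-accessors
#' @export
setMethod("standardErrors", "MomentSet", function(x) x@se)

#' Accessors for KPairwiseModel parameters
#' @param x a KPairwiseModel.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("fieldsH", function(x) standardGeneric("fieldsH"))
#' @rdname model-accessors
#' @export
setMethod("fieldsH", "KPairwiseModel", function(x) x@h)
#' @rdname model-accessors
#' @export
setGeneric("couplingsJ", function(x) standardGeneric("couplingsJ"))
#' @rdname model-accessors
#' @export
setMethod("couplingsJ", "KPairwiseModel", function(x) x@J)
#' @rdname model-accessors
#' @export
setGeneric("potentialsV", function(x) standardGeneric("potentialsV"))
#' @rdname model-accessors
#' @export
setMethod("potentialsV", "KPairwiseModel", function(x) x@V)
#' @rdname model-accessors
#' @export
setGeneric("fittedMask", function(x) standardGeneric("fittedMask"))
#' @rdname model-accessors
#' @export
setMethod("fittedMask", "KPairwiseModel", function(x) x@fittedMask)

#' Curve accessor for a temperature sweep
#' @param x a ThermoCurve.
#' @return data.frame with columns temperature, cv, cvSe, chi, chiSe, initMode.
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))
#' @rdname curveTable
#' @export
setMethod("curveTable", "ThermoCurve", function(x) {
  data.frame(temperature = x@temperatures, cv = x@cv, cvSe = x@cvSe,
             chi = x@chi, chiSe = x@chiSe, initMode = x@initMode)
})

setMethod("show", "DynamicsParams", function(object) {
  cat("DynamicsParams: vc =", object@vThreshold,
      " deltaU =", object@deltaU, " deltaURec =", object@deltaURec, "\n",
      "  deltaV =", object@deltaV, " beta =", object@beta,
      " gMin =", object@gMin, "\n")
})

setMethod("show", "NetworkTopology", function(object) {
  k <- lengths(object@edges)
  cat("NetworkTopology:", object@nNeurons, "neurons in [0,",
      format(object@side, digits = 4), "]^3\n",
      " ", sum(object@inhibitory), "inhibitory;",
      sum(k), "synapses; out-degree in [", min(k), ",", max(k), "]\n")
})

setMethod("show", "SpikeEvents", function(object) {
  cat("SpikeEvents:", length(object@time), "events on", object@nChannels,
      "channels over", object@nTimesteps, "timesteps",
      if (!is.na(object@dtMs)) paste0("(", object@dtMs, " ms each)"), "\n")
})

setMethod("show", "BinnedRaster", function(object) {
  cat("BinnedRaster:", nrow(object@sigma), "channels x", ncol(object@sigma),
      "bins (binWidth =", object@binWidth, ")\n",
      "  active-bin fraction:",
      format(mean(object@sigma == 1L), digits = 4), "\n")
})

setMethod("show", "MomentSet", function(object) {
  cat("MomentSet:", length(object@mean), "channels,", object@nBins, "bins\n",
      "  <sigma> in [", format(min(object@mean), digits = 3), ",",
      format(max(object@mean), digits = 3), "], P(K=0) =",
      format(object@pk[1], digits = 4), "\n")
})

setMethod("show", "KPairwiseModel", function(object) {
  cat("KPairwiseModel: N =", length(object@h), "\n",
      "  h in [", format(min(object@h), digits = 3), ",",
      format(max(object@h), digits = 3), "];",
      sum(object@fittedMask), "fitted potentials V_K\n")
})

setMethod("show", "ThermoCurve", function(object) {
  cat("ThermoCurve (", object@initMode, " start): ",
      length(object@temperatures), " temperatures in [",
      format(min(object@temperatures), digits = 3), ", ",
      format(max(object@temperatures), digits = 3), "]\n", sep = "")
})

setMethod("show", "ScalingFit", function(object) {
  cat("ScalingFit: exponent =", format(object@exponent, digits = 4),
      "+/-", format(object@exponentSe, digits = 3),
      "over n in {", paste(unique(object@table$n), collapse = ", "), "}\n")
})

setMethod("show", "ExperimentPlan", function(object) {
  cat("ExperimentPlan:", object@state, "state; N in {",
      paste(object@nValues, collapse = ", "), "};",
      object@replicates, "replicate(s);", object@nBins, "bins\n")
})
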