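## Central S4 containers.  Validity checks are kept structural (dimensions,
## ranges, symmetry); the statistical invariants of the generating operations
## are asserted in the unit tests.

#' Parameters of the integrate-and-fire avalanche dynamics
#'
#' Holds the dimensionless constants of the network dynamics: firing
#' threshold \code{vThreshold} (\eqn{v_c = 1}), fraction of synaptic
#' resources released per spike \code{deltaU} (\eqn{\delta u = 0.05}),
#' between-avalanche resource recovery \code{deltaURec} (\eqn{\delta
#' u_{rec}}, the tuning knob that moves the dynamics between subcritical,
#' critical and supercritical avalanche regimes), external drive
#' \code{deltaV} (\eqn{\delta v = 0.1} added to one random neuron per
#' quiescent timestep), long-term adaptation rate \code{beta}
#' (\eqn{\beta = 0.04}), minimum synaptic strength \code{gMin}
#' (\eqn{g_{min} = 10^{-5}}) and the pre-training budget in avalanches.
#'
#' @slot vThreshold numeric(1) firing threshold.
#' @slot deltaU numeric(1) short-term depression per spike, in (0, 1).
#' @slot deltaURec numeric(1) resource recovery per avalanche.
#' @slot deltaV numeric(1) external drive per quiescent timestep.
#' @slot beta numeric(1) long-term potentiation rate.
#' @slot gMin numeric(1) lower bound for synaptic strengths.
#' @slot pretrainAvalanches numeric(1) avalanche budget for pre-training.
#' @exportClass DynamicsParams
setClass("DynamicsParams",
  representation(vThreshold = "numeric", deltaU = "numeric",
                 deltaURec = "numeric", deltaV = "numeric", beta = "numeric",
                 gMin = "numeric", pretrainAvalanches = "numeric"),
  validity = function(object) {
    v <- c(object@vThreshold, object@deltaU, object@deltaURec, object@deltaV,
           object@beta, object@gMin)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all dynamics parameters must be finite and strictly positive")
    if (!is.finite(object@pretrainAvalanches) || object@pretrainAvalanches < 0)
      return("pretrainAvalanches must be nonnegative")
    if (object@deltaU >= 1) return("deltaU must be < 1")
    TRUE
  })

#' @describeIn DynamicsParams constructor with the standard defaults;
#'   only \code{deltaURec} has no canonical value and must be chosen (or
#'   calibrated with \code{\link{calibrateDeltaURec}}).
#' @param deltaURec,vThreshold,deltaU,deltaV,beta,gMin,pretrainAvalanches
#'   see slots.
#' @export
dynamicsParams <- function(deltaURec = 0.01, vThreshold = 1, deltaU = 0.05,
                           deltaV = 0.1, beta = 0.04, gMin = 1e-5,
                           pretrainAvalanches = 1e4) {
  new("DynamicsParams", vThreshold = vThreshold, deltaU = deltaU,
      deltaURec = deltaURec, deltaV = deltaV, beta = beta, gMin = gMin,
      pretrainAvalanches = pretrainAvalanches)
}

#' Directed scale-free network with spatial embedding
#'
#' Neurons live in the cube \eqn{[0, L]^3} with density fixed at
#' \eqn{N/L^3 = 0.016}; 20\% are inhibitory; out-degrees follow
#' \eqn{P(k) \propto k^{-2}} and targets are drawn with probability
#' \eqn{\propto e^{-r/5}} in the Euclidean distance \eqn{r}.
#'
#' @slot nNeurons integer(1) number of neurons.
#' @slot side numeric(1) cube side L.
#' @slot positions N x 3 matrix of coordinates in [0, L]^3.
#' @slot inhibitory logical(N).
#' @slot edges list of integer vectors; \code{edges[[i]]} are the 1-based
#'   post-synaptic targets of neuron i.
#' @slot strengths list of numeric vectors parallel to \code{edges}.
#' @exportClass NetworkTopology
setClass("NetworkTopology",
  representation(nNeurons = "integer", side = "numeric", positions = "matrix",
                 inhibitory = "logical", edges = "list", strengths = "list"),
  validity = function(object) {
    n <- object@nNeurons
    if (length(object@inhibitory) != n) return("inhibitory flags must have length N")
    if (nrow(object@positions) != n || ncol(object@positions) != 3)
      return("positions must be an N x 3 matrix")
    if (length(object@edges) != n || length(object@strengths) != n)
      return("edges and strengths must have one entry per neuron")
    for (i in seq_len(n)) {
      e <- object@edges[[i]]
      if (length(e) != length(object@strengths[[i]]))
        return("strengths must be parallel to edges")
      if (any(e == i)) return("self-edges are not allowed")
      if (length(e) && (min(e) < 1 || max(e) > n)) return("edge target out of range")
    }
    g <- unlist(object@strengths)
    if (length(g) && (any(g <= 0) || any(g > 1)))
      return("synaptic strengths must lie in (0, 1]")
    TRUE
  })

#' Time-stamped spike events
#'
#' The interchange record between the simulator, the synthetic generators
#' and the statistics: 1-based channel ids with integer timestamps on the
#' event clock (simulation timesteps, or milliseconds via \code{dtMs} for
#' recording-style files).
#'
#' @slot time integer vector of event times, non-decreasing, in
#'   [0, nTimesteps).
#' @slot channel integer vector of 1-based channel ids.
#' @slot nChannels integer(1).
#' @slot nTimesteps numeric(1) total recording length on the event clock.
#' @slot dtMs numeric(1) duration of one clock unit in milliseconds
#'   (NA for dimensionless model time).
#' @exportClass SpikeEvents
setClass("SpikeEvents",
  representation(time = "numeric", channel = "integer", nChannels = "integer",
                 nTimesteps = "numeric", dtMs = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@channel))
      return("time and channel must have equal length")
    if (length(object@channel) &&
        (min(object@channel) < 1 || max(object@channel) > object@nChannels))
      return("channel ids must lie in 1..nChannels")
    if (is.unsorted(object@time)) return("events must be time-ordered")
    if (length(object@time) && (min(object@time) < 0 ||
                                max(object@time) >= object@nTimesteps))
      return("event times must lie in [0, nTimesteps)")
    TRUE
  })

#' Binary +/-1 raster of binned spiking activity
#'
#' \code{sigma[i, k] = +1} iff channel i fired at least once in time bin k,
#' else \eqn{-1}; the trailing partial bin of the recording is dropped.
#'
#' @slot sigma integer matrix, channels x bins, entries in \{-1, +1\}.
#' @slot binWidth numeric(1) bin duration on the event clock.
#' @exportClass BinnedRaster
setClass("BinnedRaster",
  representation(sigma = "matrix", binWidth = "numeric"),
  validity = function(object) {
    if (length(object@sigma) && !all(object@sigma == 1L | object@sigma == -1L))
      return("raster entries must be -1 or +1")
    if (object@binWidth <= 0) return("binWidth must be positive")
    TRUE
  })

#' Constrained firing statistics of a raster
#'
#' The feature set the K-pairwise model is fitted to: per-channel means
#' \eqn{\langle\sigma_i\rangle}, pairwise moments
#' \eqn{\langle\sigma_i\sigma_j\rangle} (stored as a symmetric matrix with
#' unit diagonal), and the synchrony distribution \eqn{P(K)}, K = 0..N,
#' each with standard errors estimated from contiguous block subsets of
#' the bins.
#'
#' @slot mean numeric(N).
#' @slot pair symmetric N x N matrix, unit diagonal.
#' @slot pk numeric(N + 1), nonnegative, sums to 1.
#' @slot se list with elements \code{mean}, \code{pair}, \code{pk}.
#' @slot nBins numeric(1) number of bins the statistics came from.
#' @exportClass MomentSet
setClass("MomentSet",
  representation(mean = "numeric", pair = "matrix", pk = "numeric",
                 se = "list", nBins = "numeric"),
  validity = function(object) {
    n <- length(object@mean)
    if (any(abs(object@mean) > 1 + 1e-12)) return("means must lie in [-1, 1]")
    if (nrow(object@pair) != n || ncol(object@pair) != n)
      return("pair matrix must be N x N")
    if (any(abs(object@pair) > 1 + 1e-12)) return("pair moments must lie in [-1, 1]")
    if (max(abs(object@pair - t(object@pair))) > 1e-12)
      return("pair matrix must be symmetric")
    if (length(object@pk) != n + 1) return("pk must have length N + 1")
    if (any(object@pk < -1e-15)) return("P(K) must be nonnegative")
    if (abs(sum(object@pk) - 1) > 1e-9) return("P(K) must sum to 1")
    TRUE
  })

#' K-pairwise generalized Ising model
#'
#' Parameters of the Hamiltonian
#' \deqn{H(\sigma) = -\sum_i h_i \sigma_i - \sum_{i<j} J_{ij} \sigma_i
#'   \sigma_j - \sum_K V_K \delta_{K, K'(\sigma)}}
#' with \eqn{K'(\sigma)} the number of up spins.  The potential at K = 0 is
#' the gauge-pinned one (exactly zero), and potentials whose synchrony
#' probability was below the fitting threshold stay exactly zero as well
#' (\code{fittedMask}).
#'
#' @slot h numeric(N) local fields.
#' @slot J symmetric N x N coupling matrix with zero diagonal.
#' @slot V numeric(N + 1) synchrony potentials, \code{V[1]} is K = 0.
#' @slot fittedMask logical(N + 1); FALSE entries are pinned to zero.
#' @exportClass KPairwiseModel
setClass("KPairwiseModel",
  representation(h = "numeric", J = "matrix", V = "numeric",
                 fittedMask = "logical"),
  validity = function(object) {
    n <- length(object@h)
    if (nrow(object@J) != n || ncol(object@J) != n) return("J must be N x N")
    if (max(abs(object@J - t(object@J))) > 1e-12) return("J must be symmetric")
    if (any(diag(object@J) != 0)) return("J must have zero diagonal")
    if (length(object@V) != n + 1) return("V must have length N + 1")
    if (length(object@fittedMask) != n + 1)
      return("fittedMask must have length N + 1")
    if (object@fittedMask[1]) return("V at K = 0 is the gauge and cannot be fitted")
    if (object@V[1] != 0) return("V at K = 0 must be exactly 0")
    if (any(object@V[!object@fittedMask] != 0))
      return("unfitted potentials must be exactly 0")
    TRUE
  })

#' Temperature sweep of the response functions
#'
#' \eqn{C_v(T) = (\langle H^2\rangle - \langle H\rangle^2)/T^2} and
#' \eqn{\chi(T) = (\langle M^2\rangle - \langle M\rangle^2)/T} sampled from
#' \eqn{P(\sigma, T) \propto e^{-H(\sigma)/T}}, with standard errors across
#' independent chains.
#'
#' @slot temperatures numeric grid.
#' @slot cv,cvSe,chi,chiSe numeric, parallel to \code{temperatures}.
#' @slot initMode character(1), "random" or "silent" chain starts.
#' @exportClass ThermoCurve
setClass("ThermoCurve",
  representation(temperatures = "numeric", cv = "numeric", cvSe = "numeric",
                 chi = "numeric", chiSe = "numeric", initMode = "character"),
  validity = function(object) {
    k <- length(object@temperatures)
    if (length(object@cv) != k || length(object@chi) != k ||
        length(object@cvSe) != k || length(object@chiSe) != k)
      return("curve columns must be parallel to the temperature grid")
    if (any(object@temperatures <= 0)) return("temperatures must be positive")
    if (any(object@cv < 0) || any(object@chi < 0))
      return("Cv and chi are variances over T powers and cannot be negative")
    TRUE
  })

#' Finite-size scaling fit of response-function maxima
#'
#' @slot table data.frame with columns \code{n}, \code{value},
#'   \code{replicate} (the per-replicate maxima entering the fit).
#' @slot exponent numeric(1) least-squares slope of log(value) vs log(n).
#' @slot exponentSe numeric(1) bootstrap standard error over replicates.
#' @slot tmax numeric, argmax temperature per n (NA when not recorded).
#' @exportClass ScalingFit
setClass("ScalingFit",
  representation(table = "data.frame", exponent = "numeric",
                 exponentSe = "numeric", tmax = "numeric"))

#' Boltzmann-machine learning schedule
#'
#' @slot alpha numeric(1) exponent of the decreasing learning rate
#'   \eqn{\theta(n) = \theta_0 n^{-\alpha}}.
#' @slot theta0 numeric(1) learning-rate prefactor.
#' @slot thetaJRatio numeric(1) ratio of the coupling rate to
#'   \eqn{\theta(n)} (1/2).
#' @slot vkSwitchIter numeric(1) iteration after which the potential rate
#'   becomes \eqn{\theta(n)/P(K)_{data}}.
#' @slot maxIters numeric(1).
#' @slot mcSamples numeric(1) Metropolis attempts averaged per iteration.
#' @slot pkThreshold numeric(1) only potentials with
#'   \eqn{P(K)_{data}} above this are fitted; NA selects
#'   \eqn{10^{-5}} when the data has at least \eqn{10^6} bins and
#'   \eqn{10^{-4}} otherwise.
#' @slot tolMean,tolPk numeric(1) stopping tolerances on
#'   \eqn{\max_i |\Delta\langle\sigma_i\rangle|} and
#'   \eqn{\max_K |\Delta P(K)|/P(K)_{data}}.
#' @exportClass LearningSchedule
setClass("LearningSchedule",
  representation(alpha = "numeric", theta0 = "numeric", thetaJRatio = "numeric",
                 vkSwitchIter = "numeric", maxIters = "numeric",
                 mcSamples = "numeric", pkThreshold = "numeric",
                 tolMean = "numeric", tolPk = "numeric"),
  validity = function(object) {
    if (object@alpha <= 0) return("alpha must be positive")
    if (object@theta0 <= 0 || object@maxIters < 1 || object@mcSamples < 1)
      return("theta0, maxIters and mcSamples must be positive")
    TRUE
  })

#' @describeIn LearningSchedule constructor with the standard schedule.
#' @param alpha,theta0,thetaJRatio,vkSwitchIter,maxIters,mcSamples,pkThreshold,tolMean,tolPk
#'   see slots.
#' @export
learningSchedule <- function(alpha = 0.6, theta0 = 0.1, thetaJRatio = 0.5,
                             vkSwitchIter = 5000, maxIters = 2e5,
                             mcSamples = 3e5, pkThreshold = NA_real_,
                             tolMean = 5e-3, tolPk = 0.1) {
  new("LearningSchedule", alpha = alpha, theta0 = theta0,
      thetaJRatio = thetaJRatio, vkSwitchIter = vkSwitchIter,
      maxIters = maxIters, mcSamples = mcSamples, pkThreshold = pkThreshold,
      tolMean = tolMean, tolPk = tolPk)
}

#' Metropolis sampler configuration
#'
#' @slot nSamples numeric(1) post-burn-in flip attempts per chain (Mc).
#' @slot burnIn numeric(1) discarded attempts; NA means 150 N.
#' @slot nChains integer(1) independent restarts.
#' @slot seed integer(1).
#' @exportClass SamplerConfig
setClass("SamplerConfig",
  representation(nSamples = "numeric", burnIn = "numeric",
                 nChains = "integer", seed = "integer"),
  validity = function(object) {
    if (!is.na(object@burnIn) && object@burnIn < 0) return("burnIn must be >= 0")
    if (object@nChains < 1) return("nChains must be >= 1")
    if (object@nSamples < 1) return("nSamples must be >= 1")
    TRUE
  })

#' @describeIn SamplerConfig constructor.
#' @param nSamples,burnIn,nChains,seed see slots.
#' @export
samplerConfig <- function(nSamples = 3e5, burnIn = NA_real_, nChains = 1L,
                          seed = 1L) {
  new("SamplerConfig", nSamples = nSamples, burnIn = burnIn,
      nChains = as.integer(nChains), seed = as.integer(seed))
}

#' End-to-end experiment plan
#'
#' Describes one simulate -> bin -> classify -> fit -> thermodynamics ->
#' scaling experiment: the dynamical state, the system sizes, the number of
#' independent network replicates per size, the binning and recording
#' budgets, and the learning/sampling configurations.  All randomness
#' derives from \code{masterSeed}.
#'
#' @slot state character(1), "sub", "crit" or "super".
#' @slot nValues integer vector of system sizes.
#' @slot replicates integer(1) independent networks per size.
#' @slot binWidth numeric(1) bin duration in timesteps.
#' @slot nBins numeric(1) recording length in bins.
#' @slot schedule LearningSchedule.
#' @slot sampler SamplerConfig used for model evaluation.
#' @slot masterSeed integer(1).
#' @slot outputDir character(1).
#' @exportClass ExperimentPlan
setClass("ExperimentPlan",
  representation(state = "character", nValues = "integer",
                 replicates = "integer", binWidth = "numeric",
                 nBins = "numeric", schedule = "LearningSchedule",
                 sampler = "SamplerConfig", masterSeed = "integer",
                 outputDir = "character"),
  validity = function(object) {
    if (!object@state %in% c("sub", "crit", "super"))
      return("state must be one of 'sub', 'crit', 'super'")
    if (object@replicates < 1) return("replicates must be >= 1")
    if (object@nBins < 1 || object@binWidth < 1)
      return("nBins and binWidth must be >= 1")
    TRUE
  })
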