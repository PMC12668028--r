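# Shared fixtures: random K-pairwise models, hand-built topologies,
# and a per-session cache for expensive shared computations.

randomModel <- function(n, seed, hSd = 0.5, jSd = 0.3, vSd = 0.3,
                        hMean = -0.5) {
  withr::local_seed(seed)
  J <- matrix(0, n, n)
  J[upper.tri(J)] <- rnorm(n * (n - 1) / 2, 0, jSd)
  J <- J + t(J)
  V <- c(0, rnorm(n, 0, vSd))
  kPairwiseModel(h = rnorm(n, hMean, hSd), J = J, V = V,
                 fittedMask = c(FALSE, rep(TRUE, n)))
}

independentModel <- function(h) kPairwiseModel(h = h)

# A two-neuron feed-forward chain: neuron 1 projects to neuron 2.
chainTopology <- function(g12 = 0.6, inhibitory1 = FALSE) {
  new("NetworkTopology", nNeurons = 2L, side = 5,
      positions = matrix(c(1, 1, 1, 2, 1, 1), 2, 3, byrow = TRUE),
      inhibitory = c(inhibitory1, FALSE),
      edges = list(2L, integer(0)),
      strengths = list(g12, numeric(0)))
}

rasterFromMatrix <- function(m, binWidth = 1) {
  storage.mode(m) <- "integer"
  new("BinnedRaster", sigma = m, binWidth = binWidth)
}

# Session cache so expensive shared objects (calibration, fitted models)
# are computed once across test files.
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# The calibrated critical recovery value used by the IF-model tests.
# Calibration is deterministic given the seed.
critDeltaURec <- function(nNeurons = 100) {
  cached(paste0("ducrit", nNeurons),
         calibrateDeltaURec(nNeurons, seed = 5)$estimate)
}
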