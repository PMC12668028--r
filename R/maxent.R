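## The K-pairwise model: energies, exact enumeration (the small-N oracle),
## Metropolis sampling, Boltzmann-machine inference and the three-point
## prediction.

#' Construct a K-pairwise model
#'
#' @param h numeric(N) local fields.
#' @param J symmetric N x N coupling matrix with zero diagonal (or an
#'   upper-triangular one, symmetrized here).
#' @param V numeric(N + 1) synchrony potentials (V[1], the K = 0 entry, is
#'   the gauge and must be 0); defaults to all zero.
#' @param fittedMask logical(N + 1); defaults to marking every nonzero V
#'   (plus none at K = 0) as fitted.
#' @return a \linkS4class{KPairwiseModel}.
#' @export
kPairwiseModel <- function(h, J = NULL, V = NULL, fittedMask = NULL) {
  n <- length(h)
  if (is.null(J)) J <- matrix(0, n, n)
  if (max(abs(J - t(J))) > 0) J <- J + t(J) - diag(diag(J))
  diag(J) <- 0
  if (is.null(V)) V <- numeric(n + 1)
  if (is.null(fittedMask)) fittedMask <- c(FALSE, V[-1] != 0)
  new("KPairwiseModel", h = as.numeric(h), J = J, V = as.numeric(V),
      fittedMask = fittedMask)
}

#' Energy of a spin configuration
#'
#' \eqn{H(\sigma) = -\sum_i h_i\sigma_i - \sum_{i<j} J_{ij}\sigma_i\sigma_j
#' - V_{K'(\sigma)}}, each unordered pair counted once.
#'
#' @param model a \linkS4class{KPairwiseModel}.
#' @param sigma numeric/integer vector of +/-1.
#' @return numeric(1).
#' @export
modelEnergy <- function(model, sigma) {
  stopifnot(length(sigma) == length(model@h), all(abs(sigma) == 1))
  K <- sum(sigma == 1)
  -sum(model@h * sigma) -
    sum(model@J[upper.tri(model@J)] * (tcrossprod(sigma))[upper.tri(model@J)]) -
    model@V[K + 1]
}

#' Energy change for a single spin flip
#'
#' Matches \code{modelEnergy(after) - modelEnergy(before)} to within
#' \eqn{10^{-10}}; the synchrony count moves by \eqn{\mp 1} and the
#' potential term by \eqn{V_{K'\mp 1} - V_{K'}}.
#'
#' @inheritParams modelEnergy
#' @param flipIndex 1-based index of the spin to flip.
#' @export
deltaEnergy <- function(model, sigma, flipIndex) {
  i <- flipIndex
  K <- sum(sigma == 1)
  Knew <- K - sigma[i]
  2 * sigma[i] * (model@h[i] + sum(model@J[i, ] * sigma)) +
    model@V[K + 1] - model@V[Knew + 1]
}

emptyTriples <- matrix(integer(0), 0, 3)

#' Exact enumeration of a small model
#'
#' Sums over all \eqn{2^N} states (N <= 20) of
#' \eqn{P(\sigma, T) \propto e^{-H(\sigma)/T}} and returns the exact
#' moments, synchrony distribution, energy/magnetization moments and the
#' response functions; the test oracle for every sampling-based routine.
#'
#' @param model a \linkS4class{KPairwiseModel} with at most 20 spins.
#' @param temperature sampling temperature (the Hamiltonian stays the
#'   T = 1 one).
#' @param triples optional 1-based triple matrix for exact third moments.
#' @param returnProbs also return the full 2^N state probabilities
#'   (states ordered by Gray code; element 1 is all spins down).
#' @return list with \code{logZ}, \code{moments} (a
#'   \linkS4class{MomentSet} with zero SEs), \code{energy} (mean, var),
#'   \code{magnetization} (mean, var), \code{cv}, \code{chi},
#'   \code{triple} (data.frame if requested), \code{probs}, and
#'   \code{states} when \code{returnProbs}.
#' @examples
#' m <- kPairwiseModel(h = c(0, 0), J = matrix(c(0, .5, .5, 0), 2))
#' enumerateModel(m)$moments@pair[1, 2]   # tanh(0.5)
#' @export
enumerateModel <- function(model, temperature = 1, triples = NULL,
                           returnProbs = FALSE) {
  n <- length(model@h)
  if (n > 20) stop("exact enumeration refused for N > 20 (state-space guard)")
  tr <- if (is.null(triples)) emptyTriples else {
    storage.mode(triples) <- "integer"; triples
  }
  res <- cpp_enumerate(model@h, model@J, model@V, temperature, returnProbs,
                       if (nrow(tr)) tr - 1L else tr)
  pair <- pairVectorToMatrix(res$pair, n, diagValue = 1)
  mom <- new("MomentSet", mean = res$mean_sigma, pair = pair,
             pk = pmax(res$pk, 0) / sum(pmax(res$pk, 0)),
             se = list(mean = numeric(n), pair = matrix(0, n, n),
                       pk = numeric(n + 1)),
             nBins = 2^n)
  varH <- res$H2 - res$H^2
  varM <- res$M2 - res$M^2
  out <- list(logZ = res$logZ, moments = mom,
              energy = list(mean = res$H, var = varH),
              magnetization = list(mean = res$M, var = varM),
              cv = varH / temperature^2, chi = varM / temperature)
  if (!is.null(triples))
    out$triple <- data.frame(i = tr[, 1], j = tr[, 2], k = tr[, 3],
                             moment = res$triple)
  if (returnProbs) {
    out$probs <- res$probs
    out$states <- grayStates(n)
  }
  out
}

# The 2^n states in the Gray-code order used by the enumerator.
grayStates <- function(n) {
  m <- matrix(-1L, 2^n, n)
  s <- rep(-1L, n)
  for (idx in seq_len(2^n - 1)) {
    b <- 1L
    mm <- idx
    while (mm %% 2 == 0) { mm <- mm %/% 2; b <- b + 1L }
    s[b] <- -s[b]
    m[idx + 1, ] <- s
  }
  m
}

resolveBurnIn <- function(cfg, n) {
  if (is.na(cfg@burnIn)) 150 * n else cfg@burnIn
}

#' Metropolis estimate of the model moments and fluctuations
#'
#' Single-spin-flip Metropolis sampling of
#' \eqn{P(\sigma, T) \propto e^{-H(\sigma)/T}} with acceptance
#' \eqn{\min(1, e^{-\Delta H/T})}; statistics are per-attempt averages
#' after a burn-in of 150 N attempts (by default), with means and
#' standard errors taken across the independent chains.
#'
#' @param model a \linkS4class{KPairwiseModel}.
#' @param temperature sampling temperature.
#' @param config a \linkS4class{SamplerConfig}.
#' @param initMode "random" or "silent" (all spins down) chain starts.
#' @param triples optional triple matrix for third-moment estimates.
#' @param pairStride attempts between pair/triple accumulations (1 =
#'   every attempt; the default N keeps the cost linear per attempt).
#' @return list with \code{moments} (\linkS4class{MomentSet}, SEs across
#'   chains), \code{energy}, \code{magnetization} (mean, var, se),
#'   \code{cv}, \code{chi} (with \code{cvSe}, \code{chiSe}), and the
#'   per-chain tables in \code{chains}.
#' @export
metropolisMoments <- function(model, temperature = 1,
                              config = samplerConfig(),
                              initMode = c("random", "silent"),
                              triples = NULL, pairStride = NULL) {
  n <- length(model@h)
  initMode <- match.arg(initMode)
  if (is.null(pairStride)) pairStride <- n
  tr <- if (is.null(triples)) emptyTriples else {
    storage.mode(triples) <- "integer"; triples
  }
  res <- cpp_metropolis(model@h, model@J, model@V, temperature,
                        config@nSamples, resolveBurnIn(config, n),
                        config@nChains, if (initMode == "random") 0L else 1L,
                        integer(0), as.integer(pairStride),
                        if (nrow(tr)) tr - 1L else tr, config@seed)
  nc <- config@nChains
  chSe <- function(x) if (nc > 1) sd(x) / sqrt(nc) else NA_real_
  m <- colMeans(res$mean_sigma)
  pk <- colMeans(res$pk)
  pk <- pmax(pk, 0); pk <- pk / sum(pk)
  if (pairStride > 0) {
    pairv <- colMeans(res$pair)
    pairSeV <- apply(res$pair, 2, chSe)
  } else {
    # pair accumulation disabled (thermo sweeps): placeholder moments
    pairv <- numeric(n * (n - 1) / 2)
    pairSeV <- numeric(n * (n - 1) / 2)
  }
  mom <- new("MomentSet", mean = m,
             pair = pairVectorToMatrix(pairv, n, diagValue = 1),
             pk = pk,
             se = list(mean = apply(res$mean_sigma, 2, chSe),
                       pair = pairVectorToMatrix(pairSeV, n, diagValue = 0),
                       pk = apply(res$pk, 2, chSe)),
             nBins = config@nSamples * nc)
  # fluctuations are pooled across chains (the estimator behind averaging
  # over many random initial configurations): chains frozen in different
  # metastable states then contribute their dispersion, which is what
  # makes the low-temperature initial-condition dependence observable
  poolStat <- function(m1, m2, denom) (mean(m2) - mean(m1)^2) / denom
  jackSe <- function(m1, m2, denom) {
    if (nc < 2) return(NA_real_)
    loo <- vapply(seq_len(nc), function(c)
      poolStat(m1[-c], m2[-c], denom), numeric(1))
    sqrt((nc - 1) / nc * sum((loo - mean(loo))^2))
  }
  out <- list(moments = mom,
              energy = list(mean = mean(res$H), se = chSe(res$H),
                            var = poolStat(res$H, res$H2, 1)),
              magnetization = list(mean = mean(res$M), se = chSe(res$M),
                                   var = poolStat(res$M, res$M2, 1)),
              cv = poolStat(res$H, res$H2, temperature^2),
              cvSe = jackSe(res$H, res$H2, temperature^2),
              chi = poolStat(res$M, res$M2, temperature),
              chiSe = jackSe(res$M, res$M2, temperature),
              chains = res)
  if (!is.null(triples))
    out$triple <- data.frame(i = tr[, 1], j = tr[, 2], k = tr[, 3],
                             moment = colMeans(res$triple),
                             se = apply(res$triple, 2, chSe))
  out
}

#' Boltzmann-machine fit of a K-pairwise model
#'
#' Gradient descent on the Lagrange multipliers driven by the gap between
#' model-sampled and data moments:
#' \eqn{h_i \leftarrow h_i - \theta(n)(\langle\sigma_i\rangle_{MEM} -
#' \langle\sigma_i\rangle_{data})} and likewise for \eqn{J_{ij}} at rate
#' \eqn{\theta(n)/2} and \eqn{V_K} at rate \eqn{\theta(n)} (switched to
#' \eqn{\theta(n)/P(K)_{data}} after \code{vkSwitchIter} iterations).
#' Initialization: \eqn{h_i = \langle\sigma_i\rangle_{data}},
#' \eqn{J = V = 0}.  Only potentials with \eqn{P(K)_{data}} above the
#' fitting threshold are learned; the rest, and the K = 0 gauge, stay
#' exactly zero.  Moments at each iteration come from a persistent
#' Metropolis chain re-equilibrated over the burn-in.
#'
#' @param data a \linkS4class{MomentSet} estimated from at least
#'   \eqn{10^4} bins.
#' @param schedule a \linkS4class{LearningSchedule}; an NA
#'   \code{pkThreshold} selects \eqn{10^{-5}} when the data has at least
#'   \eqn{10^6} bins and \eqn{10^{-4}} otherwise.
#' @param config a \linkS4class{SamplerConfig} whose \code{nSamples}
#'   overrides \code{schedule@mcSamples} when supplied.
#' @param seed RNG seed of the learning chain.
#' @return list with \code{model} (the fitted
#'   \linkS4class{KPairwiseModel}), \code{trace} (data.frame iter /
#'   discrepancies), \code{converged}, \code{iterations}.
#' @export
fitKPairwise <- function(data, schedule = learningSchedule(), config = NULL,
                         seed = 1L) {
  n <- length(data@mean)
  if (n < 2) stop("need at least 2 channels")
  if (data@nBins < 1e4)
    stop("data moments must come from at least 1e4 bins (got ",
         data@nBins, ")")
  thr <- schedule@pkThreshold
  if (is.na(thr)) thr <- if (data@nBins >= 1e6) 1e-5 else 1e-4
  fitMask <- data@pk > thr
  fitMask[1] <- FALSE                       # K = 0 is the gauge
  mc <- if (!is.null(config)) config@nSamples else schedule@mcSamples
  burn <- if (!is.null(config)) resolveBurnIn(config, n) else 150 * n
  res <- cpp_bm_fit(data@mean, pairVectorLex(data@pair), data@pk, fitMask,
                    schedule@theta0, schedule@alpha,
                    as.integer(schedule@vkSwitchIter),
                    as.integer(schedule@maxIters), mc, burn,
                    schedule@tolMean, schedule@tolPk,
                    as.integer(max(1, n %/% 2)), 1e3, as.integer(seed),
                    as.integer(max(1, schedule@maxIters %/% 400)))
  trace <- data.frame(iter = res$trace[, 1], dMean = res$trace[, 2],
                      dPkRel = res$trace[, 3], dPair = res$trace[, 4])
  if (res$diverged)
    stop("Boltzmann-machine learning diverged (a parameter exceeded 1e3) ",
         "after ", res$n_iter, " iterations; trace in the condition call")
  model <- new("KPairwiseModel", h = res$h, J = res$J, V = res$V,
               fittedMask = fitMask)
  list(model = model, trace = trace, converged = res$converged,
       iterations = res$n_iter)
}

#' Sample a synthetic raster from a model
#'
#' Rows of Metropolis states thinned by N attempts (by default); the
#' raster's statistics converge to the model's moments, which makes this
#' the generator for recovery experiments and for emulating
#' recording-style data.
#'
#' @param model a \linkS4class{KPairwiseModel}.
#' @param nBins number of raster columns to draw.
#' @param seed RNG seed.
#' @param thin Metropolis attempts between recorded states.
#' @param temperature sampling temperature.
#' @param binWidth nominal bin width stored in the raster.
#' @return a \linkS4class{BinnedRaster} (channels x bins).
#' @export
sampleRaster <- function(model, nBins, seed = 1L, thin = NULL,
                         temperature = 1, binWidth = 1) {
  n <- length(model@h)
  if (is.null(thin)) thin <- n
  if (nBins == 0)
    return(new("BinnedRaster", sigma = matrix(integer(0), n, 0),
               binWidth = binWidth))
  states <- cpp_sample_raster(model@h, model@J, model@V, temperature,
                              as.integer(nBins), as.integer(thin),
                              150 * n, 0L, integer(0), as.integer(seed))
  new("BinnedRaster", sigma = t(states), binWidth = binWidth)
}

#' Predict three-point correlations from a fitted model
#'
#' Evaluates \eqn{T_{ijk}} on Metropolis samples of the model, averaging
#' over \code{config@nChains} random-start chains (100 by default at the
#' evaluation stage) with chain-level standard errors.  The central
#' moments use the model's own sampled means.
#'
#' @param model a \linkS4class{KPairwiseModel}.
#' @param triples optional 1-based triple matrix; defaults to all triples.
#' @param config a \linkS4class{SamplerConfig}.
#' @return data.frame with i, j, k, value (the central moment
#'   \eqn{T_{ijk}}), se.
#' @export
predictThreePoint <- function(model, triples = NULL,
                              config = samplerConfig(nSamples = 3e4,
                                                     nChains = 100L)) {
  n <- length(model@h)
  if (is.null(triples)) triples <- tripleIndices(n)
  res <- metropolisMoments(model, 1, config, triples = triples,
                           pairStride = max(1L, n %/% 4L))
  ch <- res$chains
  pidx <- function(a, b) {                  # lexicographic pair index, a < b
    i0 <- a - 1; j0 <- b - 1
    i0 * n - i0 * (i0 + 1) / 2 + (j0 - i0 - 1) + 1
  }
  # per-chain central moment from raw moments:
  # T = <sss> - m_i <s_j s_k> - m_j <s_i s_k> - m_k <s_i s_j> + 2 m_i m_j m_k
  nc <- nrow(ch$mean_sigma)
  tc <- vapply(seq_len(nrow(triples)), function(r) {
    i <- triples[r, 1]; j <- triples[r, 2]; k <- triples[r, 3]
    ch$triple[, r] -
      ch$mean_sigma[, i] * ch$pair[, pidx(j, k)] -
      ch$mean_sigma[, j] * ch$pair[, pidx(i, k)] -
      ch$mean_sigma[, k] * ch$pair[, pidx(i, j)] +
      2 * ch$mean_sigma[, i] * ch$mean_sigma[, j] * ch$mean_sigma[, k]
  }, numeric(nc))
  tc <- matrix(tc, nrow = nc)
  data.frame(i = triples[, 1], j = triples[, 2], k = triples[, 3],
             value = colMeans(tc),
             se = if (nc > 1) apply(tc, 2, sd) / sqrt(nc) else NA_real_)
}
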