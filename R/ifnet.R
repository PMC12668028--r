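## Integrate-and-fire avalanche network: construction, dynamics, plasticity,
## and calibration of the recovery parameter delta_u_rec.

NEURON_DENSITY <- 0.016
INHIBITORY_FRACTION <- 0.2
DISTANCE_SCALE <- 5
DEGREE_EXPONENT <- 2
STRENGTH_INIT_RANGE <- c(0.4, 0.6)

#' Build a scale-free spatial network
#'
#' Places \code{nNeurons} neurons uniformly in the cube \eqn{[0, L]^3} with
#' \eqn{L = (N/0.016)^{1/3}} (constant density), marks a rounded 20\% of
#' them inhibitory, draws each neuron's out-degree from the discrete power
#' law \eqn{P(k) \propto k^{-2}} on \eqn{[2, 20]} (\eqn{[2, 100]} for
#' \eqn{N > 100}) and picks its post-synaptic targets without replacement
#' with probability \eqn{\propto e^{-r/5}} in the Euclidean distance
#' \eqn{r}.  Initial strengths are uniform in \eqn{[0.4, 0.6]}.
#'
#' @param nNeurons number of neurons (at least 3, so that the minimum
#'   out-degree of 2 can be realized).
#' @param params a \linkS4class{DynamicsParams} (unused in construction but
#'   kept for interface symmetry).
#' @param seed integer seed; construction is deterministic given the seed.
#' @return a \linkS4class{NetworkTopology}.
#' @examples
#' topo <- buildNetwork(50, seed = 1)
#' range(lengths(topo@edges))   # out-degrees within [2, 20]
#' @export
buildNetwork <- function(nNeurons, params = dynamicsParams(), seed = 1L) {
  nNeurons <- as.integer(nNeurons)
  kMin <- 2L
  if (nNeurons - 1L < kMin)
    stop("nNeurons is too small to realize the minimum out-degree of ", kMin)
  kMax <- if (nNeurons <= 100) 20L else 100L
  kMax <- min(kMax, nNeurons - 1L)
  L <- (nNeurons / NEURON_DENSITY)^(1 / 3)
  withSeed(seed, {
    pos <- matrix(runif(3 * nNeurons, 0, L), ncol = 3)
    inhib <- logical(nNeurons)
    inhib[sample.int(nNeurons, round(INHIBITORY_FRACTION * nNeurons))] <- TRUE
    ks <- sampleOutDegrees(nNeurons, kMin, kMax)
    edges <- vector("list", nNeurons)
    strengths <- vector("list", nNeurons)
    for (i in seq_len(nNeurons)) {
      d <- sqrt(colSums((t(pos) - pos[i, ])^2))
      w <- exp(-d / DISTANCE_SCALE)
      w[i] <- 0
      k <- min(ks[i], sum(w > 0))
      if (k < ks[i])
        warning("neuron ", i, ": out-degree truncated to ", k,
                " (too few candidates)")
      edges[[i]] <- sort(sample.int(nNeurons, k, prob = w))
      strengths[[i]] <- runif(k, STRENGTH_INIT_RANGE[1], STRENGTH_INIT_RANGE[2])
    }
    new("NetworkTopology", nNeurons = nNeurons, side = L, positions = pos,
        inhibitory = inhib, edges = edges, strengths = strengths)
  })
}

# Discrete power-law out-degrees P(k) ~ k^-2 on [kMin, kMax].
sampleOutDegrees <- function(n, kMin, kMax) {
  kk <- kMin:kMax
  p <- kk^(-DEGREE_EXPONENT)
  sample(kk, n, replace = TRUE, prob = p / sum(p))
}

#' Number of synapses of a topology
#' @param topo a \linkS4class{NetworkTopology}.
#' @export
nSynapses <- function(topo) sum(lengths(topo@edges))

#' Fresh neuron state: resting potentials, full resources, no refractoriness
#' @param topo a \linkS4class{NetworkTopology}.
#' @return list with elements \code{v}, \code{u}, \code{refractory}.
#' @export
initialState <- function(topo) {
  n <- topo@nNeurons
  list(v = numeric(n), u = rep(1, n), refractory = logical(n))
}

#' Advance one synchronous avalanche timestep (reference implementation)
#'
#' All supra-threshold, non-refractory neurons fire together: each target j
#' of a firer i receives \eqn{\pm v_i u_i g_{ij}} (negative for inhibitory
#' i), contributions summed over simultaneous firers; then every firer has
#' its resources depressed (\eqn{u_i \to u_i(1 - \delta u)}), its potential
#' reset to zero and its refractory flag set, while the previous flags are
#' cleared.  A refractory neuron accumulates input but cannot fire.
#'
#' This pure-R step is the reference against which the compiled recording
#' loop is tested; use \code{\link{runRecording}} for long runs.
#'
#' @param state list(v, u, refractory) as from \code{\link{initialState}}.
#' @param topo a \linkS4class{NetworkTopology}.
#' @param params a \linkS4class{DynamicsParams}.
#' @return list(state = updated state, fired = integer ids of the firers).
#' @export
advanceAvalancheStep <- function(state, topo, params = dynamicsParams()) {
  firers <- which(state$v >= params@vThreshold & !state$refractory)
  if (!length(firers))
    stop("no supra-threshold non-refractory neuron: not an avalanche step")
  dv <- numeric(topo@nNeurons)
  for (i in firers) {
    amp <- state$v[i] * state$u[i] * (if (topo@inhibitory[i]) -1 else 1)
    tg <- topo@edges[[i]]
    dv[tg] <- dv[tg] + amp * topo@strengths[[i]]
  }
  state$refractory[] <- FALSE
  state$v <- state$v + dv
  state$u[firers] <- state$u[firers] * (1 - params@deltaU)
  state$v[firers] <- 0
  state$refractory[firers] <- TRUE
  list(state = state, fired = firers)
}

#' Long-term synaptic adaptation for one set of post-synaptic changes
#'
#' During an avalanche each used synapse is potentiated proportionally to
#' the potential change it caused in its target,
#' \eqn{\delta g_j = \beta \Delta v_j}; at the end of the avalanche all
#' synapses are depressed by the mean increment
#' \eqn{(1/N_s)\sum \delta g_j}.  Strengths are clipped to
#' \eqn{[g_{min}, 1]}.
#'
#' @param topo a \linkS4class{NetworkTopology}.
#' @param deltaVPost data.frame with columns \code{from}, \code{edge}
#'   (index into \code{topo@edges[[from]]}) and \code{dv}, the potential
#'   change each synapse caused.  May have zero rows.
#' @param params a \linkS4class{DynamicsParams}.
#' @param finalize if TRUE, also apply the end-of-avalanche normalization
#'   using the total increment accumulated in \code{attr(, "sumDeltaG")}.
#' @return the updated topology; the summed increment is attached as
#'   attribute \code{sumDeltaG}.
#' @export
applyLongTermStep <- function(topo, deltaVPost, params = dynamicsParams(),
                              finalize = FALSE) {
  sumDg <- attr(topo, "sumDeltaG")
  if (is.null(sumDg)) sumDg <- 0
  if (nrow(deltaVPost)) {
    for (r in seq_len(nrow(deltaVPost))) {
      i <- deltaVPost$from[r]; e <- deltaVPost$edge[r]
      dg <- params@beta * deltaVPost$dv[r]
      sumDg <- sumDg + dg
      g <- topo@strengths[[i]][e] + dg
      topo@strengths[[i]][e] <- min(1, max(params@gMin, g))
    }
  }
  if (finalize) {
    m <- sumDg / nSynapses(topo)
    topo@strengths <- lapply(topo@strengths,
                             function(g) pmin(1, pmax(params@gMin, g - m)))
    sumDg <- 0
  }
  attr(topo, "sumDeltaG") <- sumDg
  topo
}

# Flatten a topology to the CSR arrays the compiled loop uses.
topologyCSR <- function(topo) {
  k <- lengths(topo@edges)
  list(ptr = as.integer(c(0, cumsum(k))),
       tgt = as.integer(unlist(topo@edges, use.names = FALSE) - 1L),
       g = as.numeric(unlist(topo@strengths, use.names = FALSE)))
}

csrToTopology <- function(topo, g) {
  k <- lengths(topo@edges)
  topo@strengths <- split(g, rep.int(seq_along(k), k))
  names(topo@strengths) <- NULL
  topo
}

#' Run the avalanche dynamics and record spikes
#'
#' Quiescent timesteps add the external drive \eqn{\delta v} to one
#' uniformly random neuron; when any potential reaches threshold an
#' avalanche unfolds by synchronous steps (see
#' \code{\link{advanceAvalancheStep}}) until all potentials fall below
#' threshold; after each avalanche every neuron's resources recover by
#' \eqn{\delta u_{rec}}, capped at 1.  The clock counts quiescent and
#' avalanche timesteps alike.  With \code{plasticityOn}, the long-term
#' adaptation rule reshapes the synaptic strengths (see
#' \code{\link{applyLongTermStep}}).
#'
#' @param topo a \linkS4class{NetworkTopology}.
#' @param params a \linkS4class{DynamicsParams}.
#' @param nTimesteps,nAvalanches the run budget; supply exactly one.
#' @param seed integer seed for the drive (and nothing else).
#' @param plasticityOn apply the long-term adaptation rule.
#' @param stopAtGMin stop as soon as a synaptic strength first reaches
#'   \eqn{g_{min}} (pre-training semantics).
#' @param state optional initial list(v, u, refractory); defaults to
#'   \code{\link{initialState}}.
#' @return list with \code{events} (\linkS4class{SpikeEvents}),
#'   \code{catalog} (data.frame start/duration/size, one row per
#'   avalanche), \code{topology} (with updated strengths), \code{state}
#'   (final v, u), \code{gMinHit} and \code{nTimesteps}.
#' @examples
#' topo <- buildNetwork(30, seed = 2)
#' rec <- runRecording(topo, dynamicsParams(deltaURec = 0.01),
#'                     nTimesteps = 2000, seed = 3)
#' nrow(rec$catalog)                        # avalanches observed
#' sum(rec$catalog$size) == length(rec$events@time)   # spike conservation
#' @export
runRecording <- function(topo, params, nTimesteps = NULL, nAvalanches = NULL,
                         seed = 1L, plasticityOn = FALSE, stopAtGMin = FALSE,
                         state = NULL) {
  if (is.null(nTimesteps) == is.null(nAvalanches))
    stop("supply exactly one of nTimesteps or nAvalanches")
  if (is.null(state)) state <- initialState(topo)
  csr <- topologyCSR(topo)
  res <- cpp_run_recording(csr$ptr, csr$tgt, csr$g, topo@inhibitory,
                           state$v, state$u,
                           params@vThreshold, params@deltaU, params@deltaURec,
                           params@deltaV, params@beta, params@gMin,
                           if (is.null(nTimesteps)) 0 else nTimesteps,
                           if (is.null(nAvalanches)) 0 else nAvalanches,
                           plasticityOn, stopAtGMin, 0, as.integer(seed))
  events <- new("SpikeEvents", time = as.numeric(res$spike_t),
                channel = as.integer(res$spike_id + 1L),
                nChannels = topo@nNeurons,
                nTimesteps = max(res$t_end, 1), dtMs = NA_real_)
  catalog <- data.frame(start = res$av_start, duration = res$av_dur,
                        size = res$av_size)
  list(events = events, catalog = catalog,
       topology = csrToTopology(topo, res$g),
       state = list(v = res$v, u = res$u),
       gMinHit = res$gmin_hit, nTimesteps = res$t_end)
}

#' Pre-train a network with long-term plasticity
#'
#' Applies the long-term adaptation rule for
#' \code{params@pretrainAvalanches} avalanches (default \eqn{10^4}) or
#' until a synaptic strength first reaches \eqn{g_{min}}, whichever comes
#' first; this shapes the synaptic strength distribution before
#' measurement runs, which are then performed with plasticity off.
#'
#' Long-term adaptation shapes the stationary dynamics, so the plastic
#' avalanches act on the self-organized steady state: the network is first
#' relaxed with plasticity off (\code{warmupAvalanches}) before the
#' adaptation rule is switched on.  Without the warm-up, the very first
#' avalanche from the fresh all-resources state is system-spanning and its
#' end-of-avalanche normalization collapses every synapse to \eqn{g_{min}}
#' in one step.
#'
#' @inheritParams runRecording
#' @param warmupAvalanches plasticity-off avalanches run first to relax
#'   the membrane potentials and resources to their stationary profile.
#' @return the trained \linkS4class{NetworkTopology}.
#' @export
pretrainNetwork <- function(topo, params, seed = 1L,
                            warmupAvalanches = 2000) {
  if (params@pretrainAvalanches == 0) return(topo)
  state <- NULL
  if (warmupAvalanches > 0) {
    warm <- runRecording(topo, params, nAvalanches = warmupAvalanches,
                         seed = deriveSeed(seed, "warmup"))
    state <- warm$state
    state$refractory <- logical(topo@nNeurons)
  }
  res <- runRecording(topo, params, nAvalanches = params@pretrainAvalanches,
                      seed = seed, plasticityOn = TRUE, stopAtGMin = TRUE,
                      state = state)
  if (nrow(res$catalog) == 0)
    stop("pre-training produced no avalanches; deltaURec = ",
         params@deltaURec, " is too small for the drive settings")
  res$topology
}

#' Calibrate the recovery parameter to the critical point
#'
#' Scans a geometric grid of candidate \eqn{\delta u_{rec}} values (12 per
#' decade over three decades by default), classifying the avalanche size
#' and duration distributions of a pre-trained network at each candidate
#' with \code{\link{classifyState}}, then refines once around the critical
#' plateau.  The returned estimate is the geometric midpoint of the
#' critical plateau; by construction of the dynamics, one tenth of it
#' classifies subcritical and ten times it supercritical.
#'
#' @param nNeurons system size.
#' @param params baseline \linkS4class{DynamicsParams} (its deltaURec is
#'   ignored).
#' @param seed integer master seed (topology, pre-training and
#'   measurement streams are derived from it).
#' @param gridRange numeric(2), range of the candidate grid.
#' @param perDecade candidates per decade.
#' @param nAvalanches measurement avalanches per candidate (at least
#'   1000 for a stable classification).
#' @return list with \code{estimate}, the candidate table
#'   (\code{candidates}: deltaURec, label) and the refined table.
#' @export
calibrateDeltaURec <- function(nNeurons, params = dynamicsParams(),
                               seed = 1L, gridRange = c(1e-4, 1e-1),
                               perDecade = 12, nAvalanches = 8000) {
  nDec <- log10(gridRange[2] / gridRange[1])
  grid <- 10^seq(log10(gridRange[1]), log10(gridRange[2]),
                 length.out = round(perDecade * nDec) + 1)
  scan <- scanDeltaURec(nNeurons, params, seed, grid, nAvalanches)
  plateau <- criticalPlateau(scan)
  if (!length(plateau)) {
    print(scan)
    stop("no candidate classified critical; see the table above")
  }
  # refine once around the onset of the critical plateau (the sub -> crit
  # boundary is the sharp feature; the upper boundary is classification-
  # noise limited)
  lo <- grid[max(1, min(plateau) - 1)]
  hi <- grid[min(length(grid), plateau[min(length(plateau), 6)] + 1)]
  fine <- 10^seq(log10(lo), log10(hi), length.out = perDecade + 2)
  refined <- scanDeltaURec(nNeurons, params, seed, fine, nAvalanches)
  plateauF <- criticalPlateau(refined)
  est <- if (length(plateauF))
    exp(mean(log(refined$deltaURec[head(plateauF, 6)])))
  else exp(mean(log(grid[head(plateau, 6)])))
  list(estimate = est, candidates = scan, refined = refined)
}

# Indices of the first contiguous run of "critical" labels (the critical
# plateau above the sub -> crit boundary).
criticalPlateau <- function(scan) {
  lab <- scan$label
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values == "critical" & !is.na(r$values))
  if (!length(hit)) return(integer(0))
  seq(starts[hit[1]], ends[hit[1]])
}

scanDeltaURec <- function(nNeurons, params, seed, grid, nAvalanches) {
  labels <- character(length(grid))
  for (ci in seq_along(grid)) {
    p <- params
    p@deltaURec <- grid[ci]
    labels[ci] <- tryCatch({
      topo <- buildNetwork(nNeurons, p, seed = deriveSeed(seed, "topo"))
      topo <- pretrainNetwork(topo, p, seed = deriveSeed(seed, "pre", ci))
      run <- runRecording(topo, p, nAvalanches = nAvalanches,
                          seed = deriveSeed(seed, "meas", ci))
      cls <- classifyState(avalancheDistributions(run$catalog), nNeurons)
      cls$label
    }, error = function(e) NA_character_)
  }
  data.frame(deltaURec = grid, label = labels)
}

#' Simulate one dynamical regime with the standard protocol
#'
#' Builds a network, pre-trains it with long-term plasticity at the
#' \emph{critical} recovery value (networks develop under physiological
#' conditions; the off-critical regimes are perturbations applied
#' afterwards, mirroring drug application to a mature culture), then
#' relaxes and records at the regime's recovery value
#' (\eqn{0.1\times}, \eqn{1\times} or \eqn{10\times} critical) with
#' plasticity off.
#'
#' @param nNeurons system size.
#' @param deltaURecCrit calibrated critical recovery value for this size.
#' @param state "sub", "crit" or "super".
#' @param seed master seed for this run.
#' @param nTimesteps,nAvalanches measurement budget (exactly one).
#' @param params baseline parameters.
#' @param relaxAvalanches plasticity-off avalanches run at the regime
#'   value before measurement starts, so that measurements sample the
#'   regime's stationary state.
#' @return as \code{\link{runRecording}}.
#' @export
simulateStateRun <- function(nNeurons, deltaURecCrit,
                             state = c("crit", "sub", "super"), seed = 1L,
                             nTimesteps = NULL, nAvalanches = NULL,
                             params = dynamicsParams(),
                             relaxAvalanches = 1000) {
  state <- match.arg(state)
  pCrit <- params; pCrit@deltaURec <- deltaURecCrit
  pMeas <- params
  pMeas@deltaURec <- deltaURecForState(deltaURecCrit, state)
  topo <- buildNetwork(nNeurons, pCrit, seed = deriveSeed(seed, "topo"))
  topo <- pretrainNetwork(topo, pCrit, seed = deriveSeed(seed, "pretrain"))
  st <- NULL
  if (relaxAvalanches > 0) {
    relax <- runRecording(topo, pMeas, nAvalanches = relaxAvalanches,
                          seed = deriveSeed(seed, "relax"))
    st <- relax$state
    st$refractory <- logical(nNeurons)
  }
  runRecording(topo, pMeas, nTimesteps = nTimesteps,
               nAvalanches = nAvalanches, seed = deriveSeed(seed, "measure"),
               state = st)
}

#' Convenience: the three dynamical regimes from one calibrated value
#'
#' @param deltaURecCrit the calibrated critical recovery value.
#' @param state "sub", "crit" or "super".
#' @return the deltaURec for the requested regime: 0.1x, 1x or 10x the
#'   critical value.
#' @export
deltaURecForState <- function(deltaURecCrit, state = c("crit", "sub", "super")) {
  state <- match.arg(state)
  deltaURecCrit * switch(state, sub = 0.1, crit = 1, super = 10)
}
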