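## Avalanche size/duration distributions and the operational classification
## of a dataset as subcritical, critical or supercritical.

#' Log-binned avalanche size and duration distributions
#'
#' Histograms P(S) and P(D) on a logarithmic grid with bin ratio
#' \eqn{2^{1/4}}; bins narrower than one integer collapse onto single
#' integers, so the head of the distribution is exact.  Probabilities are
#' per integer value (density), normalized over the observed support.
#'
#' @param catalog data.frame with columns \code{size} and \code{duration}
#'   (as returned by \code{\link{runRecording}}).
#' @return object of class \code{AvalancheDistributions}: list with
#'   \code{size} and \code{duration} tables (center, p, count), the raw
#'   vectors, maxima and the avalanche count.
#' @export
avalancheDistributions <- function(catalog) {
  if (!nrow(catalog)) stop("empty avalanche catalog")
  out <- list(size = logBinnedPMF(catalog$size),
              duration = logBinnedPMF(catalog$duration),
              rawSize = catalog$size, rawDuration = catalog$duration,
              maxSize = max(catalog$size), maxDuration = max(catalog$duration),
              nAvalanches = nrow(catalog))
  class(out) <- "AvalancheDistributions"
  out
}

#' @export
print.AvalancheDistributions <- function(x, ...) {
  cat("AvalancheDistributions:", x$nAvalanches, "avalanches; max size",
      x$maxSize, "; max duration", x$maxDuration, "\n")
  invisible(x)
}

# Probability mass per integer value on a log grid of ratio 2^(1/4).
logBinnedPMF <- function(x, ratio = 2^0.25) {
  stopifnot(all(x >= 1))
  xmax <- max(x)
  edges <- unique(floor(ratio^(0:ceiling(log(xmax + 1, ratio)))))
  edges <- edges[edges <= xmax + 1]
  if (edges[length(edges)] <= xmax) edges <- c(edges, xmax + 1)
  cnt <- tabulate(findInterval(x, edges), nbins = length(edges) - 1)
  width <- diff(edges)                      # integers per bin
  center <- exp((log(edges[-length(edges)]) + log(edges[-1] - 1)) / 2)
  center[width == 1] <- edges[-length(edges)][width == 1]
  data.frame(center = center, p = cnt / (length(x) * width), count = cnt,
             lower = edges[-length(edges)], upper = edges[-1] - 1)
}

# Truncated discrete power-law MLE on x >= xmin (support xmin..xmax).
fitDiscretePowerLaw <- function(x, xmin = 2) {
  x <- x[x >= xmin]
  xmax <- max(x)
  supp <- xmin:xmax
  nll <- function(tau) {
    logZ <- log(sum(supp^(-tau)))
    tau * mean(log(x)) + logZ
  }
  opt <- optimize(nll, c(1.01, 6))
  list(exponent = opt$minimum, logLik = -length(x) * opt$objective, n = length(x))
}

# Geometric (discrete exponential) MLE on x >= xmin.
fitDiscreteExponential <- function(x, xmin = 2) {
  x <- x[x >= xmin]
  m <- mean(x - xmin)
  p <- 1 / (1 + m)                      # P(x) = p (1-p)^(x - xmin)
  ll <- sum(log(p) + (x - xmin) * log1p(-p))
  list(rate = -log1p(-p), logLik = ll, n = length(x))
}

# Akaike weight of the exponential model against the power law (both one
# parameter, so this is a plain likelihood ratio on the Akaike scale).
exponentialWeight <- function(x, xmin = 2) {
  pl <- fitDiscretePowerLaw(x, xmin)
  ex <- fitDiscreteExponential(x, xmin)
  d <- ex$logLik - pl$logLik
  w <- 1 / (1 + exp(-d))
  list(weight = w, powerLaw = pl, exponential = ex)
}

# Bump detection: a local probability excess at large sizes, measured as
# the dip-to-peak prominence of the log-binned distribution (power laws
# and exponentials decay monotonically, so any substantial rise marks the
# supercritical excess of system-spanning events).  Returns the center of
# the peak, or NA.
detectBump <- function(tab, minCenter, minRise = 0.5, minCount = 4) {
  tab <- tab[tab$count >= minCount, , drop = FALSE]
  if (nrow(tab) < 3) return(NA_real_)
  lp <- log(tab$p)
  best <- NA_real_
  bestRise <- 0
  for (i in seq_len(nrow(tab) - 1)) {
    later <- which(tab$center > minCenter)
    later <- later[later > i]
    if (!length(later)) next
    r <- lp[later] - lp[i]
    if (max(r) > bestRise) {
      bestRise <- max(r)
      best <- tab$center[later[which.max(r)]]
    }
  }
  if (bestRise > minRise) best else NA_real_
}

# Tail excess over the extrapolated power-law trend: fit log p ~ log S on
# the intermediate range [4, N/2] and measure how far the observed tail
# (S > N/2) sits above the extrapolation.  A supercritical excess of
# system-spanning avalanches shows up as a strongly positive residual; a
# critical cut-off as a negative one.
tailTrendExcess <- function(tab, nScale, minCount = 10) {
  fitTab <- tab[tab$center >= 4 & tab$center <= nScale / 2 &
                tab$count >= minCount, , drop = FALSE]
  tailTab <- tab[tab$center > nScale / 2 & tab$count >= minCount, ,
                 drop = FALSE]
  if (nrow(fitTab) < 4 || nrow(tailTab) < 1) return(NA_real_)
  fit <- lm(log(p) ~ log(center), data = fitTab)
  pred <- predict(fit, newdata = tailTab)
  max(log(tailTab$p) - pred)
}

#' Reconstruct an avalanche catalog from a spike event list
#'
#' Groups time-ordered events into avalanches by the quiescence between
#' them: a new avalanche starts whenever the gap to the previous event
#' exceeds \code{maxGap} timesteps.  For the integrate-and-fire dynamics
#' this reconstruction is exact up to rare refractory-only steps inside an
#' avalanche (hence the default gap of 2).
#'
#' @param events a \linkS4class{SpikeEvents}.
#' @param maxGap largest within-avalanche silent gap, in timesteps.
#' @return data.frame with columns start, duration, size.
#' @export
eventsToCatalog <- function(events, maxGap = 2) {
  if (!length(events@time))
    return(data.frame(start = numeric(0), duration = numeric(0),
                      size = numeric(0)))
  tm <- events@time
  newAv <- c(TRUE, diff(tm) > maxGap)
  id <- cumsum(newAv)
  start <- tapply(tm, id, min)
  end <- tapply(tm, id, max)
  data.frame(start = as.numeric(start),
             duration = as.numeric(end - start + 1),
             size = as.numeric(tabulate(id)))
}

#' Classify avalanche dynamics as subcritical, critical or supercritical
#'
#' Operational criteria: a dataset is \emph{supercritical} when the size
#' distribution shows a local probability excess (a rising stretch of the
#' log-binned P(S)) at sizes beyond half the system scale -- the bump near
#' the power-law cut-off; it is \emph{subcritical} when a discrete
#' exponential beats the truncated power law in an Akaike-weighted
#' likelihood comparison over \eqn{S \ge 2} and avalanches stay well below
#' the system-size cut-off; otherwise it is \emph{critical}.  The duration
#' distribution serves as a tie-breaker when the size-based evidence is
#' marginal.
#'
#' @param dist an \code{AvalancheDistributions} object.
#' @param nNeurons system size N, setting the cut-off scale.
#' @param minAvalanches minimum catalog size for a stable label.
#' @param tailThreshold minimum probability of avalanches reaching half
#'   the system scale, \eqn{P(S \ge N/2)}, for the distribution to count
#'   as cut off at the system size rather than well before it.
#' @return list with \code{label} (one of "subcritical", "critical",
#'   "supercritical") and \code{evidence} (named numeric scores).
#' @export
classifyState <- function(dist, nNeurons, minAvalanches = 1000,
                          tailThreshold = 3e-3) {
  if (dist$nAvalanches < minAvalanches)
    stop("need at least ", minAvalanches,
         " avalanches for a stable classification (got ",
         dist$nAvalanches, ")")
  wS <- exponentialWeight(dist$rawSize)
  bumpS <- detectBump(dist$size, minCenter = 0.5 * nNeurons)
  # durations as tie-breaker: a duration bump also marks the excess of
  # system-spanning events when the size bump is marginal
  bumpD <- detectBump(dist$duration, minCenter = 0.25 * nNeurons)
  excess <- tailTrendExcess(dist$size, nNeurons)
  q99 <- unname(quantile(dist$rawSize, 0.99))
  tailFrac <- mean(dist$rawSize >= nNeurons / 2)
  evidence <- c(expWeightSize = wS$weight,
                sizeExponent = wS$powerLaw$exponent,
                bumpCenter = bumpS, bumpCenterDuration = bumpD,
                tailExcess = excess,
                q99Size = q99, tailFraction = tailFrac,
                maxSize = dist$maxSize)
  label <- if (!is.na(bumpS) || !is.na(bumpD) ||
               (!is.na(excess) && excess > 0.7)) {
    "supercritical"
  } else if ((wS$weight > 0.5 && q99 < nNeurons / 2) ||
             tailFrac < tailThreshold) {
    # exponential-like decay, or a distribution that dies well before the
    # system-size cut-off: no scaling up to the system scale
    "subcritical"
  } else {
    "critical"
  }
  list(label = label, evidence = evidence)
}
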