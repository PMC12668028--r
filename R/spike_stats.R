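## Binning of event lists and the constrained statistics: local activities,
## pairwise moments, synchrony distribution P(K), three-point correlations,
## firing rates and their allometric scaling.

#' Bin a spike event list into a +/-1 raster
#'
#' \code{sigma[i, k] = +1} iff channel i has at least one event in bin k
#' (multiplicity is ignored); the trailing partial bin is dropped.
#'
#' @param events a \linkS4class{SpikeEvents}.
#' @param binWidth bin duration in event-clock units (>= 1).
#' @return a \linkS4class{BinnedRaster}.
#' @examples
#' ev <- new("SpikeEvents", time = c(3, 27), channel = c(1L, 1L),
#'           nChannels = 2L, nTimesteps = 100, dtMs = 1)
#' raster <- binEvents(ev, 25)
#' sigmaMatrix(raster)[1, ]   # bins 1 and 2 active, rest silent
#' @export
binEvents <- function(events, binWidth) {
  stopifnot(binWidth >= 1)
  nb <- floor(events@nTimesteps / binWidth)
  sig <- matrix(-1L, nrow = events@nChannels, ncol = nb)
  if (length(events@time)) {
    bin <- floor(events@time / binWidth) + 1
    keep <- bin <= nb
    sig[cbind(events@channel[keep], bin[keep])] <- 1L
  }
  new("BinnedRaster", sigma = sig, binWidth = binWidth)
}

#' Constrained statistics of a raster, with block standard errors
#'
#' Computes \eqn{\langle\sigma_i\rangle}, the pairwise moments
#' \eqn{\langle\sigma_i\sigma_j\rangle} and the synchrony distribution
#' \eqn{P(K)} over the bins.  Standard errors come from \code{nBlocks}
#' contiguous block subsets of the bins (the blocked mean respects
#' temporal correlation; the SE is the standard deviation of the block
#' statistics over \eqn{\sqrt{nBlocks}}).
#'
#' @param raster a \linkS4class{BinnedRaster}.
#' @param nBlocks number of contiguous blocks for the standard errors
#'   (reduced when there are fewer bins than blocks).
#' @return a \linkS4class{MomentSet}.
#' @export
computeMoments <- function(raster, nBlocks = 100) {
  sig <- raster@sigma
  nb <- ncol(sig)
  if (nb == 0) stop("raster has no bins")
  n <- nrow(sig)
  sigd <- sig
  storage.mode(sigd) <- "double"
  m <- rowMeans(sigd)
  pair <- tcrossprod(sigd) / nb
  diag(pair) <- 1
  K <- colSums(sig == 1L)
  pk <- tabulate(K + 1L, nbins = n + 1L) / nb
  nBlocks <- min(nBlocks, nb)
  idx <- splitBlocks(nb, nBlocks)
  bm <- matrix(0, nBlocks, n)
  bpk <- matrix(0, nBlocks, n + 1)
  pairAcc <- matrix(0, n, n)
  pairAcc2 <- matrix(0, n, n)
  for (b in seq_len(nBlocks)) {
    sl <- sigd[, idx[[b]], drop = FALSE]
    bm[b, ] <- rowMeans(sl)
    bp <- tcrossprod(sl) / ncol(sl)
    pairAcc <- pairAcc + bp
    pairAcc2 <- pairAcc2 + bp^2
    bpk[b, ] <- tabulate(K[idx[[b]]] + 1L, nbins = n + 1L) / length(idx[[b]])
  }
  pairSe <- sqrt(pmax(pairAcc2 / nBlocks - (pairAcc / nBlocks)^2, 0) / nBlocks)
  diag(pairSe) <- 0
  se <- list(mean = apply(bm, 2, sd) / sqrt(nBlocks),
             pair = pairSe,
             pk = apply(bpk, 2, sd) / sqrt(nBlocks))
  new("MomentSet", mean = m, pair = pair, pk = pk, se = se, nBins = nb)
}

splitBlocks <- function(nb, nBlocks) {
  split(seq_len(nb), cut(seq_len(nb), nBlocks, labels = FALSE))
}

#' Three-point central-moment correlations
#'
#' \eqn{T_{ijk} = \langle(\sigma_i - \langle\sigma_i\rangle)(\sigma_j -
#' \langle\sigma_j\rangle)(\sigma_k - \langle\sigma_k\rangle)\rangle} for
#' unordered channel triples; invariant under permutations of (i, j, k)
#' and not constrained by the K-pairwise fit, hence the standard test of
#' its predictive power.
#'
#' @param raster a \linkS4class{BinnedRaster}.
#' @param triples optional integer matrix (rows = triples, 1-based); by
#'   default all \eqn{\binom{N}{3}} triples (N < 3 gives an empty result).
#' @return data.frame with columns i, j, k, value.
#' @export
threePointCorrelations <- function(raster, triples = NULL) {
  n <- nrow(raster@sigma)
  if (is.null(triples)) triples <- tripleIndices(n)
  if (!nrow(triples))
    return(data.frame(i = integer(0), j = integer(0), k = integer(0),
                      value = numeric(0)))
  storage.mode(triples) <- "integer"
  val <- cpp_three_point(raster@sigma, triples - 1L)
  data.frame(i = triples[, 1], j = triples[, 2], k = triples[, 3],
             value = val)
}

#' Convert a raster back to a spike event list
#'
#' Each active bin becomes one event stamped at the bin start; the inverse
#' of \code{\link{binEvents}} up to within-bin timing and multiplicity.
#'
#' @param raster a \linkS4class{BinnedRaster}.
#' @param dtMs clock unit of the resulting events in milliseconds (NA for
#'   dimensionless model time).
#' @return a \linkS4class{SpikeEvents}.
#' @export
rasterToEvents <- function(raster, dtMs = NA_real_) {
  act <- which(raster@sigma == 1L, arr.ind = TRUE)
  tm <- (act[, 2] - 1) * raster@binWidth
  o <- order(tm, act[, 1])
  new("SpikeEvents", time = tm[o], channel = as.integer(act[o, 1]),
      nChannels = nrow(raster@sigma),
      nTimesteps = ncol(raster@sigma) * raster@binWidth, dtMs = dtMs)
}

#' Per-channel firing rates and the population total
#'
#' \eqn{r_i = (\langle\sigma_i\rangle + 1) / (2 \Delta t_b)}: the active-bin
#' fraction per unit of the event clock, or in Hz when the bin duration is
#' given in seconds.
#'
#' @param raster a \linkS4class{BinnedRaster} (or a
#'   \linkS4class{MomentSet}).
#' @param binSeconds optional bin duration in seconds; if supplied, rates
#'   are returned in Hz instead of per clock unit.
#' @return list with \code{rates} (per channel) and \code{total}
#'   (\eqn{n_a = \sum_i r_i}).
#' @export
firingRates <- function(raster, binSeconds = NULL) {
  m <- if (is(raster, "MomentSet")) raster@mean else rowMeans(raster@sigma)
  denom <- if (is.null(binSeconds)) {
    if (is(raster, "MomentSet"))
      stop("supply binSeconds when starting from a MomentSet")
    raster@binWidth
  } else binSeconds
  r <- (m + 1) / (2 * denom)
  list(rates = r, total = sum(r))
}

#' Allometric scaling of the total firing rate
#'
#' Least-squares fit of \eqn{\log n_a} against \eqn{\log N}; the total
#' population rate grows as \eqn{n_a \propto N^\eta} with \eqn{\eta < 1}
#' (sublinear) in all three dynamical regimes of the avalanche network.
#' The exponent's standard error is bootstrapped over replicates when a
#' \code{replicate} column is present (resampling replicates within each
#' N), else over case resampling.
#'
#' @param data data.frame with columns \code{n}, \code{na} and optionally
#'   \code{replicate}.
#' @param nBoot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{eta}, \code{etaSe}, and the \code{fit} lm
#'   object.
#' @examples
#' d <- data.frame(n = c(20, 40, 80, 100), na = 2 * c(20, 40, 80, 100)^0.8)
#' allometricFit(d)$eta    # exactly 0.8
#' @export
allometricFit <- function(data, nBoot = 1000, seed = 1L) {
  stopifnot(all(data$na > 0), all(data$n > 0))
  fit <- lm(log(na) ~ log(n), data = data)
  eta <- unname(coef(fit)[2])
  etaSe <- withSeed(seed, {
    slopes <- vapply(seq_len(nBoot), function(b) {
      res <- if ("replicate" %in% names(data)) {
        do.call(rbind, lapply(split(data, data$n), function(d)
          d[sample.int(nrow(d), replace = TRUE), , drop = FALSE]))
      } else data[sample.int(nrow(data), replace = TRUE), , drop = FALSE]
      if (length(unique(res$n)) < 2) return(NA_real_)
      unname(coef(lm(log(na) ~ log(n), data = res))[2])
    }, numeric(1))
    sd(slopes, na.rm = TRUE)
  })
  list(eta = eta, etaSe = etaSe, fit = fit)
}
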