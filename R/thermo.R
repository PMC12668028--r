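## Temperature sweeps of the inferred models: specific heat and
## susceptibility from energy/magnetization fluctuations, maxima location,
## glassy-onset detection and finite-size scaling of the maxima.

#' Default temperature grid
#'
#' 60 geometrically spaced points on [0.01, 3.00] plus a dense linear
#' insert of 21 points on [0.8, 1.6], where the response maxima of
#' data-inferred models live.
#'
#' @return sorted numeric grid.
#' @export
defaultTemperatureGrid <- function() {
  sort(unique(signif(c(10^seq(log10(0.01), log10(3), length.out = 60),
                       seq(0.8, 1.6, length.out = 21)), 10)))
}

#' Temperature sweep of Cv and chi
#'
#' At each grid temperature, Metropolis sampling of
#' \eqn{P(\sigma, T) \propto e^{-H(\sigma)/T}} (the Hamiltonian is always
#' the T = 1 one; temperature enters the acceptance rule and the
#' fluctuation prefactors only) yields
#' \eqn{C_v = (\langle H^2\rangle - \langle H\rangle^2)/T^2} and
#' \eqn{\chi = (\langle M^2\rangle - \langle M\rangle^2)/T}, with standard
#' errors across the independent chains.
#'
#' @param model a \linkS4class{KPairwiseModel}.
#' @param tGrid temperature grid within [0.01, 3].
#' @param config a \linkS4class{SamplerConfig} (per-temperature budget).
#' @param initMode "random" or "silent" chain starts.
#' @return a \linkS4class{ThermoCurve}.
#' @export
responseCurve <- function(model, tGrid = defaultTemperatureGrid(),
                          config = samplerConfig(nSamples = 3e4, nChains = 8L),
                          initMode = c("random", "silent")) {
  initMode <- match.arg(initMode)
  stopifnot(all(tGrid > 0))
  k <- length(tGrid)
  cv <- cvSe <- chi <- chiSe <- numeric(k)
  for (ti in seq_len(k)) {
    cfg <- config
    cfg@seed <- deriveSeed(config@seed, "thermo", ti)
    r <- metropolisMoments(model, tGrid[ti], cfg, initMode = initMode,
                           pairStride = 0L)
    cv[ti] <- max(0, r$cv); cvSe[ti] <- r$cvSe
    chi[ti] <- max(0, r$chi); chiSe[ti] <- r$chiSe
  }
  new("ThermoCurve", temperatures = tGrid, cv = cv, cvSe = cvSe,
      chi = chi, chiSe = chiSe, initMode = initMode)
}

#' Locate the maximum of a response curve
#'
#' Grid argmax refined by a local quadratic interpolation over the 5
#' surrounding points (in log T); a maximum sitting on the grid edge is
#' flagged non-interior.  When a glassy onset temperature is supplied the
#' search is restricted to T > tStar, since sub-T* values are sampling
#' artifacts.
#'
#' @param curve a \linkS4class{ThermoCurve}.
#' @param observable "cv" or "chi".
#' @param tMin optional lower temperature cut (e.g. a detected T*).
#' @return list with \code{tMax}, \code{value}, \code{interior}.
#' @export
locateMaximum <- function(curve, observable = c("cv", "chi"), tMin = NULL) {
  observable <- match.arg(observable)
  y <- slot(curve, observable)
  tg <- curve@temperatures
  keep <- if (is.null(tMin)) rep(TRUE, length(tg)) else tg > tMin
  y <- y[keep]; tg <- tg[keep]
  i <- which.max(y)
  interior <- i > 1 && i < length(y)
  tMax <- tg[i]; value <- y[i]
  if (interior) {
    lo <- max(1, i - 2); hi <- min(length(y), i + 2)
    x <- log(tg[lo:hi]); yy <- y[lo:hi]
    fit <- lm(yy ~ x + I(x^2))
    a <- coef(fit)
    if (is.finite(a[3]) && a[3] < 0) {
      xs <- -a[2] / (2 * a[3])
      if (xs >= min(x) && xs <= max(x)) {
        tMax <- exp(xs)
        value <- unname(a[1] + a[2] * xs + a[3] * xs^2)
      }
    }
  }
  list(tMax = unname(tMax), value = unname(value), interior = interior)
}

#' Detect the glassy onset temperature T*
#'
#' Runs paired temperature sweeps from (a) uniformly random initial spin
#' states and (b) the all-silent state \eqn{\sigma = -1}.  T* is the
#' largest grid temperature below which either Cv or chi differs between
#' the two sweeps by more than 3 combined standard errors on two
#' consecutive grid points; when the sweeps agree everywhere the grid
#' minimum is returned as a sentinel with \code{detected = FALSE}.
#'
#' @inheritParams responseCurve
#' @return list with \code{tStar}, \code{detected}, and the two
#'   \linkS4class{ThermoCurve}s (\code{random}, \code{silent}).
#' @export
glassyOnset <- function(model, tGrid = defaultTemperatureGrid(),
                        config = samplerConfig(nSamples = 3e4, nChains = 8L)) {
  cr <- responseCurve(model, tGrid, config, initMode = "random")
  cfg2 <- config
  cfg2@seed <- deriveSeed(config@seed, "silent")
  cs <- responseCurve(model, tGrid, cfg2, initMode = "silent")
  sig <- function(a, aSe, b, bSe) {
    comb <- sqrt(aSe^2 + bSe^2)
    abs(a - b) > 3 * comb & comb > 0
  }
  flag <- sig(cr@cv, cr@cvSe, cs@cv, cs@cvSe) |
          sig(cr@chi, cr@chiSe, cs@chi, cs@chiSe)
  flag[is.na(flag)] <- FALSE
  consec <- which(flag[-1] & flag[-length(flag)])   # i and i+1 both flagged
  if (length(consec)) {
    tStar <- tGrid[max(consec) + 1]
    detected <- TRUE
  } else {
    tStar <- min(tGrid)
    detected <- FALSE
  }
  list(tStar = tStar, detected = detected, random = cr, silent = cs)
}

#' Finite-size scaling of response-function maxima
#'
#' Least-squares fit of \eqn{\log(\max)} against \eqn{\log N}; the
#' exponent's standard error is bootstrapped over the replicates within
#' each N (1000 resamples).
#'
#' @param data data.frame with columns \code{n}, \code{value} and
#'   optionally \code{replicate} and \code{tmax}.
#' @param nBoot bootstrap resamples.
#' @param seed bootstrap RNG seed.
#' @return a \linkS4class{ScalingFit}.
#' @examples
#' d <- data.frame(n = c(20, 40), value = c(20, 40))
#' finiteSizeScaling(d)@exponent    # exactly 1
#' @export
finiteSizeScaling <- function(data, nBoot = 1000, seed = 1L) {
  stopifnot(all(data$value > 0), length(unique(data$n)) >= 2)
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  fit <- lm(log(value) ~ log(n), data = data)
  expo <- unname(coef(fit)[2])
  se <- withSeed(seed, {
    slopes <- vapply(seq_len(nBoot), function(b) {
      res <- do.call(rbind, lapply(split(data, data$n), function(d)
        d[sample.int(nrow(d), replace = TRUE), , drop = FALSE]))
      unname(coef(lm(log(value) ~ log(n), data = res))[2])
    }, numeric(1))
    sd(slopes)
  })
  tmax <- if ("tmax" %in% names(data))
    vapply(split(data$tmax, data$n), mean, numeric(1))
  else rep(NA_real_, length(unique(data$n)))
  new("ScalingFit", table = data, exponent = expo,
      exponentSe = if (is.finite(se) && se > 0) se else 1e-12, tmax = tmax)
}
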