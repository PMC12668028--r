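# Binning, constrained statistics, three-point correlations, firing rates
# and allometric scaling.

test_that("binning maps events to +/-1 bins and drops the partial tail", {
  ev <- new("SpikeEvents", time = c(3, 27), channel = c(1L, 1L),
            nChannels = 2L, nTimesteps = 100, dtMs = 1)
  r <- binEvents(ev, 25)
  expect_equal(nBins(r), 4)
  expect_equal(sigmaMatrix(r)[1, ], c(1L, 1L, -1L, -1L))
  expect_equal(sigmaMatrix(r)[2, ], rep(-1L, 4))
  # empty list with stated duration: valid all-silent raster
  ev0 <- new("SpikeEvents", time = numeric(0), channel = integer(0),
             nChannels = 3L, nTimesteps = 100, dtMs = 1)
  r0 <- binEvents(ev0, 25)
  expect_equal(dim(sigmaMatrix(r0)), c(3L, 4L))
  expect_true(all(sigmaMatrix(r0) == -1L))
  # two events in the same bin count once
  ev2 <- new("SpikeEvents", time = c(3, 7), channel = c(1L, 1L),
             nChannels = 1L, nTimesteps = 25, dtMs = 1)
  expect_equal(sigmaMatrix(binEvents(ev2, 25))[1, ], 1L)
  # a 107-unit recording at width 25 keeps floor(107/25) = 4 bins
  ev3 <- new("SpikeEvents", time = 104, channel = 1L, nChannels = 1L,
             nTimesteps = 107, dtMs = 1)
  expect_equal(nBins(binEvents(ev3, 25)), 4)
})

test_that("moments match hand counts and the covariance identity", {
  # channel active 3 of 4 bins
  m <- computeMoments(rasterFromMatrix(matrix(c(1, 1, 1, -1), 1)))
  expect_equal(meanSigma(m), 0.5)
  # all-silent raster: P(0) = 1 and zero covariance
  ms <- computeMoments(rasterFromMatrix(matrix(-1, 3, 10)))
  expect_equal(synchronyPK(ms)[1], 1)
  expect_true(all(abs(correlationMatrix(ms)[upper.tri(diag(3))]) < 1e-15))
  # two perfectly synchronized channels on a 6-bin raster
  row <- c(1, -1, 1, 1, -1, 1)
  m2 <- computeMoments(rasterFromMatrix(rbind(row, row)))
  mu <- mean(row)
  expect_equal(correlationMatrix(m2)[1, 2], 1 - mu^2)
  expect_equal(correlationMatrix(m2)[1, 2],
               mean(row * row) - mean(row)^2)   # both Cij forms agree
})

test_that("Cij equals the brute-force central-moment sum on small rasters", {
  withr::local_seed(11)
  for (rep in 1:5) {
    sig <- matrix(sample(c(-1L, 1L), 5 * 400, replace = TRUE,
                         prob = c(0.8, 0.2)), 5, 400)
    m <- computeMoments(rasterFromMatrix(sig))
    C <- correlationMatrix(m)
    for (i in 1:4) for (j in (i + 1):5) {
      direct <- mean((sig[i, ] - mean(sig[i, ])) * (sig[j, ] - mean(sig[j, ])))
      expect_equal(C[i, j], direct, tolerance = 1e-12)
    }
  }
})

test_that("P(K) is normalized and binomial for independent channels", {
  withr::local_seed(12)
  n <- 12; nb <- 20000; p <- 0.3
  sig <- matrix(ifelse(runif(n * nb) < p, 1L, -1L), n, nb)
  m <- computeMoments(rasterFromMatrix(sig))
  expect_lt(abs(sum(synchronyPK(m)) - 1), 1e-12)
  se <- standardErrors(m)$pk
  expected <- dbinom(0:n, n, p)
  dev <- abs(synchronyPK(m) - expected)
  expect_true(all(dev <= pmax(3 * se, 5e-4)))
})

test_that("three-point correlations match brute force and vanish as expected", {
  # constant raster: central moments vanish
  cst <- threePointCorrelations(rasterFromMatrix(matrix(1, 4, 8)))
  expect_true(all(cst$value == 0))
  # hand raster: direct enumeration over the 4 bins
  sig <- matrix(c(1, -1, 1, -1,
                  1, 1, -1, -1,
                  -1, 1, 1, -1), 3, 4, byrow = TRUE)
  tp <- threePointCorrelations(rasterFromMatrix(sig))
  a <- sig[1, ] - mean(sig[1, ]); b <- sig[2, ] - mean(sig[2, ])
  cc <- sig[3, ] - mean(sig[3, ])
  expect_equal(tp$value, mean(a * b * cc))
  # permutation invariance via explicit triple orderings
  tpPerm <- threePointCorrelations(rasterFromMatrix(sig[c(2, 3, 1), ]))
  expect_equal(tpPerm$value, tp$value)
  # independent channels decorrelate as Nb grows
  withr::local_seed(13)
  nb <- 1e5
  ind <- matrix(sample(c(-1L, 1L), 3 * nb, replace = TRUE), 3, nb)
  tpI <- threePointCorrelations(rasterFromMatrix(ind))
  expect_true(all(abs(tpI$value) < 4 / sqrt(nb)))
  # fewer than 3 channels: empty result
  expect_equal(nrow(threePointCorrelations(rasterFromMatrix(matrix(1, 2, 4)))), 0)
})

test_that("firing rates convert activities to rates in the right units", {
  silent <- rasterFromMatrix(matrix(-1L, 2, 10), binWidth = 25)
  expect_equal(firingRates(silent, binSeconds = 0.025)$rates, c(0, 0))
  always <- rasterFromMatrix(matrix(1L, 1, 10), binWidth = 25)
  expect_equal(firingRates(always, binSeconds = 0.025)$rates, 40)  # Hz
  expect_equal(firingRates(always)$rates, 1 / 25)  # per clock unit
})

test_that("allometric fits recover exact exponents", {
  d <- data.frame(n = c(20, 40, 80, 100), na = 2 * c(20, 40, 80, 100)^0.8)
  expect_equal(allometricFit(d, nBoot = 50)$eta, 0.8, tolerance = 1e-10)
  dc <- data.frame(n = c(20, 40, 80), na = c(7, 7, 7))
  expect_equal(allometricFit(dc, nBoot = 50)$eta, 0, tolerance = 1e-10)
})
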