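# K-pairwise model: energies, exact enumeration, Metropolis sampling,
# Boltzmann-machine learning, raster generation and the model file format.

test_that("energy evaluates the Hamiltonian term by term", {
  n <- 4
  m0 <- kPairwiseModel(h = rep(0, n))
  for (s in list(rep(1, n), rep(-1, n), c(1, -1, 1, -1)))
    expect_equal(modelEnergy(m0, s), 0)
  m <- kPairwiseModel(h = c(1, -1), J = matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(modelEnergy(m, c(1, 1)), -0.5)
  mV <- kPairwiseModel(h = c(1, -1), J = matrix(c(0, 0.5, 0.5, 0), 2),
                       V = c(0, 0, 2))
  expect_equal(modelEnergy(mV, c(1, 1)), -2.5)
})

test_that("delta energy matches full recomputation for every flip", {
  m <- randomModel(8, seed = 21)
  # independent spin: flipping +1 in field h = 1 costs +2
  expect_equal(deltaEnergy(independentModel(1), 1, 1), 2)
  withr::local_seed(22)
  s <- sample(c(-1, 1), 8, replace = TRUE)
  for (i in 1:8) {
    s2 <- s; s2[i] <- -s2[i]
    expect_equal(deltaEnergy(m, s, i), modelEnergy(m, s2) - modelEnergy(m, s),
                 tolerance = 1e-10)
    # flip up then down sums to zero
    expect_equal(deltaEnergy(m, s, i) + deltaEnergy(m, s2, i), 0,
                 tolerance = 1e-12)
  }
})

test_that("exact enumeration reproduces closed forms", {
  e1 <- enumerateModel(kPairwiseModel(h = 0))
  expect_equal(exp(e1$logZ), 2)
  expect_equal(e1$moments@mean, 0)
  # h = 0 pair: <s1 s2> = tanh(J)
  e2 <- enumerateModel(kPairwiseModel(h = c(0, 0),
                                      J = matrix(c(0, 0.5, 0.5, 0), 2)))
  expect_equal(e2$moments@pair[1, 2], tanh(0.5))
  # field-only models: <s_i> = tanh(h_i / T)
  hh <- c(-1.2, 0.3, 0.8)
  for (Tt in c(0.5, 1, 2))
    expect_equal(enumerateModel(kPairwiseModel(h = hh), Tt)$moments@mean,
                 tanh(hh / Tt))
  # zero model: P(K) binomial
  e3 <- enumerateModel(kPairwiseModel(h = rep(0, 3)))
  expect_equal(e3$moments@pk, choose(3, 0:3) / 8)
  expect_error(enumerateModel(kPairwiseModel(h = rep(0, 21))), "N > 20")
})

test_that("Metropolis moments agree with enumeration and closed forms", {
  # single spin: tanh(1) within 3 chain SEs
  mm1 <- metropolisMoments(independentModel(1), 1,
                           samplerConfig(nSamples = 2e4, nChains = 8L, seed = 1))
  expect_lt(abs(mm1$moments@mean - tanh(1)), 3 * mm1$moments@se$mean)
  # random N = 8 model against the exact oracle
  m <- randomModel(8, seed = 31)
  ex <- enumerateModel(m)
  mm <- metropolisMoments(m, 1, samplerConfig(nSamples = 5e4, nChains = 16L,
                                              seed = 2))
  se <- mm$moments@se
  expect_true(all(abs(mm$moments@mean - ex$moments@mean) <
                  pmax(3 * se$mean, 1e-3)))
  up <- upper.tri(se$pair)
  expect_true(all(abs(mm$moments@pair - ex$moments@pair)[up] <
                  pmax(3 * se$pair, 1e-3)[up]))
  expect_true(all(abs(mm$moments@pk - ex$moments@pk) <
                  pmax(3 * se$pk, 1e-3)))
  # infinite-temperature limit: free spins, binomial synchrony
  mmT <- metropolisMoments(m, 1e3, samplerConfig(nSamples = 5e4, nChains = 8L,
                                                 seed = 3))
  expect_true(all(abs(mmT$moments@mean) < 0.05))
  expect_true(all(abs(mmT$moments@pk - dbinom(0:8, 8, 0.5)) < 0.02))
})

test_that("sampled states respect detailed balance on a spin marginal", {
  # single spin in a field: occupation ratio must equal exp(2h/T)
  h <- 0.7
  r <- sampleRaster(independentModel(h), 4e4, seed = 4)
  pUp <- mean(sigmaMatrix(r) == 1)
  expect_lt(abs(pUp / (1 - pUp) - exp(2 * h)), 3 * 0.05 * exp(2 * h))
})

test_that("Boltzmann-machine learning fits independent spins", {
  n <- 6
  truth <- 0.5
  pk <- dbinom(0:n, n, (truth + 1) / 2)
  mom <- new("MomentSet", mean = rep(truth, n),
             pair = matrix(truth^2, n, n) + diag(1 - truth^2, n),
             pk = pk,
             se = list(mean = rep(1e-3, n), pair = matrix(1e-3, n, n),
                       pk = rep(1e-3, n + 1)),
             nBins = 1e5)
  fit <- fitKPairwise(mom, learningSchedule(theta0 = 0.3, maxIters = 5e3,
                                            mcSamples = 1e4,
                                            pkThreshold = 1e-3), seed = 5)
  ex <- enumerateModel(fit$model)
  expect_true(all(abs(ex$moments@mean - truth) < 0.02))
  C <- correlationMatrix(ex$moments)
  expect_true(all(abs(C[upper.tri(C)]) < 0.02))
  # gauge: K = 0 potential pinned, unfitted potentials exactly zero
  expect_identical(fit$model@V[1], 0)
  expect_true(all(fit$model@V[!fit$model@fittedMask] == 0))
})

test_that("learning recovers the moments of a known model", {
  truth <- randomModel(8, seed = 41, jSd = 0.2, vSd = 0.3)
  raster <- sampleRaster(truth, 3e4, seed = 42)
  mom <- computeMoments(raster)
  fit <- fitKPairwise(mom, learningSchedule(theta0 = 0.3, maxIters = 1.5e4,
                                            mcSamples = 1e4,
                                            pkThreshold = 1e-3), seed = 43)
  ex <- enumerateModel(fit$model)
  se <- standardErrors(mom)
  expect_true(all(abs(ex$moments@mean - mom@mean) < pmax(3 * se$mean, 0.01)))
  up <- upper.tri(diag(8))
  expect_true(all(abs(ex$moments@pair - mom@pair)[up] <
                  pmax(3 * se$pair, 0.01)[up]))
  fk <- fit$model@fittedMask
  expect_true(all(abs(ex$moments@pk - mom@pk)[fk] <
                  pmax(3 * se$pk, 0.1 * mom@pk)[fk]))
})

test_that("fit preconditions are enforced", {
  mom <- computeMoments(rasterFromMatrix(matrix(sample(c(-1L, 1L), 200,
                                                       replace = TRUE), 2)))
  expect_error(fitKPairwise(mom), "1e4 bins")
})

test_that("sampled rasters converge to the model moments", {
  # strongly silent independent model: P(K) from enumeration
  h <- rep(atanh(-0.9), 6)
  mod <- independentModel(h)
  r <- sampleRaster(mod, 2e4, seed = 6)
  pk <- synchronyPK(computeMoments(r))
  exPk <- enumerateModel(mod)$moments@pk
  expect_equal(exPk[1], 0.95^6, tolerance = 1e-12)
  expect_true(all(abs(pk - exPk) < 0.01))
  # zero bins: empty raster
  r0 <- sampleRaster(mod, 0, seed = 1)
  expect_equal(dim(sigmaMatrix(r0)), c(6L, 0L))
  # random model: sampled moments near enumeration
  m <- randomModel(10, seed = 51, jSd = 0.2)
  rs <- sampleRaster(m, 1e5, seed = 52)
  ms <- computeMoments(rs)
  ex <- enumerateModel(m)
  expect_true(all(abs(ms@mean - ex$moments@mean) <
                  pmax(3 * ms@se$mean, 5e-3)))
})

test_that("three-point predictions match enumeration and factorize", {
  # independent spins: all triple central moments vanish
  ind <- independentModel(c(-0.5, 0.2, 0.4, -1))
  tp <- predictThreePoint(ind, config = samplerConfig(nSamples = 5e3,
                                                      nChains = 20L, seed = 7))
  expect_true(all(abs(tp$value) < pmax(3 * tp$se, 5e-3)))
  # against exact enumeration on a coupled model
  m <- randomModel(7, seed = 61, jSd = 0.25)
  tpm <- predictThreePoint(m, config = samplerConfig(nSamples = 2e4,
                                                     nChains = 20L, seed = 8))
  trs <- t(combn(7, 3))
  ex <- enumerateModel(m, triples = trs)
  mom <- ex$moments
  exact <- vapply(seq_len(nrow(ex$triple)), function(r) {
    i <- ex$triple$i[r]; j <- ex$triple$j[r]; k <- ex$triple$k[r]
    ex$triple$moment[r] - mom@mean[i] * mom@pair[j, k] -
      mom@mean[j] * mom@pair[i, k] - mom@mean[k] * mom@pair[i, j] +
      2 * mom@mean[i] * mom@mean[j] * mom@mean[k]
  }, numeric(1))
  expect_true(all(abs(tpm$value - exact) < pmax(3 * tpm$se, 5e-3)))
})

test_that("model files round-trip bit exactly", {
  m <- randomModel(9, seed = 71)
  path <- withr::local_tempfile(fileext = ".txt")
  writeKPairwiseModel(m, path)
  m2 <- readKPairwiseModel(path)
  expect_identical(m@h, m2@h)
  expect_identical(m@J, m2@J)
  expect_identical(m@V, m2@V)
  expect_identical(m@fittedMask, m2@fittedMask)
})
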