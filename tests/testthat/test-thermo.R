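# Thermodynamics of the models: response curves against closed forms and
# enumeration, fluctuation-dissipation consistency, maxima location,
# glassy-onset detection and finite-size scaling fits.

test_that("single-spin specific heat matches the closed form", {
  # Cv(T) = h^2 sech^2(h/T) / T^2; at h = T = 1 this is ~ 0.4200
  m <- independentModel(1)
  expect_equal(enumerateModel(m, 1)$cv, 1 / cosh(1)^2, tolerance = 1e-12)
  for (Tt in c(0.5, 1, 2))
    expect_equal(enumerateModel(m, Tt)$cv, (1 / cosh(1 / Tt)^2) / Tt^2,
                 tolerance = 1e-12)
  curve <- responseCurve(m, tGrid = 1,
                         config = samplerConfig(nSamples = 5e4, nChains = 8L,
                                                seed = 1))
  expect_lt(abs(curve@cv - 0.4199743), pmax(3 * curve@cvSe, 5e-3))
})

test_that("free spins have unit intensive susceptibility at T = 1", {
  n <- 10
  m <- kPairwiseModel(h = rep(0, n))
  expect_equal(enumerateModel(m, 1)$chi / n, 1)
  curve <- responseCurve(m, tGrid = 1,
                         config = samplerConfig(nSamples = 5e4, nChains = 8L,
                                                seed = 2))
  expect_lt(abs(curve@chi / n - 1), pmax(3 * curve@chiSe / n, 0.01))
})

test_that("sampled response curves track enumeration across the grid", {
  m <- randomModel(10, seed = 81, jSd = 0.2)
  tg <- c(0.5, 0.8, 1, 1.3, 2)
  curve <- responseCurve(m, tg, samplerConfig(nSamples = 4e4, nChains = 12L,
                                              seed = 3))
  for (ti in seq_along(tg)) {
    ex <- enumerateModel(m, tg[ti])
    expect_lt(abs(curve@cv[ti] - ex$cv), pmax(3 * curve@cvSe[ti], 0.05))
    expect_lt(abs(curve@chi[ti] - ex$chi), pmax(3 * curve@chiSe[ti], 0.05))
  }
  expect_true(all(curve@cv >= 0) && all(curve@chi >= 0))
})

test_that("Cv equals dE/dT on the enumeration (fluctuation-dissipation)", {
  m <- randomModel(8, seed = 91, jSd = 0.25)
  dT <- 2e-4
  for (Tt in c(0.6, 1, 1.5)) {
    dEdT <- (enumerateModel(m, Tt + dT)$energy$mean -
             enumerateModel(m, Tt - dT)$energy$mean) / (2 * dT)
    expect_lt(abs(enumerateModel(m, Tt)$cv - dEdT), 1e-6)
  }
})

test_that("maxima are located with quadratic refinement", {
  tg <- seq(0.5, 2.5, by = 0.1)
  mkCurve <- function(y) new("ThermoCurve", temperatures = tg, cv = y,
                             cvSe = rep(0.001, length(tg)), chi = y,
                             chiSe = rep(0.001, length(tg)),
                             initMode = "random")
  bump <- 2 - (tg - 1.2)^2
  loc <- locateMaximum(mkCurve(bump), "cv")
  expect_true(loc$interior)
  expect_equal(loc$tMax, 1.2, tolerance = 0.02)
  mono <- locateMaximum(mkCurve(3 - tg), "cv")
  expect_false(mono$interior)
  expect_equal(mono$tMax, tg[1])
  # restriction to T > tMin skips a spurious low-T peak
  spiky <- bump; spiky[1] <- 5
  locR <- locateMaximum(mkCurve(spiky), "cv", tMin = 0.7)
  expect_equal(locR$tMax, 1.2, tolerance = 0.02)
})

test_that("well-mixed models show no initial-condition dependence", {
  tg <- c(0.2, 0.5, 1, 2)
  cfg <- samplerConfig(nSamples = 2e4, nChains = 8L, seed = 4)
  # independent spins: nothing to frustrate
  gi <- glassyOnset(independentModel(rep(-1, 8)), tg, cfg)
  expect_false(gi$detected)
  expect_equal(gi$tStar, min(tg))
  # small random model in the oracle regime mixes at these temperatures
  gm <- glassyOnset(randomModel(10, seed = 101, jSd = 0.15), tg, cfg)
  expect_false(gm$detected)
})

test_that("finite-size scaling fits recover exact exponents", {
  d <- data.frame(n = rep(c(20, 40, 80), each = 3),
                  value = 0.5 * rep(c(20, 40, 80), each = 3)^1.5,
                  replicate = rep(1:3, 3))
  sf <- finiteSizeScaling(d, nBoot = 200)
  expect_equal(sf@exponent, 1.5, tolerance = 1e-10)
  expect_lt(sf@exponentSe, 1e-6)
  two <- finiteSizeScaling(data.frame(n = c(20, 40), value = c(20, 40)),
                           nBoot = 50)
  expect_equal(two@exponent, 1, tolerance = 1e-10)
})
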